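# ADTA scoring: image scores, patient medians, risk classes, staging.

test_that("image score is the positive in-tumor patch fraction", {
  ps <- patch_set("img", data.frame(x = c(0, 100, 0, 100),
                                    y = c(0, 0, 100, 100),
                                    prob = c(0.9, 0.8, 0.1, 0.5)), 100)
  full <- tumor_mask("img", matrix(1L, 200, 200))
  sc <- score_image(ps, full)
  expect_equal(sc$n_total, 4)
  expect_equal(sc$n_pos, 2)
  expect_equal(sc$value, 0.5)
})

test_that("positivity boundary follows the configured rule", {
  ps <- patch_set("img", data.frame(x = 0, y = 0, prob = 0.775), 100)
  full <- tumor_mask("img", matrix(1L, 100, 100))
  expect_equal(score_image(ps, full, scoring_config())$n_pos, 1)
  expect_equal(
    score_image(ps, full,
                scoring_config(boundary_rule = "strictly_above"))$n_pos, 0)
})

test_that("an image with no tumor patches is an error", {
  ps <- grid_patches(3, 3, 10)
  empty <- tumor_mask("img", matrix(0L, 30, 30))
  expect_error(score_image(ps, empty), class = "adta_validation_error")
  expect_error(score_image(ps, empty), "no tumor patches")
})

test_that("image score is non-increasing in the positivity threshold", {
  set.seed(5)
  ps <- grid_patches(10, 10, 10)
  full <- tumor_mask("fixture", matrix(1L, 100, 100))
  vals <- vapply(seq(0.05, 0.95, by = 0.05), function(tau)
    score_image(ps, full, scoring_config(positivity_threshold = tau))$value,
    numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("patches outside the mask never affect the score", {
  set.seed(6)
  ring <- cbind(c(0, 50, 50, 0), c(0, 0, 50, 50))
  ann <- tumor_annotation("a", list(list(ring)))
  inside <- expand.grid(x = (0:4) * 10, y = (0:4) * 10)
  outside <- expand.grid(x = (6:9) * 10, y = (6:9) * 10)
  probs_in <- runif(nrow(inside))
  base <- score_image(
    patch_set("a", data.frame(inside, prob = probs_in), 10), ann)
  extended <- score_image(
    patch_set("a", data.frame(x = c(inside$x, outside$x),
                              y = c(inside$y, outside$y),
                              prob = c(probs_in, runif(nrow(outside)))), 10),
    ann)
  expect_equal(extended$n_total, base$n_total)
  expect_equal(extended$value, base$value)
})

test_that("patient score is the median of image scores with risk direction", {
  expect_equal(score_patient(c(0.1, 0.3, 0.2))$adta, 0.2)
  expect_equal(score_patient(c(0.1, 0.3))$adta, 0.2)
  one <- score_patient(0.07, scoring_config(risk_cutoff = 0.065))
  expect_equal(one$adta, 0.07)
  expect_equal(one$risk_class, "low_risk")
  low <- score_patient(0.05, scoring_config(risk_cutoff = 0.065))
  expect_equal(low$risk_class, "high_risk")
  # boundary: score exactly at the cutoff is low risk (inclusive)
  expect_equal(score_patient(0.065)$risk_class, "low_risk")
  expect_error(score_patient(numeric(0)), "no scored images")
})

test_that("patient median is invariant to image ordering", {
  set.seed(8)
  vals <- runif(7)
  for (i in 1:5)
    expect_equal(score_patient(sample(vals))$adta, score_patient(vals)$adta)
})

test_that("cohort scoring partitions patients into classes plus exclusions", {
  set.seed(9)
  cfg <- sim_config(seed = 9, n_patients = 10, grid_dims = c(6L, 6L),
                    patch_size = 10L)
  co <- gen_cohort(cfg)
  sc <- score_cohort(co$patch_sets, co$annotations, co$index)
  n_classified <- sum(sc$patients$risk_class %in% c("high_risk", "low_risk"))
  n_excluded <- sum(sc$excluded$unit == "patient")
  expect_equal(n_classified + n_excluded, cfg$n_patients)
  expect_true(all(sc$images$n_pos <= sc$images$n_total))
  expect_equal(sc$images$image_score,
               sc$images$n_pos / sc$images$n_total)
})

test_that("stage derivation follows the node/satellite-then-depth rule", {
  cl <- validate_clinical(data.frame(
    patient_id = c("A", "B", "C", "D", "E"),
    dss_event = 0, followup_months = 10,
    t_stage = c(NA, 2L, 6L, NA, NA),
    depth_mm = c(5, 1.2, 3.5, 0.4, NA),
    ulceration = c(0L, 0L, 1L, 0L, NA),
    node_or_satellite_positive = c(1L, 0L, 0L, 0L, NA)))
  st <- derive_stage(cl)
  expect_equal(st[1], 3L)            # positive node -> III regardless of depth
  expect_equal(st[2], 1L)            # T1b -> I
  expect_equal(st[3], 2L)            # T3b -> II
  expect_equal(st[4], 1L)            # depth 0.4, no ulceration -> T1a -> I
  expect_true(is.na(st[5]))          # nothing usable
})

test_that("T stage from depth and ulceration uses the AJCC bands", {
  expect_equal(t_stage_from_depth(c(0.5, 1.0, 1.5, 2.5, 4.0, 6.0),
                                  c(0, 1, 0, 1, 0, 1)),
               c(1L, 2L, 3L, 6L, 5L, 8L))
})
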