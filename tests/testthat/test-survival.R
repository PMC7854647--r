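# Kaplan-Meier, log-rank, and Cox fits checked against hand-written
# textbook computations.

test_that("product-limit estimate matches the hand computation on toy data", {
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1), report_times = c(0, 2.5))
  tab <- km$table[km$table$n_event > 0, ]
  expect_equal(tab$time, c(1, 3))
  expect_equal(tab$surv, c(2 / 3, 0))          # (1 - 1/3), then (1 - 1/1)
  expect_equal(km$at_risk$n_risk, c(3L, 1L))   # all 3 at t=0, 1 left at 2.5
})

test_that("a group with no events has S identically 1", {
  km <- km_estimate(c(5, 10, 15), c(0, 0, 0))
  expect_true(all(km$table$surv == 1))
  expect_equal(km$n_events, 0)
})

test_that("KM matches the independent product-limit oracle on random cohorts", {
  set.seed(404)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    time <- round(rexp(n, 0.05), 1) + 0.1      # rounding induces ties
    event <- rbinom(n, 1, 0.7)
    if (sum(event) == 0) next
    km <- km_estimate(time, event)
    ref <- oracle_km(time, event)
    got <- km$table[km$table$n_event > 0, c("time", "surv")]
    expect_equal(got$time, ref$time)
    expect_equal(got$surv, ref$surv, tolerance = 1e-12)
  }
})

test_that("KM with no censoring is the empirical survival function", {
  set.seed(15)
  time <- rexp(30, 0.1)
  km <- km_estimate(time, rep(1, 30))
  for (j in seq_len(nrow(km$table)))
    expect_equal(km$table$surv[j], mean(time > km$table$time[j]),
                 tolerance = 1e-12)
})

test_that("log-rank statistic matches the per-event-time hypergeometric sum", {
  time <- c(1, 2, 3, 3)
  event <- c(1, 1, 0, 0)
  group <- c("A", "A", "B", "B")
  lr <- logrank_test(time, event, group)
  # hand sum: t=1: O=1 E=1/2 V=1/4; t=2: O=1 E=1/3 V=2/9 -> (O-E)^2/V = 49/17
  expect_equal(lr$statistic, 49 / 17, tolerance = 1e-10)
  expect_equal(lr$statistic, oracle_logrank(time, event, group),
               tolerance = 1e-10)

  set.seed(505)
  for (i in 1:15) {
    n <- sample(10:50, 1)
    time <- rexp(n, 0.1)
    event <- rbinom(n, 1, 0.6)
    group <- rbinom(n, 1, 0.5)
    if (sum(event) == 0 || length(unique(group)) < 2) next
    expect_equal(logrank_test(time, event, group)$statistic,
                 oracle_logrank(time, event, group), tolerance = 1e-9)
  }
})

test_that("log-rank on exchangeable groups is null", {
  time <- rep(c(2, 5, 9, 14), 2)
  event <- rep(c(1, 0, 1, 1), 2)
  group <- rep(c("A", "B"), each = 4)
  lr <- logrank_test(time, event, group)
  expect_lt(lr$statistic, 1e-9)
  expect_equal(lr$p_value, 1, tolerance = 1e-6)
})

test_that("log-rank is symmetric in group order and time-scale invariant", {
  set.seed(16)
  time <- rexp(40, 0.1); event <- rbinom(40, 1, 0.6)
  group <- rep(c("A", "B"), 20)
  a <- logrank_test(time, event, group)
  swapped <- ifelse(group == "A", "B", "A")
  expect_equal(logrank_test(time, event, swapped)$statistic, a$statistic,
               tolerance = 1e-12)
  expect_equal(logrank_test(time * 7.3, event, group)$statistic, a$statistic,
               tolerance = 1e-12)
  expect_error(logrank_test(time, rep(0, 40), group), "no events")
})

test_that("Cox on exchangeable groups gives HR 1 with CI spanning 1", {
  d <- data.frame(time = rep(c(3, 6, 9, 12, 15), 2),
                  event = rep(c(1, 1, 0, 1, 0), 2),
                  z = rep(c(0, 1), each = 5))
  fit <- cox_fit(d, "z")
  expect_lt(abs(fit$table$beta), 1e-6)
  expect_true(fit$table$ci_low < 1 && fit$table$ci_high > 1)
})

test_that("Cox beta matches brute-force partial-likelihood maximization", {
  # n = 8 toy, one binary covariate, no ties
  d <- data.frame(time = c(1.1, 2.3, 3.7, 4.1, 5.9, 6.2, 7.8, 9.5),
                  event = c(1, 1, 0, 1, 1, 0, 1, 1),
                  x = c(1, 1, 1, 0, 1, 0, 0, 0))
  fit <- cox_fit(d, "x")
  expect_equal(fit$table$beta, oracle_cox_beta(d$time, d$event, d$x),
               tolerance = 1e-4)
  # and the reported log partial likelihood is the oracle's at beta-hat
  expect_equal(fit$loglik, cox_logpl(fit$table$beta, d$time, d$event, d$x),
               tolerance = 1e-8)
})

test_that("Cox score test equals the log-rank statistic on tie-free data", {
  set.seed(606)
  for (i in 1:10) {
    n <- 40
    time <- rexp(n, 0.1) + cumsum(rep(1e-9, n))   # continuous, no ties
    event <- rbinom(n, 1, 0.7)
    z <- rbinom(n, 1, 0.5)
    if (sum(event) == 0 || length(unique(z)) < 2) next
    d <- data.frame(time = time, event = event, z = z)
    expect_equal(cox_fit(d, "z")$score_statistic,
                 logrank_test(time, event, z)$statistic, tolerance = 1e-6)
  }
})

test_that("Cox HR direction agrees with median event times (no censoring)", {
  set.seed(17)
  z <- rep(c(0, 1), each = 25)
  time <- rexp(50, ifelse(z == 1, 0.4, 0.1))
  d <- data.frame(time = time, event = 1, z = z)
  fit <- cox_fit(d, "z")
  expect_equal(fit$table$hr > 1,
               median(time[z == 1]) < median(time[z == 0]))
})

test_that("complete separation is flagged with an unbounded CI", {
  d <- data.frame(time = c(1, 2, 3, 4, 10, 11, 12, 13),
                  event = c(1, 1, 1, 1, 0, 0, 0, 0),
                  z = c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_warning(fit <- cox_fit(d, "z"), "separation")
  expect_true(fit$table$flagged)
})

test_that("tie handling default is Efron with Breslow behind the flag", {
  set.seed(18)
  d <- data.frame(time = sample(1:6, 40, replace = TRUE),
                  event = rbinom(40, 1, 0.7), z = rbinom(40, 1, 0.5))
  fe <- cox_fit(d, "z", ties = "efron")
  fb <- cox_fit(d, "z", ties = "breslow")
  expect_false(isTRUE(all.equal(fe$table$beta, fb$table$beta)))
  expect_equal(fe$ties, "efron")
})

test_that("Cox input contracts are enforced", {
  d <- data.frame(time = c(1, 2), event = c(0, 0), z = c(0, 1))
  expect_error(cox_fit(d, "z"), "no events")
  d2 <- data.frame(time = 1:6, event = 1, a = 1:6, b = 2 * (1:6))
  expect_error(cox_fit(d2, c("a", "b")), "collinear")
  expect_error(cox_fit(d2, "missing_col"), class = "adta_format_error")
})
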