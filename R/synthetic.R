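# Synthetic cohorts: spatially clustered patch-probability maps inside
# random tumor polygons, ordinal TIL grades tied to the latent infiltration,
# and proportional-hazards disease-specific survival with uniform
# administrative censoring. Every stage of the scoring/cutoff/validation
# pipeline can run on these cohorts without any external data.
#
# Key calibration property: the number of TIL-high patches in an image is
# Binomial(n_tumor, lambda); cluster centres only steer WHERE those patches
# sit. Hence the expected in-tumor positive fraction has the closed form
#   E[s] = lambda * q_high + (1 - lambda) * q_low,
# with q_* the Beta tail mass above the positivity threshold.

#' Simulation configuration
#'
#' Defaults emulate the published study conditions: a minority
#' (`high_weight` = 0.19) of patients in a high-infiltrate good-prognosis
#' component; patch grids of 100-px patches; in-tumor positive fractions
#' spanning roughly 0-0.4 around the 0.065 cutoff; Breslow depth log-normal
#' with median ~2.4 mm; ulceration rate 0.44; a true hazard ratio of 4 for
#' the high-risk indicator; and an event fraction near 45-55% under
#' 180-month uniform administrative censoring.
#'
#' @param seed Integer RNG seed; identical configs generate byte-identical
#'   cohorts.
#' @param n_patients Number of patients.
#' @param images_per_patient Integer range `c(min, max)`; per-patient image
#'   count is uniform on it (default 1-4: primary melanomas are commonly
#'   sectioned into several slides).
#' @param grid_dims Patches per image, `c(nx, ny)`.
#' @param patch_size Patch edge in pixels.
#' @param high_weight Mixture weight of the high-infiltrate component.
#' @param lambda_low,lambda_high Beta shape pairs for the latent per-patient
#'   infiltration lambda in each component.
#' @param prob_low,prob_high Beta shape pairs for patch probabilities in
#'   background vs TIL-high patches.
#' @param cluster_count Poisson mean scale for the number of spatial
#'   clusters of TIL-high patches.
#' @param cluster_radius Cluster kernel radius in patch units.
#' @param coverage Allowed tumor coverage range of the patch grid (fraction
#'   of patch centers inside the polygon).
#' @param grade_noise Probability that the pathologist TIL grade implied by
#'   lambda is misgraded by one level.
#' @param grade_breaks Lambda thresholds separating grades 0/1/2.
#' @param baseline_hazard Baseline event rate, events/month.
#' @param beta_risk True log hazard ratio for the high-risk indicator
#'   (default log 4).
#' @param beta_depth,beta_ulc True log hazard ratios for depth (per mm) and
#'   ulceration.
#' @param depth_meanlog,depth_sdlog Log-normal parameters for Breslow depth.
#' @param ulceration_rate,node_positive_rate Bernoulli rates.
#' @param censor_window Months of uniform administrative censoring.
#' @param risk_cutoff ADTA cutoff defining the true risk class from the
#'   expected positive fraction.
#' @param positivity_threshold Patch positivity threshold tau.
#' @param institutions Character vector of institution labels to assign.
#' @param institution_weights Sampling weights for `institutions`.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 80L,
                       images_per_patient = c(1L, 4L),
                       grid_dims = c(20L, 20L),
                       patch_size = 100L,
                       high_weight = 0.19,
                       lambda_low = c(2, 60),
                       lambda_high = c(4, 3),
                       prob_low = c(2, 12),
                       prob_high = c(10, 3),
                       cluster_count = 3,
                       cluster_radius = 2.5,
                       coverage = c(0.3, 0.9),
                       grade_noise = 0.2,
                       grade_breaks = c(0.01, 0.30),
                       baseline_hazard = 0.0015,
                       beta_risk = log(4),
                       beta_depth = log(1.15),
                       beta_ulc = log(1.5),
                       depth_meanlog = log(2.4),
                       depth_sdlog = 0.6,
                       ulceration_rate = 0.44,
                       node_positive_rate = 0.2,
                       censor_window = 180,
                       risk_cutoff = 0.065,
                       positivity_threshold = 0.775,
                       institutions = "SIM",
                       institution_weights = NULL) {
  cfg <- list(seed = as.integer(seed), n_patients = as.integer(n_patients),
              images_per_patient = as.integer(images_per_patient),
              grid_dims = as.integer(grid_dims),
              patch_size = as.integer(patch_size),
              high_weight = high_weight, lambda_low = lambda_low,
              lambda_high = lambda_high, prob_low = prob_low,
              prob_high = prob_high, cluster_count = cluster_count,
              cluster_radius = cluster_radius, coverage = coverage,
              grade_noise = grade_noise, grade_breaks = grade_breaks,
              baseline_hazard = baseline_hazard, beta_risk = beta_risk,
              beta_depth = beta_depth, beta_ulc = beta_ulc,
              depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
              ulceration_rate = ulceration_rate,
              node_positive_rate = node_positive_rate,
              censor_window = censor_window, risk_cutoff = risk_cutoff,
              positivity_threshold = positivity_threshold,
              institutions = institutions,
              institution_weights = institution_weights)
  with(cfg, {
    stopifnot(n_patients >= 1, length(images_per_patient) == 2,
              images_per_patient[1] >= 1,
              images_per_patient[2] >= images_per_patient[1],
              all(grid_dims >= 2), patch_size >= 1,
              high_weight > 0, high_weight < 1,
              all(c(lambda_low, lambda_high, prob_low, prob_high) > 0),
              cluster_count > 0, cluster_radius > 0,
              coverage[1] > 0, coverage[2] <= 1, coverage[1] < coverage[2],
              grade_noise >= 0, grade_noise < 1,
              baseline_hazard > 0, censor_window > 0,
              risk_cutoff > 0, risk_cutoff < 1,
              positivity_threshold > 0, positivity_threshold < 1)
  })
  structure(cfg, class = "sim_config")
}

#' Expected in-tumor positive fraction for a latent infiltration
#'
#' Closed form `lambda * q_high + (1 - lambda) * q_low`, where `q_*` is the
#' upper tail mass of the respective patch-probability Beta component above
#' the positivity threshold. This is the exact expectation of the scored
#' image value under the generator.
#'
#' @param lambda Latent infiltration in (0, 1) (vectorized).
#' @param config A [sim_config()].
#' @return Numeric vector of expected positive fractions.
#' @export
expected_positive_fraction <- function(lambda, config) {
  tau <- config$positivity_threshold
  q_low <- stats::pbeta(tau, config$prob_low[1], config$prob_low[2],
                        lower.tail = FALSE)
  q_high <- stats::pbeta(tau, config$prob_high[1], config$prob_high[2],
                         lower.tail = FALSE)
  lambda * q_high + (1 - lambda) * q_low
}

#' Expected ADTA of the two mixture components
#'
#' @param config A [sim_config()].
#' @return Named numeric vector `c(low_infiltrate = , high_infiltrate = )`
#'   of expected positive fractions at the component mean lambdas.
#' @export
component_expected_adta <- function(config) {
  mean_low <- config$lambda_low[1] / sum(config$lambda_low)
  mean_high <- config$lambda_high[1] / sum(config$lambda_high)
  c(low_infiltrate = expected_positive_fraction(mean_low, config),
    high_infiltrate = expected_positive_fraction(mean_high, config))
}

#' Expected event fraction under exponential hazard and uniform censoring
#'
#' For event time Exp(rate) and independent censoring Uniform(0, window),
#' P(event observed) = 1 - (1 - exp(-rate*window)) / (rate*window).
#'
#' @param rate Per-subject hazard (vectorized).
#' @param window Administrative censoring window in months.
#' @return Probability the event is observed before censoring.
#' @export
expected_event_fraction <- function(rate, window) {
  rw <- rate * window
  1 - (1 - exp(-rw)) / rw
}

# Random star-shaped simple polygon around the (jittered) grid centre, with
# radii clipped to stay strictly inside the pixel frame. Retries until the
# fraction of patch centres inside lands in the configured coverage band.
random_tumor_polygon <- function(config, image_id, max_tries = 100) {
  gx <- config$grid_dims[1]; gy <- config$grid_dims[2]
  ps <- config$patch_size
  W <- gx * ps; H <- gy * ps
  grid <- expand.grid(x = (seq_len(gx) - 1L) * ps, y = (seq_len(gy) - 1L) * ps)
  for (try in seq_len(max_tries)) {
    cx <- W / 2 + stats::runif(1, -0.08, 0.08) * W
    cy <- H / 2 + stats::runif(1, -0.08, 0.08) * H
    nv <- sample(6:12, 1)
    theta <- sort(stats::runif(nv, 0, 2 * pi))
    r <- stats::runif(nv, 0.40, 1.0) * 0.5 * min(W, H)
    # largest radius that keeps the vertex inside the frame along theta
    rmax <- pmin(
      ifelse(cos(theta) > 0, (W - cx) / cos(theta),
             ifelse(cos(theta) < 0, -cx / cos(theta), Inf)),
      ifelse(sin(theta) > 0, (H - cy) / sin(theta),
             ifelse(sin(theta) < 0, -cy / sin(theta), Inf)))
    r <- pmin(r, 0.98 * rmax)
    ring <- cbind(cx + r * cos(theta), cy + r * sin(theta))
    ann <- tryCatch(tumor_annotation(image_id, list(list(ring))),
                    adta_validation_error = function(e) NULL)
    if (is.null(ann)) next
    member <- patch_in_annotation(ann, grid$x, grid$y, ps)
    cov <- mean(member)
    if (cov >= config$coverage[1] && cov <= config$coverage[2] && sum(member) >= 1)
      return(list(annotation = ann, grid = grid, member = member))
    debug_log("polygon retry %d for %s (coverage %.2f)", try, image_id, cov)
  }
  abort_validation("could not generate a tumor polygon in the coverage band for '%s'",
                   image_id)
}

#' Generate one synthetic image
#'
#' Draws a random tumor polygon covering 30-90% of the patch grid, marks a
#' Binomial(n_tumor, lambda) subset of in-tumor patches as TIL-high with
#' spatial clustering around Poisson-placed centres, and samples patch
#' probabilities from the two-component Beta model (background component for
#' all other patches, inside or outside the tumor).
#'
#' Uses the current RNG state; seed via `set.seed()` or use [gen_cohort()].
#'
#' @param config A [sim_config()].
#' @param lambda Latent infiltration for the patient.
#' @param image_id Image identifier.
#' @return List with `patches` ([patch_set()]), `annotation`
#'   ([tumor_annotation()]), `n_tumor`, `n_high`.
#' @export
gen_image <- function(config, lambda, image_id = "img") {
  stopifnot(inherits(config, "sim_config"), lambda >= 0, lambda <= 1)
  poly <- random_tumor_polygon(config, image_id)
  grid <- poly$grid
  n <- nrow(grid)
  tumor_idx <- which(poly$member == 1L)
  n_tumor <- length(tumor_idx)
  n_high <- stats::rbinom(1, n_tumor, lambda)
  high <- logical(n)
  if (n_high > 0) {
    k <- 1L + stats::rpois(1, config$cluster_count * lambda)
    centers <- tumor_idx[sample.int(n_tumor, k, replace = TRUE)]
    ps <- config$patch_size
    d2 <- matrix(0, nrow = n_tumor, ncol = k)
    for (ci in seq_len(k)) {
      d2[, ci] <- ((grid$x[tumor_idx] - grid$x[centers[ci]]) / ps)^2 +
        ((grid$y[tumor_idx] - grid$y[centers[ci]]) / ps)^2
    }
    w <- 0.02 + rowSums(exp(-d2 / (2 * config$cluster_radius^2)))
    high[tumor_idx[sample.int(n_tumor, n_high, prob = w)]] <- TRUE
  }
  prob <- numeric(n)
  prob[high] <- stats::rbeta(sum(high), config$prob_high[1], config$prob_high[2])
  prob[!high] <- stats::rbeta(sum(!high), config$prob_low[1], config$prob_low[2])
  patches <- patch_set(image_id,
                       data.frame(x = grid$x, y = grid$y, prob = prob),
                       config$patch_size)
  list(patches = patches, annotation = poly$annotation,
       n_tumor = n_tumor, n_high = n_high)
}

#' Simulate survival outcomes for given linear predictors
#'
#' Event times are exponential with rate `baseline_hazard * exp(linpred)`;
#' censoring is uniform on `(0, censor_window)`. Uses the current RNG state.
#'
#' @param linpred Linear predictor per subject (log relative hazard).
#' @param config A [sim_config()].
#' @return `data.frame` with `time`, `event`, `rate`.
#' @export
sim_survival <- function(linpred, config) {
  rate <- config$baseline_hazard * exp(linpred)
  t_event <- stats::rexp(length(linpred), rate)
  t_cens <- stats::runif(length(linpred), 0, config$censor_window)
  data.frame(time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             rate = rate)
}

#' Generate a complete synthetic cohort
#'
#' Per patient: latent infiltration lambda from the two-component mixture,
#' 1-4 images via [gen_image()], Breslow depth (log-normal), ulceration,
#' T stage implied by depth and ulceration, TIL grade from lambda with
#' misgrading noise, nodal/satellite status, and disease-specific survival
#' from the proportional-hazards model
#' `h0 * exp(beta_risk * z + beta_depth * depth + beta_ulc * ulc)` where
#' `z = 1` when the true expected ADTA is below the risk cutoff. A cohort
#' that happens to contain zero events is redrawn (survival only) with a
#' warning, since downstream fits require at least one event.
#'
#' @param config A [sim_config()].
#' @return Object of class `synthetic_cohort`: list with `clinical`
#'   (validated clinical data.frame), `truth` (per-patient latent values),
#'   `patch_sets`, `annotations` (named lists by image_id), `index`
#'   (patient_id/image_id map), `config`.
#' @export
gen_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  pid <- sprintf("P%04d", seq_len(n))
  component <- ifelse(stats::runif(n) < config$high_weight,
                      "high_infiltrate", "low_infiltrate")
  lambda <- ifelse(component == "high_infiltrate",
                   stats::rbeta(n, config$lambda_high[1], config$lambda_high[2]),
                   stats::rbeta(n, config$lambda_low[1], config$lambda_low[2]))
  expected_adta <- expected_positive_fraction(lambda, config)
  z <- as.integer(expected_adta < config$risk_cutoff)

  n_images <- sample(seq(config$images_per_patient[1],
                         config$images_per_patient[2]),
                     n, replace = TRUE)
  patch_sets <- list(); annotations <- list()
  index <- data.frame(patient_id = character(), image_id = character())
  n_tumor <- integer(n); n_high <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n_images[i])) {
      iid <- sprintf("%s_img%d", pid[i], j)
      img <- gen_image(config, lambda[i], iid)
      patch_sets[[iid]] <- img$patches
      annotations[[iid]] <- img$annotation
      index <- rbind(index, data.frame(patient_id = pid[i], image_id = iid))
      n_tumor[i] <- n_tumor[i] + img$n_tumor
      n_high[i] <- n_high[i] + img$n_high
    }
  }

  depth <- stats::rlnorm(n, config$depth_meanlog, config$depth_sdlog)
  depth <- pmax(0.15, round(depth, 2))
  ulc <- stats::rbinom(n, 1, config$ulceration_rate)
  t_stage <- t_stage_from_depth(depth, ulc)
  grade <- findInterval(lambda, config$grade_breaks)
  flip <- stats::runif(n) < config$grade_noise
  grade[flip] <- pmin(2L, pmax(0L, grade[flip] +
                                 sample(c(-1L, 1L), sum(flip), replace = TRUE)))
  node <- stats::rbinom(n, 1, config$node_positive_rate)
  institution <- if (length(config$institutions) == 1) {
    rep(config$institutions, n)
  } else {
    sample(config$institutions, n, replace = TRUE,
           prob = config$institution_weights)
  }

  linpred <- config$beta_risk * z + config$beta_depth * depth +
    config$beta_ulc * ulc
  surv <- sim_survival(linpred, config)
  tries <- 0
  while (sum(surv$event) == 0 && tries < 20) {
    warning("generated cohort had zero events; redrawing survival outcomes")
    surv <- sim_survival(linpred, config)
    tries <- tries + 1
  }

  clinical <- validate_clinical(data.frame(
    patient_id = pid, depth_mm = depth, ulceration = ulc, t_stage = t_stage,
    til_grade = grade, node_or_satellite_positive = node,
    stage = NA_integer_, institution = institution,
    dss_event = surv$event, followup_months = pmax(0.01, round(surv$time, 2))))
  truth <- data.frame(patient_id = pid, component = component,
                      lambda = lambda, expected_adta = expected_adta,
                      true_risk_class = ifelse(z == 1, "high_risk", "low_risk"),
                      hazard_rate = surv$rate,
                      n_tumor_patches = n_tumor, n_high_patches = n_high)
  structure(list(clinical = clinical, truth = truth, patch_sets = patch_sets,
                 annotations = annotations, index = index, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d images, %d events (seed %d)\n",
              nrow(x$clinical), nrow(x$index), sum(x$clinical$dss_event),
              x$config$seed))
  invisible(x)
}
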