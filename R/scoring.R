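# ADTA scoring: per-image positive in-tumor patch fraction, per-patient
# median, binary risk class, and stage derivation for Cox covariates.

#' Scoring configuration
#'
#' @param positivity_threshold Probability above which a patch counts as
#'   TIL-positive. Default 0.775, the upstream detector's empirically
#'   determined operating point (77.5%).
#' @param risk_cutoff ADTA score below which a patient is high risk.
#'   Default 0.065, the published training-cohort ROC cutoff; normally
#'   re-derived on a training cohort via [select_cutoff()].
#' @param boundary_rule How a probability exactly at the threshold is
#'   treated: `"at_least"` (default; `prob >= tau` is positive) or
#'   `"strictly_above"`.
#' @return Object of class `scoring_config`.
#' @export
scoring_config <- function(positivity_threshold = 0.775,
                           risk_cutoff = 0.065,
                           boundary_rule = c("at_least", "strictly_above")) {
  boundary_rule <- match.arg(boundary_rule)
  if (!(positivity_threshold > 0 && positivity_threshold < 1))
    abort_validation("positivity_threshold must be in (0, 1)")
  if (!(risk_cutoff >= 0 && risk_cutoff <= 1))
    abort_validation("risk_cutoff must be in [0, 1]")
  structure(list(positivity_threshold = positivity_threshold,
                 risk_cutoff = risk_cutoff,
                 boundary_rule = boundary_rule),
            class = "scoring_config")
}

#' Score one image
#'
#' The ADTA image score is the number of TIL-positive in-tumor patches over
#' the total number of in-tumor patches. Patch membership uses the mask
#' center rule ([patch_in_tumor()]) when `tumor` is a mask, or the equivalent
#' polygon test ([patch_in_annotation()]) when it is an annotation.
#'
#' @param patches An [patch_set()] object.
#' @param tumor A [tumor_mask()] or [tumor_annotation()].
#' @param config A [scoring_config()].
#' @return Object of class `image_score`: list with `image_id`, `n_total`,
#'   `n_pos`, `value` (= `n_pos / n_total`).
#' @export
score_image <- function(patches, tumor, config = scoring_config()) {
  stopifnot(inherits(patches, "image_patch_set"),
            inherits(config, "scoring_config"))
  p <- patches$patches
  member <- if (inherits(tumor, "tumor_mask")) {
    patch_in_tumor(tumor, p$x, p$y, patches$patch_size)
  } else if (inherits(tumor, "tumor_annotation")) {
    patch_in_annotation(tumor, p$x, p$y, patches$patch_size)
  } else {
    abort_validation("tumor must be a tumor_mask or tumor_annotation")
  }
  n_total <- sum(member)
  if (n_total < 1)
    abort_validation("no tumor patches in image '%s'", patches$image_id)
  probs <- p$prob[member == 1L]
  tau <- config$positivity_threshold
  n_pos <- if (config$boundary_rule == "at_least") sum(probs >= tau)
           else sum(probs > tau)
  structure(list(image_id = patches$image_id, n_total = n_total,
                 n_pos = n_pos, value = n_pos / n_total),
            class = "image_score")
}

#' Aggregate image scores to a patient score
#'
#' The patient ADTA score is the median of the patient's image score values
#' (mean of the two middle values for an even count). Risk direction follows
#' the biology: high lymphocytic infiltrate (score at or above the cutoff)
#' is low risk.
#'
#' @param image_scores List of `image_score` objects, or a numeric vector of
#'   image score values.
#' @param config A [scoring_config()]; supplies the risk cutoff.
#' @param patient_id Optional identifier carried through.
#' @return Object of class `patient_score`: list with `patient_id`, `adta`,
#'   `risk_class` (`"low_risk"` iff `adta >= risk_cutoff`), `n_images`,
#'   `image_values`.
#' @export
score_patient <- function(image_scores, config = scoring_config(),
                          patient_id = NA_character_) {
  values <- if (is.numeric(image_scores)) image_scores
            else vapply(image_scores, function(s) s$value, numeric(1))
  if (!length(values))
    abort_validation("patient '%s' has no scored images", patient_id)
  adta <- stats::median(values)
  structure(list(patient_id = patient_id, adta = adta,
                 risk_class = classify_risk(adta, config$risk_cutoff),
                 n_images = length(values), image_values = values),
            class = "patient_score")
}

#' Binary risk class from an ADTA score
#'
#' @param adta Numeric vector of patient ADTA scores.
#' @param risk_cutoff Cutoff `c`; `adta >= c` is `"low_risk"` (high
#'   infiltrate, good prognosis), `adta < c` is `"high_risk"`.
#' @return Character vector.
#' @export
classify_risk <- function(adta, risk_cutoff) {
  ifelse(adta >= risk_cutoff, "low_risk", "high_risk")
}

#' Score a full cohort
#'
#' Runs [score_image()] over every image listed in the patient-image index
#' and [score_patient()] over each patient. Images without tumor patches and
#' patients left without any scored image are excluded with a recorded
#' reason rather than dropped silently.
#'
#' @param patch_sets Named list of `image_patch_set` objects (names =
#'   image_id).
#' @param tumors Named list of `tumor_mask` / `tumor_annotation` objects.
#' @param index `data.frame` with columns `patient_id`, `image_id`; every
#'   image belongs to exactly one patient.
#' @param config A [scoring_config()].
#' @return List with `images` (data.frame: patient_id, image_id, n_total,
#'   n_pos, image_score), `patients` (data.frame: patient_id, adta,
#'   risk_class, n_images), `excluded` (data.frame: unit, id, reason).
#' @export
score_cohort <- function(patch_sets, tumors, index, config = scoring_config()) {
  stopifnot(all(c("patient_id", "image_id") %in% names(index)))
  if (anyDuplicated(index$image_id))
    abort_validation("image '%s' listed under more than one patient",
                     index$image_id[anyDuplicated(index$image_id)])
  rows <- list(); excl <- list()
  for (i in seq_len(nrow(index))) {
    iid <- index$image_id[i]
    ps <- patch_sets[[iid]]
    if (is.null(ps)) abort_format("no patch table for image '%s'", iid)
    tum <- tumors[[iid]]
    if (is.null(tum)) abort_format("no tumor annotation or mask for image '%s'", iid)
    sc <- tryCatch(score_image(ps, tum, config),
                   adta_validation_error = function(e) e)
    if (inherits(sc, "error")) {
      excl[[length(excl) + 1L]] <- data.frame(unit = "image", id = iid,
                                              reason = conditionMessage(sc))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      patient_id = index$patient_id[i], image_id = iid,
      n_total = sc$n_total, n_pos = sc$n_pos, image_score = sc$value)
  }
  images <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(), image_id = character(),
               n_total = integer(), n_pos = integer(), image_score = numeric())
  pat_rows <- list()
  for (pid in unique(index$patient_id)) {
    vals <- images$image_score[images$patient_id == pid]
    if (!length(vals)) {
      excl[[length(excl) + 1L]] <- data.frame(unit = "patient", id = pid,
                                              reason = "patient has no scored images")
      next
    }
    psc <- score_patient(vals, config, patient_id = pid)
    pat_rows[[length(pat_rows) + 1L]] <- data.frame(
      patient_id = pid, adta = psc$adta, risk_class = psc$risk_class,
      n_images = psc$n_images)
  }
  patients <- if (length(pat_rows)) do.call(rbind, pat_rows) else
    data.frame(patient_id = character(), adta = numeric(),
               risk_class = character(), n_images = integer())
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(unit = character(), id = character(), reason = character())
  list(images = images, patients = patients, excluded = excluded)
}

#' Derive overall stage (I/II/III) from clinical fields
#'
#' Any patient with a known positive lymph node or documented satellite
#' metastasis is stage III; node/satellite-negative patients are stage I
#' (T1a-T2a) or stage II (T2b-T4b), using the recorded T stage when present
#' and otherwise the T stage implied by Breslow depth and ulceration
#' ([t_stage_from_depth()]). Patients with no usable fields get `NA`.
#'
#' @param clinical Clinical `data.frame` as from [read_clinical_table()].
#' @return Integer vector (1 = I, 2 = II, 3 = III, `NA` = underivable).
#' @export
derive_stage <- function(clinical) {
  n <- nrow(clinical)
  t_stage <- clinical$t_stage
  impute <- is.na(t_stage) & !is.na(clinical$depth_mm)
  t_stage[impute] <- t_stage_from_depth(clinical$depth_mm[impute],
                                        clinical$ulceration[impute])
  stage <- ifelse(is.na(t_stage), NA_integer_, ifelse(t_stage <= 3L, 1L, 2L))
  node <- clinical$node_or_satellite_positive
  stage[!is.na(node) & node == 1] <- 3L
  as.integer(stage)
}

#' T stage from Breslow depth and ulceration
#'
#' AJCC thickness bands (T1 <= 1.0 mm, T2 <= 2.0, T3 <= 4.0, T4 > 4.0) with
#' the a/b suffix from ulceration, coded 1..8 for T1a..T4b. Missing
#' ulceration is treated as absent (the less advanced category).
#'
#' @param depth_mm Breslow depth in mm.
#' @param ulceration 0/1 (may be `NA`).
#' @return Integer vector in 1..8.
#' @export
t_stage_from_depth <- function(depth_mm, ulceration = 0L) {
  tnum <- findInterval(depth_mm, c(1, 2, 4), left.open = TRUE) + 1L  # 1..4
  ulc <- ifelse(is.na(ulceration), 0L, as.integer(ulceration))
  out <- 2L * (tnum - 1L) + 1L + ulc
  out[is.na(depth_mm)] <- NA_integer_
  out
}

#' @export
print.image_score <- function(x, ...) {
  cat(sprintf("<image_score> %s: %d/%d positive, s = %.4f\n",
              x$image_id, x$n_pos, x$n_total, x$value))
  invisible(x)
}

#' @export
print.patient_score <- function(x, ...) {
  cat(sprintf("<patient_score> %s: ADTA = %.4f over %d image(s) -> %s\n",
              x$patient_id, x$adta, x$n_images, x$risk_class))
  invisible(x)
}
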