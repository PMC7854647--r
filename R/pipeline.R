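# File-based pipeline stages: simulate -> score -> cutoff -> validate.
# Each stage writes its outputs plus a run manifest into a staging directory
# that is promoted atomically on success; a failed stage leaves no partial
# output directory behind. The `inst/scripts/adta` Rscript exposes these as
# shell subcommands.

write_manifest <- function(dir, command, params, inputs = character(),
                           seed = NULL) {
  digests <- if (length(inputs)) {
    data.frame(path = unname(inputs), md5 = unname(tools::md5sum(inputs)))
  } else {
    data.frame(path = character(), md5 = character())
  }
  manifest <- list(command = command,
                   package_version = as.character(utils::packageVersion("adta")),
                   seed = seed, params = params, inputs = digests,
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

# Run `writer(staging_dir)` and atomically promote the staging directory to
# out_dir. out_dir must not already exist unless overwrite = TRUE.
with_staging <- function(out_dir, overwrite = FALSE, writer) {
  if (dir.exists(out_dir)) {
    if (!overwrite) abort_validation("output directory already exists: %s", out_dir)
  }
  parent <- dirname(normalizePath(out_dir, mustWork = FALSE))
  dir.create(parent, recursive = TRUE, showWarnings = FALSE)
  staging <- tempfile(pattern = ".staging-", tmpdir = parent)
  dir.create(staging)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  writer(staging)
  if (dir.exists(out_dir)) unlink(out_dir, recursive = TRUE)
  if (!file.rename(staging, out_dir))
    abort_validation("could not promote staging directory to %s", out_dir)
  invisible(out_dir)
}

#' Pipeline stage: simulate a cohort to disk
#'
#' Writes a full on-disk synthetic cohort in the exact formats the readers
#' consume: `patches/<image_id>.csv`, `annotations/<image_id>.geojson`,
#' `clinical.csv`, `index.csv`, plus `truth.csv` (per-patient latent ground
#' truth, clearly synthetic) and `manifest.json`.
#'
#' @param out_dir Output directory (created; must not exist unless
#'   `overwrite`).
#' @param config A [sim_config()].
#' @param overwrite Replace an existing output directory.
#' @return `out_dir`, invisibly.
#' @export
adta_simulate <- function(out_dir, config = sim_config(), overwrite = FALSE) {
  cohort <- gen_cohort(config)
  with_staging(out_dir, overwrite, function(dir) {
    dir.create(file.path(dir, "patches"))
    dir.create(file.path(dir, "annotations"))
    for (iid in names(cohort$patch_sets)) {
      write_patch_table(cohort$patch_sets[[iid]],
                        file.path(dir, "patches", paste0(iid, ".csv")))
      write_annotation(cohort$annotations[[iid]],
                       file.path(dir, "annotations", paste0(iid, ".geojson")))
    }
    utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$index, file.path(dir, "index.csv"),
                     row.names = FALSE)
    utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                     row.names = FALSE)
    yaml::write_yaml(list(patch_size = config$patch_size), file.path(dir, "cohort.yaml"))
    write_manifest(dir, "simulate", unclass(config), seed = config$seed)
  })
}

#' Pipeline stage: score a cohort on disk
#'
#' Reads the patch tables, annotations and patient-image index from
#' `in_dir` (the layout written by [adta_simulate()]), scores every image
#' and patient, and writes `image_scores.csv`, `patient_scores.csv`,
#' `excluded.csv` and `manifest.json`. A listed image with no annotation
#' file is a hard error naming the image.
#'
#' @param in_dir Cohort directory.
#' @param out_dir Output directory.
#' @param config A [scoring_config()].
#' @param patch_size Patch edge length in pixels; defaults to the value in
#'   the cohort's `cohort.yaml` (written by [adta_simulate()]) or 100, the
#'   upstream detector's tiling.
#' @param overwrite Replace an existing output directory.
#' @return `out_dir`, invisibly.
#' @export
adta_score <- function(in_dir, out_dir, config = scoring_config(),
                       patch_size = NULL, overwrite = FALSE) {
  index_path <- file.path(in_dir, "index.csv")
  if (!file.exists(index_path)) abort_format("no index.csv in %s", in_dir)
  if (is.null(patch_size)) {
    meta_path <- file.path(in_dir, "cohort.yaml")
    patch_size <- if (file.exists(meta_path))
      yaml::read_yaml(meta_path)$patch_size %||% 100 else 100
  }
  index <- utils::read.csv(index_path, stringsAsFactors = FALSE,
                           colClasses = "character")
  patch_sets <- list(); tumors <- list()
  for (iid in index$image_id) {
    ppath <- file.path(in_dir, "patches", paste0(iid, ".csv"))
    apath <- file.path(in_dir, "annotations", paste0(iid, ".geojson"))
    if (!file.exists(ppath))
      abort_format("missing patch table for image '%s' (%s)", iid, ppath)
    if (!file.exists(apath))
      abort_format("missing annotation for image '%s' (%s)", iid, apath)
    patch_sets[[iid]] <- read_patch_table(ppath, patch_size = patch_size,
                                          image_id = iid)
    tumors[[iid]] <- read_annotation(apath, image_id = iid)
  }
  scored <- score_cohort(patch_sets, tumors, index, config)
  with_staging(out_dir, overwrite, function(dir) {
    write_score_table(scored$images, file.path(dir, "image_scores.csv"))
    write_score_table(scored$patients, file.path(dir, "patient_scores.csv"))
    write_score_table(scored$excluded, file.path(dir, "excluded.csv"))
    write_manifest(dir, "score", unclass(config),
                   inputs = c(index_path, file.path(in_dir, "clinical.csv")))
  })
}

#' Pipeline stage: derive the risk cutoff on a training cohort
#'
#' Joins patient scores with the clinical table, builds the ROC of ADTA
#' score against death from melanoma, selects the cutoff (Youden by
#' default), and writes `roc.csv` plus `cutoff.yaml` (a config fragment
#' consumed by [adta_validate()]).
#'
#' @param scores_csv Patient score table (from [adta_score()]).
#' @param clinical_csv Clinical table.
#' @param out_dir Output directory.
#' @param criterion Cutoff criterion, see [select_cutoff()].
#' @param overwrite Replace an existing output directory.
#' @return The chosen cutoff, invisibly.
#' @export
adta_cutoff <- function(scores_csv, clinical_csv, out_dir,
                        criterion = "youden", overwrite = FALSE) {
  scores <- read_score_table(scores_csv)
  clinical <- read_clinical_table(clinical_csv)
  merged <- merge(scores, clinical, by = "patient_id")
  if (!nrow(merged))
    abort_validation("no patients shared between scores and clinical table")
  roc <- roc_curve(merged$adta, merged$dss_event)
  cutoff <- select_cutoff(roc, criterion = criterion)
  with_staging(out_dir, overwrite, function(dir) {
    utils::write.csv(roc$curve, file.path(dir, "roc.csv"), row.names = FALSE)
    yaml::write_yaml(list(risk_cutoff = cutoff, criterion = criterion,
                          auc = roc$auc, n = nrow(merged)),
                     file.path(dir, "cutoff.yaml"))
    write_manifest(dir, "cutoff", list(criterion = criterion),
                   inputs = c(scores_csv, clinical_csv))
  })
  invisible(cutoff)
}

#' Pipeline stage: survival validation of the binary risk class
#'
#' Applies a previously derived cutoff to a (validation) cohort's patient
#' scores and writes: Kaplan-Meier tables per risk group with at-risk counts
#' at the requested months, the log-rank test, univariable Cox models for
#' the risk class and each standard pathology covariate, the three
#' multivariable Cox models (risk + depth + ulceration; risk + T stage;
#' risk + derived stage), and the TIL-grade association results.
#'
#' @param scores_csv Patient score table for the cohort.
#' @param clinical_csv Clinical table for the cohort.
#' @param cutoff Numeric cutoff, or path to a `cutoff.yaml` written by
#'   [adta_cutoff()].
#' @param out_dir Output directory.
#' @param report_times Months at which KM at-risk counts are reported.
#' @param overwrite Replace an existing output directory.
#' @return Invisible list with all fitted results.
#' @export
adta_validate <- function(scores_csv, clinical_csv, cutoff, out_dir,
                          report_times = c(0, 100), overwrite = FALSE) {
  if (is.character(cutoff)) {
    frag <- yaml::read_yaml(cutoff)
    cutoff_path <- cutoff
    cutoff <- frag$risk_cutoff %||%
      abort_format("no risk_cutoff entry in %s", cutoff_path)
  } else cutoff_path <- NULL
  scores <- read_score_table(scores_csv)
  clinical <- read_clinical_table(clinical_csv)
  d <- merge(scores, clinical, by = "patient_id")
  if (!nrow(d)) abort_validation("no patients shared between scores and clinical table")
  d$risk_class <- classify_risk(d$adta, cutoff)
  d$high_risk <- as.integer(d$risk_class == "high_risk")
  d$time <- d$followup_months
  d$event <- d$dss_event
  d$stage_derived <- derive_stage(d)

  km <- lapply(split(d, d$risk_class), function(g)
    km_estimate(g$time, g$event, report_times))
  lr <- tryCatch(logrank_test(d$time, d$event, d$risk_class),
                 adta_validation_error = function(e) {
                   warning("log-rank not computed: ", conditionMessage(e))
                   list(statistic = NA_real_, df = NA_integer_,
                        p_value = NA_real_)
                 })

  uni_terms <- c("high_risk", "depth_mm", "ulceration", "t_stage", "til_grade")
  uni <- lapply(uni_terms, function(v)
    tryCatch(cox_fit(d, v), adta_error = function(e) NULL))
  names(uni) <- uni_terms
  multi <- list(
    adta_depth_ulceration = tryCatch(
      cox_fit(d, c("high_risk", "depth_mm", "ulceration")),
      adta_error = function(e) NULL),
    adta_t_stage = tryCatch(cox_fit(d, c("high_risk", "t_stage")),
                            adta_error = function(e) NULL),
    adta_stage = tryCatch(cox_fit(d, c("high_risk", "stage_derived")),
                          adta_error = function(e) NULL))

  assoc <- tryCatch(spearman_grade(d$adta, d$til_grade),
                    adta_error = function(e) NULL)
  gradecmp <- tryCatch(grade_stratified_test(d$adta, d$til_grade),
                       adta_error = function(e) NULL)

  cox_rows <- function(fits) {
    do.call(rbind, lapply(names(fits), function(nm) {
      f <- fits[[nm]]
      if (is.null(f)) return(NULL)
      cbind(model = nm, f$table, n_used = f$n_used, n_events = f$n_events)
    }))
  }
  with_staging(out_dir, overwrite, function(dir) {
    km_tab <- do.call(rbind, lapply(names(km), function(g)
      cbind(group = g, km[[g]]$table)))
    at_risk <- do.call(rbind, lapply(names(km), function(g)
      cbind(group = g, km[[g]]$at_risk)))
    utils::write.csv(km_tab, file.path(dir, "km_curves.csv"), row.names = FALSE)
    utils::write.csv(at_risk, file.path(dir, "km_at_risk.csv"), row.names = FALSE)
    utils::write.csv(data.frame(statistic = lr$statistic, df = lr$df,
                                p_value = lr$p_value),
                     file.path(dir, "logrank.csv"), row.names = FALSE)
    utils::write.csv(cox_rows(uni), file.path(dir, "cox_univariable.csv"),
                     row.names = FALSE)
    utils::write.csv(cox_rows(multi), file.path(dir, "cox_multivariable.csv"),
                     row.names = FALSE)
    assoc_df <- data.frame(
      measure = c("spearman_rho", "spearman_p", "grade_test_statistic",
                  "grade_test_p"),
      value = c(assoc$rho %||% NA, assoc$p_value %||% NA,
                gradecmp$statistic %||% NA, gradecmp$p_value %||% NA))
    utils::write.csv(assoc_df, file.path(dir, "association.csv"),
                     row.names = FALSE)
    utils::write.csv(d[c("patient_id", "adta", "risk_class")],
                     file.path(dir, "risk_classes.csv"), row.names = FALSE)
    write_manifest(dir, "validate",
                   list(cutoff = cutoff, report_times = report_times),
                   inputs = c(scores_csv, clinical_csv,
                              if (!is.null(cutoff_path)) cutoff_path))
  })
  invisible(list(data = d, km = km, logrank = lr, cox_univariable = uni,
                 cox_multivariable = multi, spearman = assoc,
                 grade_comparison = gradecmp, cutoff = cutoff))
}

#' Run a pipeline command from a YAML config
#'
#' Backend of the `adta` command-line script. The config file has one map
#' per stage (`simulate`, `score`, `cutoff`, `validate`) whose keys are the
#' corresponding function's arguments; `overrides` ("stage.key=value"
#' strings) win over file values.
#'
#' @param command One of `"simulate"`, `"score"`, `"cutoff"`, `"validate"`.
#' @param config_file YAML config path.
#' @param overrides Character vector of `stage.key=value` overrides.
#' @return The stage function's return value, invisibly.
#' @export
adta_run <- function(command, config_file, overrides = character()) {
  command <- match.arg(command, c("simulate", "score", "cutoff", "validate"))
  cfg <- yaml::read_yaml(config_file)
  stage <- cfg[[command]] %||% list()
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) abort_format("override must be stage.key=value: %s", ov)
    key <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
    if (length(key) != 2) abort_format("override key must be stage.key: %s", kv[1])
    if (key[1] != command) next
    value <- utils::type.convert(paste(kv[-1], collapse = "="), as.is = TRUE)
    stage[[key[2]]] <- value
  }
  switch(command,
    simulate = {
      sim_args <- stage[setdiff(names(stage), c("out", "overwrite"))]
      sim_args <- lapply(sim_args, function(v) if (is.list(v)) unlist(v) else v)
      adta_simulate(stage$out %||% abort_format("simulate.out is required"),
                    config = do.call(sim_config, sim_args),
                    overwrite = isTRUE(stage$overwrite))
    },
    score = {
      cfg_args <- stage[intersect(names(stage),
                                  names(formals(scoring_config)))]
      adta_score(stage$`in` %||% abort_format("score.in is required"),
                 stage$out %||% abort_format("score.out is required"),
                 config = do.call(scoring_config, cfg_args),
                 overwrite = isTRUE(stage$overwrite))
    },
    cutoff = adta_cutoff(
      stage$scores %||% abort_format("cutoff.scores is required"),
      stage$clinical %||% abort_format("cutoff.clinical is required"),
      stage$out %||% abort_format("cutoff.out is required"),
      criterion = stage$criterion %||% "youden",
      overwrite = isTRUE(stage$overwrite)),
    validate = adta_validate(
      stage$scores %||% abort_format("validate.scores is required"),
      stage$clinical %||% abort_format("validate.clinical is required"),
      stage$cutoff %||% abort_format("validate.cutoff is required"),
      stage$out %||% abort_format("validate.out is required"),
      report_times = unlist(stage$report_times %||% c(0, 100)),
      overwrite = isTRUE(stage$overwrite)))
}
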