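# Agreement between ADTA scores and ordinal pathologist TIL grading
# (0 absent, 1 non-brisk, 2 brisk): Spearman rank correlation and a
# grade-stratified omnibus comparison of score distributions.

#' Spearman correlation of ADTA score with TIL grade
#'
#' rho is the Pearson correlation of mid-ranks (average ranks for ties);
#' the p value uses the t approximation. Pairs with a missing score or
#' grade are dropped.
#'
#' @param adta Per-patient ADTA scores.
#' @param grade Ordinal TIL grade (0/1/2).
#' @return Object of class `spearman_result`: list with `rho`, `p_value`,
#'   `n`.
#' @export
spearman_grade <- function(adta, grade) {
  keep <- !is.na(adta) & !is.na(grade)
  adta <- adta[keep]; grade <- grade[keep]
  n <- length(adta)
  if (n < 3) abort_validation("need at least 3 complete (score, grade) pairs")
  if (stats::var(rank(adta)) == 0 || stats::var(rank(grade)) == 0)
    abort_validation("zero rank variance")
  ct <- suppressWarnings(
    stats::cor.test(adta, grade, method = "spearman", exact = FALSE))
  structure(list(rho = unname(ct$estimate), p_value = ct$p.value, n = n),
            class = "spearman_result")
}

#' Compare ADTA score distributions across TIL grades
#'
#' Omnibus test that scores differ across the grade strata. Default is the
#' tie-corrected Kruskal-Wallis H (scores are bounded skewed fractions and
#' grades are ordinal groups); a one-way ANOVA alternative is available.
#' Degenerate input where every score is identical yields H = 0, p = 1.
#'
#' @param adta Per-patient ADTA scores.
#' @param grade Ordinal TIL grade.
#' @param method `"kruskal"` (default) or `"anova"`.
#' @return Object of class `grade_comparison`: list with `statistic`, `df`,
#'   `p_value`, `method`, `summaries` (data.frame per grade: grade, n,
#'   median, q1, q3).
#' @export
grade_stratified_test <- function(adta, grade, method = c("kruskal", "anova")) {
  method <- match.arg(method)
  keep <- !is.na(adta) & !is.na(grade)
  adta <- adta[keep]; grade <- factor(grade[keep])
  grade <- droplevels(grade)
  counts <- table(grade)
  if (sum(counts >= 2) < 2 || nlevels(grade) < 2)
    abort_validation("need at least 2 grades with at least 2 patients each")
  summaries <- do.call(rbind, lapply(levels(grade), function(g) {
    v <- adta[grade == g]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(grade = g, n = length(v), median = q[2], q1 = q[1], q3 = q[3])
  }))
  if (method == "kruskal") {
    if (length(unique(adta)) == 1) {            # all tied: H defined as 0
      stat <- 0; df <- nlevels(grade) - 1; p <- 1
    } else {
      kt <- stats::kruskal.test(adta, grade)
      stat <- unname(kt$statistic); df <- unname(kt$parameter); p <- kt$p.value
    }
  } else {
    ft <- stats::oneway.test(adta ~ grade, var.equal = TRUE)
    stat <- unname(ft$statistic); df <- unname(ft$parameter[1]); p <- ft$p.value
  }
  structure(list(statistic = stat, df = df, p_value = p, method = method,
                 summaries = summaries),
            class = "grade_comparison")
}

#' @export
print.spearman_result <- function(x, ...) {
  cat(sprintf("<spearman_result> rho = %.3f, p = %.4g, n = %d\n",
              x$rho, x$p_value, x$n))
  invisible(x)
}

#' @export
print.grade_comparison <- function(x, ...) {
  cat(sprintf("<grade_comparison> %s: statistic = %.4f (%g df), p = %.4g\n",
              x$method, x$statistic, x$df, x$p_value))
  invisible(x)
}
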