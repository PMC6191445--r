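# Statistical comparisons used for thrombosis and bleeding-time data:
# Student/Welch t-test with variance-based selection, Mann-Whitney U with
# censoring at a cap, one-way ANOVA with Tukey HSD, and the platelet-count
# inclusion filter.

new_stat_result <- function(test_name, statistic, p_value, n, notes = character()) {
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, n = n, notes = notes),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(x$test_name, "\n")
  cat(sprintf("  statistic = %.6g, p = %.6g (two-sided), n = %s\n",
              x$statistic, x$p_value, paste(x$n, collapse = "/")))
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}

#' Significance stars
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `n.s.`
#' otherwise.
#'
#' @param p P-value(s).
#' @return Character vector of stars.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "n.s.")))
}

#' Two-sample t-test with variance-based mode selection
#'
#' In `auto` mode an F-test of variance equality at alpha = 0.05 selects
#' between Student's t-test (equal variances) and Welch's t-test (unequal
#' variances); the chosen mode is recorded in the notes. Two-sided.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param mode `"auto"` (default), `"student"` or `"welch"`.
#' @return A `stat_result`.
#' @export
two_sample_test <- function(a, b, mode = c("auto", "student", "welch")) {
  mode <- match.arg(mode)
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  notes <- character()
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(new_stat_result("Student t-test", 0, 1,
                             c(length(a), length(b)),
                             "zero variance in both groups with equal means: p = 1"))
    return(new_stat_result("Student t-test", Inf, 0,
                           c(length(a), length(b)),
                           "zero variance in both groups with different means"))
  }
  if (mode == "auto") {
    f <- stats::var.test(a, b)
    equal <- f$p.value >= 0.05
    mode <- if (equal) "student" else "welch"
    notes <- c(notes, sprintf(
      "auto mode: F-test of equal variances p = %.4g at alpha = 0.05 -> %s",
      f$p.value, if (equal) "Student" else "Welch"))
  }
  tt <- stats::t.test(a, b, var.equal = (mode == "student"))
  new_stat_result(if (mode == "student") "Student t-test" else "Welch t-test",
                  unname(tt$statistic), tt$p.value,
                  c(length(a), length(b)), notes)
}

#' Mann-Whitney U test with optional censoring cap
#'
#' Observations at or above `cap` (e.g. bleeding assays stopped at 15 min)
#' are set to the cap and treated as ties there (midranks), preserving
#' their rank information. The p-value is exact (equivalent to full
#' enumeration of all group assignments) when `n_a + n_b <= 12` and there
#' are no ties, and otherwise uses the normal approximation with tie
#' correction; the method is recorded in the notes.
#'
#' @param a,b Numeric samples (non-empty; exact p needs n >= 3 per group).
#' @param cap Optional censoring value; must be >= every observation.
#' @return A `stat_result` with the U statistic for group `a`.
#' @export
mann_whitney <- function(a, b, cap = NULL) {
  if (length(a) < 1 || length(b) < 1) stop("both groups must be non-empty")
  notes <- character()
  if (!is.null(cap)) {
    if (cap < max(c(a, b))) stop("cap must be >= every observed value")
    ncens <- sum(c(a, b) == cap)
    if (ncens > 0)
      notes <- c(notes, sprintf(
        "%d observation(s) censored at cap = %g treated as ties at the cap",
        ncens, cap))
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b) <= 12) && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  notes <- c(notes, if (exact) "exact p by enumeration of all assignments"
             else "normal approximation with tie correction")
  if (ties) notes <- c(notes, "ties present (midranks)")
  new_stat_result("Mann-Whitney U test", unname(wt$statistic), wt$p.value,
                  c(length(a), length(b)), notes)
}

#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' @param groups Named list of >= 3 numeric samples, each of length >= 2.
#' @return List with `anova` (a `stat_result` for the F-test) and
#'   `pairwise` (data.frame with Tukey-adjusted and unadjusted pairwise
#'   p-values, mean differences and significance stars).
#' @export
anova_tukey <- function(groups) {
  if (!is.list(groups) || length(groups) < 3)
    stop("need at least 3 groups; for two groups use two_sample_test()")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs n >= 2")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(names(groups),
                                      vapply(groups, length, integer(1)))))
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  fres <- new_stat_result("one-way ANOVA", an$`F value`[1], an$`Pr(>F)`[1],
                          vapply(groups, length, integer(1)))
  tk <- stats::TukeyHSD(fit)$group
  mse <- an$`Mean Sq`[2]
  dfe <- an$Df[2]
  pairs <- rownames(tk)
  unadj <- vapply(pairs, function(p) {
    gs <- strsplit(p, "-", fixed = TRUE)[[1]]
    n1 <- length(groups[[gs[1]]]); n2 <- length(groups[[gs[2]]])
    se <- sqrt(mse * (1 / n1 + 1 / n2))
    2 * stats::pt(abs(tk[p, "diff"]) / se, dfe, lower.tail = FALSE)
  }, numeric(1))
  pairwise <- data.frame(comparison = pairs, diff = tk[, "diff"],
                         lwr = tk[, "lwr"], upr = tk[, "upr"],
                         p_adj = tk[, "p adj"], p_unadj = unadj,
                         stars = significance_stars(tk[, "p adj"]))
  rownames(pairwise) <- NULL
  list(anova = fres, pairwise = pairwise)
}

#' Platelet-count inclusion filter
#'
#' Animals are included only when their platelet count lies in the normal
#' range (inclusive bounds; reference range 800-1300 x 10^6 per mL).
#'
#' @param counts Platelet counts in 10^6 per mL (>= 0).
#' @param lower,upper Inclusive bounds of the normal range.
#' @return Logical vector: `TRUE` = keep, `FALSE` = drop.
#' @export
inclusion_filter <- function(counts, lower = 800, upper = 1300) {
  if (any(counts < 0)) stop("platelet counts must be >= 0")
  counts >= lower & counts <= upper
}
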