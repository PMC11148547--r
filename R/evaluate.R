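# Discrimination and association statistics: Mann-Whitney AUC with DeLong
# confidence intervals, Wilcoxon rank tests, and dose-response correlation.

split_classes <- function(scores, labels) {
  labels <- as.logical(labels)
  if (anyNA(labels)) stop("labels must be TRUE (case) / FALSE (control)")
  cases <- scores[labels]; controls <- scores[!labels]
  if (length(cases) == 0 || length(controls) == 0)
    stop("both classes must be present")
  list(cases = cases, controls = controls)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Fraction of (case, control) pairs in which the case scores higher, ties
#' counting one half.
#'
#' @param scores numeric scores.
#' @param labels logical (or coercible) vector, `TRUE` = case.
#' @return AUC in \[0,1\].
#' @export
auc <- function(scores, labels) {
  cl <- split_classes(scores, labels)
  n1 <- length(cl$cases); n0 <- length(cl$controls)
  r <- rank(c(cl$cases, cl$controls))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' DeLong confidence interval for the AUC
#'
#' Variance from DeLong's structural components: the per-case placement
#' values (fraction of controls each case beats) and per-control placement
#' values. Normal-theory interval on the AUC scale, clipped to \[0,1\].
#'
#' @inheritParams auc
#' @param level confidence level.
#' @return data frame `auc, ci_low, ci_high, se, n_case, n_control`.
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  cl <- split_classes(scores, labels)
  m <- length(cl$cases); n <- length(cl$controls)
  if (m < 2 || n < 2) stop("need at least 2 samples per class")
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  # placement values via the rank trick (O((m+n) log(m+n)))
  r_all <- rank(c(cl$cases, cl$controls))
  v10 <- (r_all[seq_len(m)] - rank(cl$cases)) / n          # per-case
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(cl$controls)) / m  # per-control
  a <- mean(v10)
  s <- stats::var(v10) / m + stats::var(v01) / n
  if (s <= 0) {
    warning("degenerate DeLong variance (AUC exactly 0 or 1); CI collapses")
    s <- 0
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(auc = a, ci_low = max(0, a - z * sqrt(s)),
             ci_high = min(1, a + z * sqrt(s)), se = sqrt(s),
             n_case = m, n_control = n)
}

#' Wilcoxon rank test
#'
#' Unpaired: two-sided rank-sum test; paired: two-sided signed-rank test.
#' Exact null enumeration is used for small untied samples (fewer than 10
#' per group), the normal approximation with tie correction otherwise.
#' Identical paired samples return p = 1 by convention.
#'
#' @param x,y numeric samples.
#' @param paired paired test?
#' @return two-sided p-value.
#' @export
rank_test <- function(x, y, paired = FALSE) {
  if (paired) {
    if (length(x) != length(y)) stop("paired samples must have equal length")
    if (all(x == y)) return(1)
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && min(length(x), length(y)) < 10
  suppressWarnings(
    stats::wilcox.test(x, y, paired = paired, exact = exact,
                       correct = !exact)$p.value)
}

#' Dose-response correlation of scores with pack-years
#'
#' Spearman rank correlation by default (no linearity assumption); Pearson
#' available. Incomplete pairs are dropped.
#'
#' @param scores numeric scores.
#' @param pack_years cumulative smoking dose per sample.
#' @param method `"spearman"` or `"pearson"`.
#' @return list with `r`, `p`, and `n` complete pairs.
#' @export
dose_correlation <- function(scores, pack_years,
                             method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ok <- !is.na(scores) & !is.na(pack_years)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  x <- scores[ok]; y <- pack_years[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in scores or pack_years")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Evaluate group discrimination of a score table
#'
#' For each CpG set and each requested comparison (pair of types), reports
#' the raw- and corrected-score AUC with DeLong confidence intervals and the
#' unpaired Wilcoxon p-value. The first type of each pair is the case class.
#'
#' @param score_tab output of [score_table()].
#' @param comparisons list of length-2 character vectors, e.g.
#'   `list(c("current", "never"))`.
#' @return data frame with one row per set x comparison.
#' @export
evaluate_scores <- function(score_tab,
                            comparisons = list(c("current", "never"))) {
  out <- list()
  for (nm in unique(score_tab$set)) {
    st <- score_tab[score_tab$set == nm, , drop = FALSE]
    for (cmp in comparisons) {
      sub <- st[st$type %in% cmp, , drop = FALSE]
      lab <- sub$type == cmp[1]
      raw_ci <- delong_ci(sub$raw, lab)
      row <- data.frame(set = nm, comparison = paste(cmp, collapse = "_vs_"),
                        auc = raw_ci$auc, ci_low = raw_ci$ci_low,
                        ci_high = raw_ci$ci_high,
                        auc_corrected = NA_real_,
                        p_wilcoxon = rank_test(sub$raw[lab], sub$raw[!lab]),
                        n_case = raw_ci$n_case, n_control = raw_ci$n_control,
                        stringsAsFactors = FALSE)
      if (!all(is.na(sub$corrected)))
        row$auc_corrected <- auc(sub$corrected, lab)
      out[[paste(nm, row$comparison)]] <- row
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
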