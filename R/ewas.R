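# Per-CpG association of methylation with current smoking, adjusted for age
# and cell composition, with Holm-Bonferroni family-wise error control.

# Vectorised OLS of every row of Y on a shared design X.
# Returns coefficients (rows of Y x columns of X), their SEs, residual df.
ols_rows <- function(Y, X) {
  n <- ncol(Y); p <- ncol(X)
  if (nrow(X) != n) stop("design/response dimension mismatch")
  qrx <- qr(X)
  if (qrx$rank < p) stop("design matrix is rank-deficient")
  XtXinv <- chol2inv(qr.R(qrx))
  B <- Y %*% X %*% XtXinv                     # rows x p
  res <- Y - B %*% t(X)
  df <- n - p
  s2 <- rowSums(res^2) / df
  SE <- sqrt(outer(s2, diag(XtXinv)))
  list(coef = B, se = SE, df = df, sigma2 = s2, XtXinv = XtXinv)
}

#' Per-CpG smoking association model
#'
#' Ordinary least squares of a CpG's beta values on a current-vs-never
#' smoking indicator, age, and a cell-composition covariate (immune cell
#' proportion in buccal/cervical samples; lymphoid proportion in blood).
#' Returns the smoking-indicator coefficient with a two-sided p-value from
#' the t distribution on the residual degrees of freedom.
#'
#' @param beta_row named numeric vector of beta values (names = sample ids).
#' @param sheet sample sheet covering those samples (never/current rows used).
#' @param fractions cell-fraction data frame with the composition covariate.
#' @param composition_covariate `"immune_proportion"` or
#'   `"lymphoid_proportion"`.
#' @param min_group minimum samples required per smoking group.
#' @return list with `effect`, `se`, `p`, `n` and a `constant` flag.
#' @export
fit_cpg <- function(beta_row, sheet, fractions,
                    composition_covariate = c("immune_proportion",
                                              "lymphoid_proportion"),
                    min_group = 10) {
  composition_covariate <- match.arg(composition_covariate)
  d <- ewas_design(sheet, fractions, composition_covariate, min_group)
  y <- beta_row[d$ids]
  ok <- !is.na(y)
  y <- y[ok]; X <- d$X[ok, , drop = FALSE]
  if (length(unique(y)) == 1)
    return(list(effect = 0, se = NA_real_, p = 1, n = length(y),
                constant = TRUE))
  check_collinearity(X)
  fit <- ols_rows(matrix(y, nrow = 1), X)
  tval <- fit$coef[1, 2] / fit$se[1, 2]
  list(effect = unname(fit$coef[1, 2]), se = unname(fit$se[1, 2]),
       p = 2 * stats::pt(-abs(tval), fit$df), n = length(y), constant = FALSE)
}

ewas_design <- function(sheet, fractions, composition_covariate, min_group) {
  keep <- sheet$smoking_type %in% c("never", "current")
  sheet <- sheet[keep, , drop = FALSE]
  counts <- table(factor(sheet$smoking_type, c("never", "current")))
  if (any(counts < min_group))
    stop("need at least ", min_group, " samples per smoking group (have ",
         counts[["never"]], " never, ", counts[["current"]], " current)")
  f <- fractions[[composition_covariate]][match(sheet$sample_id,
                                                fractions$sample_id)]
  if (anyNA(f))
    stop("missing ", composition_covariate, " for ",
         sum(is.na(f)), " sample(s)")
  X <- cbind(intercept = 1,
             current = as.numeric(sheet$smoking_type == "current"),
             age = sheet$age, composition = f)
  list(X = X, ids = sheet$sample_id)
}

check_collinearity <- function(X) {
  if (qr(X)$rank == ncol(X)) return(invisible(TRUE))
  cn <- colnames(X)[-1]
  cc <- abs(stats::cor(X[, -1, drop = FALSE]))
  diag(cc) <- 0
  w <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  stop("collinear covariates: ", cn[w[1]], " and ", cn[w[2]])
}

#' Run an EWAS over all CpGs of one tissue
#'
#' Applies [fit_cpg()]'s model to every row of the beta matrix (vectorised
#' over CpGs with identical complete designs; rows with missing betas are
#' fitted individually on complete cases) and Holm-adjusts the p-values
#' across all CpGs tested in the tissue. Ex-smokers are excluded: discovery
#' contrasts current against never smokers only.
#'
#' @param beta CpG x sample beta matrix.
#' @param sheet sample sheet.
#' @param fractions cell fractions with the composition covariate.
#' @param tissue tissue label; rows of `sheet` are filtered to it. Blood uses
#'   the lymphoid proportion as composition covariate, other tissues the
#'   immune proportion (overridable via `composition_covariate`).
#' @param composition_covariate covariate column; default chosen from tissue.
#' @param min_group minimum samples per smoking group.
#' @return data frame `cpg_id, tissue, effect, se, p, p_holm, n, constant`,
#'   with the genomic-inflation factor (median chi-square ratio) attached as
#'   attribute `lambda`.
#' @export
run_ewas <- function(beta, sheet, fractions, tissue,
                     composition_covariate = NULL, min_group = 10) {
  sheet <- sheet[sheet$tissue == tissue, , drop = FALSE]
  if (is.null(composition_covariate))
    composition_covariate <- if (tissue == "blood") "lymphoid_proportion"
                             else "immune_proportion"
  d <- ewas_design(sheet, fractions, composition_covariate, min_group)
  miss <- setdiff(d$ids, colnames(beta))
  if (length(miss) > 0)
    stop("sample(s) in sheet absent from beta matrix: ",
         paste(utils::head(miss, 3), collapse = ", "))
  Y <- beta[, d$ids, drop = FALSE]
  n_cpg <- nrow(Y)
  out <- data.frame(cpg_id = rownames(Y), tissue = tissue,
                    effect = NA_real_, se = NA_real_, p = NA_real_,
                    n = NA_integer_, constant = FALSE,
                    stringsAsFactors = FALSE)
  complete <- !apply(Y, 1, anyNA)
  const <- apply(Y, 1, function(r) length(unique(r[!is.na(r)])) == 1)
  vec <- complete & !const
  if (any(vec)) {
    check_collinearity(d$X)
    fit <- ols_rows(Y[vec, , drop = FALSE], d$X)
    tval <- fit$coef[, 2] / fit$se[, 2]
    out$effect[vec] <- fit$coef[, 2]
    out$se[vec] <- fit$se[, 2]
    out$p[vec] <- 2 * stats::pt(-abs(tval), fit$df)
    out$n[vec] <- ncol(Y)
  }
  out$effect[const] <- 0; out$p[const] <- 1
  out$n[const] <- rowSums(!is.na(Y[const, , drop = FALSE]))
  out$constant[const] <- TRUE
  for (i in which(!complete & !const)) {
    res <- tryCatch(fit_cpg(Y[i, ], sheet, fractions, composition_covariate,
                            min_group),
                    error = function(e) {
                      warning("CpG ", rownames(Y)[i], " failed: ",
                              conditionMessage(e))
                      NULL
                    })
    if (!is.null(res)) {
      out$effect[i] <- res$effect; out$se[i] <- res$se; out$p[i] <- res$p
      out$n[i] <- res$n; out$constant[i] <- res$constant
    }
  }
  tested <- !is.na(out$p)
  out$p_holm <- NA_real_
  out$p_holm[tested] <- holm_adjust(out$p[tested])
  chi <- (out$effect / out$se)^2
  attr(out, "lambda") <- stats::median(chi, na.rm = TRUE) /
    stats::qchisq(0.5, df = 1)
  out
}

#' Holm-Bonferroni step-down adjustment
#'
#' Step-down Holm adjustment with enforced monotonicity, capped at 1;
#' controls the family-wise error rate at the nominal level without any
#' independence assumption. With m tests, the smallest rejection threshold
#' at level alpha is alpha/m.
#'
#' @param pvals numeric vector of p-values in \[0,1\]; `NA`/`NaN` rejected.
#' @return adjusted p-values, same order as the input.
#' @export
holm_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (anyNA(pvals)) stop("NA/NaN p-values are not allowed")
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0,1]")
  stats::p.adjust(pvals, method = "holm")
}

#' Union of significant CpGs across tissues, with sex-chromosome filtering
#'
#' A CpG is retained when its Holm-adjusted p-value is below `alpha` in at
#' least one tissue. When a chromosome annotation is supplied, CpGs on the X
#' or Y chromosome are removed; annotated-but-missing CpGs are kept with a
#' warning.
#'
#' @param results one EWAS result data frame or a list of them (one per
#'   tissue).
#' @param alpha family-wise significance level.
#' @param annotation optional named chromosome vector from
#'   [read_annotation()].
#' @return character vector of significant CpG ids (sorted).
#' @export
significant_sites <- function(results, alpha = 0.05, annotation = NULL) {
  if (is.data.frame(results)) results <- list(results)
  hits <- unique(unlist(lapply(results, function(r)
    r$cpg_id[!is.na(r$p_holm) & r$p_holm < alpha])))
  if (!is.null(annotation)) {
    chr <- annotation[hits]
    unknown <- hits[is.na(chr)]
    if (length(unknown) > 0)
      warning(length(unknown), " significant CpG(s) missing from the ",
              "annotation were retained")
    sex <- !is.na(chr) & sub("^chr", "", chr) %in% c("X", "Y")
    hits <- hits[!sex]
  }
  sort(hits)
}
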