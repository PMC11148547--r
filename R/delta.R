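# Compartment-specific smoking effects by intercept extrapolation: fit
# group-wise lines of beta against the composition fraction f, then read off
# differences at f = 0 (pure epithelial / myeloid) and f = 1 (pure immune /
# lymphoid).

#' Canonical delta-beta column order
#'
#' @return the fixed six-column order of the cross-tissue delta-beta feature
#'   matrix: epithelial and immune effects in buccal, epithelial and immune
#'   in cervical, lymphoid and myeloid in blood.
#' @export
delta_column_names <- function() {
  c("delta_epi_buccal", "delta_imm_buccal",
    "delta_epi_cervical", "delta_imm_cervical",
    "delta_lymphoid_blood", "delta_myeloid_blood")
}

#' Fit per-group regression lines of beta on composition
#'
#' One unweighted least-squares line `beta ~ f` per group (e.g. never and
#' current smokers fitted separately). Extrapolation to pure compartments is
#' statistically fragile on small or narrow designs, so each group must have
#' at least `min_n` samples and an f range of at least `spread_min`.
#'
#' @param y numeric vector of beta values for one CpG.
#' @param f composition fraction per sample (immune or lymphoid proportion).
#' @param groups group label per sample.
#' @param min_n minimum samples per group.
#' @param spread_min minimum per-group range of `f`.
#' @return named list of group lines: `intercept`, `slope`, `n`,
#'   `residual_sd`, and the coefficient covariance entries needed for
#'   intercept-at-f standard errors.
#' @export
fit_group_lines <- function(y, f, groups, min_n = 20, spread_min = 0.2) {
  stopifnot(length(y) == length(f), length(f) == length(groups))
  ok <- !is.na(y) & !is.na(f) & !is.na(groups)
  y <- y[ok]; f <- f[ok]; groups <- as.character(groups[ok])
  out <- list()
  for (g in unique(groups)) {
    idx <- groups == g
    if (sum(idx) < min_n)
      stop("group '", g, "' has ", sum(idx), " samples; need >= ", min_n)
    fg <- f[idx]
    if (diff(range(fg)) < spread_min)
      stop("composition range too narrow for extrapolation in group '", g,
           "' (spread ", signif(diff(range(fg)), 3), " < ", spread_min, ")")
    X <- cbind(1, fg)
    fit <- ols_rows(matrix(y[idx], nrow = 1), X)
    out[[g]] <- list(intercept = unname(fit$coef[1, 1]),
                     slope = unname(fit$coef[1, 2]),
                     n = sum(idx),
                     residual_sd = sqrt(fit$sigma2[1]),
                     vcov = fit$sigma2[1] * fit$XtXinv)
  }
  out
}

line_at <- function(line, at) {
  v <- c(1, at)
  list(value = line$intercept + at * line$slope,
       se = sqrt(drop(t(v) %*% line$vcov %*% v)))
}

#' Compartment-specific delta-beta between two smoking groups
#'
#' Fits group-wise lines of beta on `f` and returns the difference of their
#' extrapolated values at `at = 0` (the pure compartment with f = 0) or
#' `at = 1` (the pure compartment with f = 1):
#' `delta(0) = intercept_current - intercept_never`,
#' `delta(1) = (intercept + slope)_current - (intercept + slope)_never`.
#'
#' @inheritParams fit_group_lines
#' @param current,never labels of the two contrasted groups.
#' @param at extrapolation point, 0 or 1.
#' @return list with `delta`, `se` (quadrature of the two group SEs) and the
#'   fitted `lines`.
#' @export
delta_beta <- function(y, f, groups, current = "current", never = "never",
                       at = 0, min_n = 20, spread_min = 0.2) {
  stopifnot(at %in% c(0, 1))
  keep <- groups %in% c(current, never)
  lines <- fit_group_lines(y[keep], f[keep], groups[keep], min_n, spread_min)
  if (!all(c(current, never) %in% names(lines)))
    stop("both groups must be present: ", current, ", ", never)
  a <- line_at(lines[[current]], at)
  b <- line_at(lines[[never]], at)
  list(delta = a$value - b$value, se = sqrt(a$se^2 + b$se^2), lines = lines)
}

# Vectorised group-line fits for all CpGs of one tissue. Returns, for each
# extrapolation point, the matrix of per-CpG deltas and SEs.
delta_rows <- function(Y, f, groups, current, never, min_n, spread_min) {
  res <- list()
  for (g in c(never, current)) {
    idx <- which(groups == g)
    if (length(idx) < min_n)
      stop("group '", g, "' has ", length(idx), " samples; need >= ", min_n)
    fg <- f[idx]
    if (diff(range(fg)) < spread_min)
      stop("composition range too narrow for extrapolation in group '", g, "'")
    X <- cbind(1, fg)
    fit <- ols_rows(Y[, idx, drop = FALSE], X)
    for (at in c(0, 1)) {
      v <- c(1, at)
      res[[paste(g, at)]] <- list(
        value = drop(fit$coef %*% v),
        var = fit$sigma2 * drop(t(v) %*% fit$XtXinv %*% v))
    }
  }
  out <- list()
  for (at in c(0, 1)) {
    a <- res[[paste(current, at)]]; b <- res[[paste(never, at)]]
    out[[as.character(at)]] <- list(delta = a$value - b$value,
                                    se = sqrt(a$var + b$var))
  }
  out
}

#' Assemble the cross-tissue delta-beta feature matrix
#'
#' For each CpG in `cpg_ids` and each available tissue, fits never/current
#' lines of beta on the tissue's composition fraction and extrapolates:
#' buccal and cervical use the immune proportion (f = 0 epithelial, f = 1
#' immune); blood uses the lymphoid proportion (f = 1 lymphoid, f = 0
#' myeloid). Missing tissues yield NA columns.
#'
#' @param beta_list named list of CpG x sample beta matrices per tissue.
#' @param sheet_list named list of sample sheets per tissue.
#' @param fractions_list named list of cell-fraction data frames per tissue.
#' @param cpg_ids CpGs to include (rows of the output).
#' @param min_n,spread_min per-group design requirements, see
#'   [fit_group_lines()].
#' @return an `smk_delta_matrix`: CpG x 6 matrix in the canonical
#'   [delta_column_names()] order, with the per-entry standard errors in
#'   attribute `se`.
#' @export
build_delta_matrix <- function(beta_list, sheet_list, fractions_list, cpg_ids,
                               min_n = 20, spread_min = 0.2) {
  if (length(cpg_ids) == 0) stop("cpg_ids is empty")
  if (length(beta_list) == 0) stop("at least one tissue is required")
  cols <- delta_column_names()
  D <- matrix(NA_real_, length(cpg_ids), 6, dimnames = list(cpg_ids, cols))
  SE <- D
  plan <- list(
    buccal = list(cov = "immune_proportion",
                  at0 = "delta_epi_buccal", at1 = "delta_imm_buccal"),
    cervical = list(cov = "immune_proportion",
                    at0 = "delta_epi_cervical", at1 = "delta_imm_cervical"),
    blood = list(cov = "lymphoid_proportion",
                 at0 = "delta_myeloid_blood", at1 = "delta_lymphoid_blood"))
  for (tissue in intersect(names(plan), names(beta_list))) {
    p <- plan[[tissue]]
    beta <- beta_list[[tissue]]
    sheet <- sheet_list[[tissue]]
    fr <- fractions_list[[tissue]]
    present <- intersect(cpg_ids, rownames(beta))
    if (length(present) == 0) next
    keep <- sheet$smoking_type %in% c("never", "current")
    ids <- sheet$sample_id[keep]
    f <- fr[[p$cov]][match(ids, fr$sample_id)]
    if (anyNA(f)) stop("missing ", p$cov, " for tissue ", tissue)
    Y <- beta[present, ids, drop = FALSE]
    grp <- sheet$smoking_type[keep]
    complete <- !apply(Y, 1, anyNA)
    if (any(complete)) {
      res <- delta_rows(Y[complete, , drop = FALSE], f, grp,
                        "current", "never", min_n, spread_min)
      D[present[complete], p$at0] <- res[["0"]]$delta
      SE[present[complete], p$at0] <- res[["0"]]$se
      D[present[complete], p$at1] <- res[["1"]]$delta
      SE[present[complete], p$at1] <- res[["1"]]$se
    }
    for (cpg in present[!complete]) {
      for (at in c(0, 1)) {
        cn <- if (at == 0) p$at0 else p$at1
        res <- tryCatch(delta_beta(Y[cpg, ], f, grp, at = at, min_n = min_n,
                                   spread_min = spread_min),
                        error = function(e) NULL)
        if (!is.null(res)) {
          D[cpg, cn] <- res$delta; SE[cpg, cn] <- res$se
        }
      }
    }
  }
  attr(D, "se") <- SE
  class(D) <- c("smk_delta_matrix", class(D))
  D
}
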