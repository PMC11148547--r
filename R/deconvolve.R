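# Reference-based cell-type deconvolution. Per sample we solve a
# non-negative least-squares problem against the compartment reference
# profiles and renormalise the weights to sum to one.

#' Estimate per-sample compartment fractions from bulk beta values
#'
#' For each sample, solves `min || b - R w ||^2` subject to `w >= 0` over the
#' CpGs shared between the bulk matrix and the reference, then normalises `w`
#' to sum to one. Derived columns are added when recognisable: an `immune`
#' compartment yields `immune_proportion` (immune over all reference
#' compartments), a `lymphoid`/`myeloid` reference yields
#' `lymphoid_proportion`.
#'
#' @param beta CpG x sample matrix of beta values.
#' @param ref CpG x compartment reference matrix (mean beta per compartment).
#' @param warn_below warn when fewer shared CpGs than this remain.
#' @return data frame: `sample_id`, one column per reference compartment, and
#'   derived proportion columns.
#' @export
estimate_fractions <- function(beta, ref, warn_below = 30) {
  shared <- intersect(rownames(beta), rownames(ref))
  if (length(shared) == 0)
    stop("no CpGs shared between beta matrix and reference")
  if (length(shared) < warn_below)
    warning("only ", length(shared), " CpGs shared with the reference; ",
            "fraction estimates may be unstable")
  R <- as.matrix(ref[shared, , drop = FALSE])
  if (ncol(R) < 2) stop("reference must contain at least 2 compartments")
  if (qr(R)$rank < ncol(R))
    stop("reference matrix is rank-deficient on the shared CpGs")
  B <- beta[shared, , drop = FALSE]
  W <- matrix(NA_real_, ncol(B), ncol(R),
              dimnames = list(colnames(B), colnames(R)))
  for (j in seq_len(ncol(B))) {
    b <- B[, j]
    ok <- !is.na(b)
    if (sum(ok) < ncol(R))
      stop("sample ", colnames(B)[j], " has fewer non-missing shared CpGs ",
           "than reference compartments")
    w <- pracma::lsqnonneg(R[ok, , drop = FALSE], b[ok])$x
    s <- sum(w)
    if (s <= 0) {
      warning("all weights collapsed to zero for sample ", colnames(B)[j],
              "; returning uniform fractions")
      w <- rep(1 / ncol(R), ncol(R)); s <- 1
    }
    W[j, ] <- w / s
  }
  out <- data.frame(sample_id = rownames(W), W,
                    check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  add_derived_proportions(out)
}

# Rescale rule of the two-level estimator: subtype fractions (summing to 1
# within the immune compartment) are multiplied by the level-1 immune
# fraction, so they sum to it.
rescale_subtypes <- function(raw, immune_fraction) {
  raw * immune_fraction
}

add_derived_proportions <- function(fr) {
  if ("immune" %in% names(fr) && !"immune_proportion" %in% names(fr))
    fr$immune_proportion <- fr$immune
  if (all(c("lymphoid", "myeloid") %in% names(fr)) &&
      !"lymphoid_proportion" %in% names(fr))
    fr$lymphoid_proportion <- 1 - fr$myeloid
  fr
}

#' Aggregate blood immune subtypes into myeloid and lymphoid lineages
#'
#' Monocytes, neutrophils and eosinophils are grouped as the myeloid lineage;
#' the lymphoid proportion is defined as one minus the myeloid proportion.
#'
#' @param fractions data frame with subtype columns `mono`, `neutro`,
#'   `eosino` (plus any others).
#' @return `fractions` with added `myeloid`, `lymphoid` and
#'   `lymphoid_proportion` columns.
#' @export
aggregate_lineages <- function(fractions) {
  need <- c("mono", "neutro", "eosino")
  miss <- setdiff(need, names(fractions))
  if (length(miss) > 0)
    stop("missing myeloid constituent subtype(s): ", paste(miss, collapse = ", "))
  fractions$myeloid <- rowSums(fractions[, need, drop = FALSE])
  fractions$lymphoid <- 1 - fractions$myeloid
  fractions$lymphoid_proportion <- fractions$lymphoid
  fractions
}

#' Two-level (hierarchical) fraction estimation
#'
#' First estimates tissue-level compartments against `ref_level1` (which must
#' contain an immune compartment), then estimates immune-subtype proportions
#' against `ref_level2` and rescales them so the subtypes sum to the
#' level-1 immune fraction of each sample.
#'
#' @param beta CpG x sample beta matrix.
#' @param ref_level1 tissue-compartment reference (must include a column
#'   named by `immune_compartment`).
#' @param ref_level2 immune-subtype reference.
#' @param immune_compartment level-1 column holding the immune fraction.
#' @return data frame with level-1 non-immune compartments, rescaled subtype
#'   fractions, and `immune_proportion`.
#' @export
hierarchical_fractions <- function(beta, ref_level1, ref_level2,
                                   immune_compartment = "immune") {
  if (!immune_compartment %in% colnames(ref_level1))
    stop("level-1 reference lacks an '", immune_compartment, "' compartment")
  f1 <- estimate_fractions(beta, ref_level1)
  f2 <- estimate_fractions(beta, ref_level2)
  sub_cols <- colnames(ref_level2)
  imm <- f1[[immune_compartment]]
  f2[sub_cols] <- rescale_subtypes(f2[sub_cols], imm)
  out <- cbind(f1[c("sample_id",
                    setdiff(colnames(ref_level1), immune_compartment))],
               f2[sub_cols])
  out$immune_proportion <- imm
  out
}
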