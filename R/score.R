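# Mean methylation scoring of CpG sets and the cell-composition correction:
# per smoking type, a line of score against composition fraction f is
# fitted; each sample's residual from its type's line is added to that
# line's value at the target composition (f = 0 pure epithelial, f = 1 pure
# immune), yielding an estimate of the sample's pure-compartment score.

#' Mean methylation score of a CpG set
#'
#' The per-sample mean beta over the set members present in the matrix;
#' missing values are skipped and the per-sample coverage (fraction of set
#' members contributing) is reported.
#'
#' @param beta CpG x sample beta matrix.
#' @param set a [cpg_set()].
#' @return data frame `sample_id, score, coverage`.
#' @export
mean_score <- function(beta, set) {
  stopifnot(inherits(set, "smk_cpg_set"))
  members <- intersect(set$cpgs, rownames(beta))
  if (length(members) == 0)
    stop("no members of set '", set$name, "' present in the beta matrix")
  sub <- beta[members, , drop = FALSE]
  data.frame(sample_id = colnames(beta),
             score = colMeans(sub, na.rm = TRUE),
             coverage = colSums(!is.na(sub)) / length(set$cpgs),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit the per-type composition-correction model
#'
#' For each smoking/exposure type, fits a least-squares line of the mean
#' methylation score against the composition fraction f. The target f* is
#' taken from the set's compartment: epithelial scores are extrapolated to
#' f* = 0, immune scores to f* = 1.
#'
#' @param scores numeric vector of mean methylation scores.
#' @param f composition fraction per sample.
#' @param types smoking/exposure type per sample.
#' @param target_compartment `"epithelial"` (f* = 0) or `"immune"` (f* = 1).
#' @param min_n minimum samples per type.
#' @param spread_min minimum per-type range of f.
#' @return an `smk_correction_model`: per type intercept/slope/n, plus
#'   `f_star`.
#' @export
fit_correction <- function(scores, f, types,
                           target_compartment = c("epithelial", "immune"),
                           min_n = 10, spread_min = 0.2) {
  target_compartment <- match.arg(target_compartment)
  lines <- fit_group_lines(scores, f, types, min_n = min_n,
                           spread_min = spread_min)
  structure(list(lines = lines,
                 f_star = if (target_compartment == "epithelial") 0 else 1,
                 target_compartment = target_compartment),
            class = "smk_correction_model")
}

#' Apply the cell-composition correction to scores
#'
#' For a sample of type t with score y at composition f, the corrected score
#' is the type-t line evaluated at the target composition plus the sample's
#' residual: `corrected = intercept_t(f*) + (y - (intercept_t + slope_t *
#' f))`. At f = f* the correction is the identity. Corrected values are not
#' clipped; values outside \[0,1\] are flagged.
#'
#' @param scores numeric vector of raw scores.
#' @param f composition fraction per sample.
#' @param types type label per sample; every type must have a fitted line.
#' @param model an `smk_correction_model` from [fit_correction()].
#' @return data frame `raw, corrected, f, type, out_of_range`.
#' @export
correct_scores <- function(scores, f, types, model) {
  stopifnot(inherits(model, "smk_correction_model"))
  types <- as.character(types)
  missing_types <- setdiff(unique(types), names(model$lines))
  if (length(missing_types) > 0)
    stop("no correction line fitted for type(s): ",
         paste(missing_types, collapse = ", "),
         "; refusing to borrow another type's line")
  corrected <- numeric(length(scores))
  for (t in unique(types)) {
    ln <- model$lines[[t]]
    idx <- types == t
    yhat <- ln$intercept + ln$slope * f[idx]
    corrected[idx] <- (ln$intercept + ln$slope * model$f_star) +
      (scores[idx] - yhat)
  }
  data.frame(raw = scores, corrected = corrected, f = f, type = types,
             out_of_range = corrected < 0 | corrected > 1,
             stringsAsFactors = FALSE)
}

#' Score a cohort over several CpG sets, raw and composition-corrected
#'
#' Convenience wrapper: computes [mean_score()] per set, fits the per-type
#' correction on the cohort and applies it. The composition fraction is the
#' `immune_proportion` column when present, else `lymphoid_proportion`.
#'
#' @param beta CpG x sample beta matrix.
#' @param sets named list of [cpg_set()] objects.
#' @param fractions cell-fraction data frame.
#' @param sheet sample sheet (provides the type per sample).
#' @param corrected also fit and apply the composition correction.
#' @param min_n,spread_min correction-fit requirements.
#' @return data frame `sample_id, set, raw, corrected, f, type, coverage,
#'   out_of_range` (corrected columns NA when `corrected = FALSE`).
#' @export
score_table <- function(beta, sets, fractions, sheet, corrected = TRUE,
                        min_n = 10, spread_min = 0.2) {
  fcol <- if ("immune_proportion" %in% names(fractions)) "immune_proportion"
          else "lymphoid_proportion"
  ids <- colnames(beta)
  f <- fractions[[fcol]][match(ids, fractions$sample_id)]
  type <- sheet$smoking_type[match(ids, sheet$sample_id)]
  if (anyNA(f) || anyNA(type))
    stop("every sample in the beta matrix needs a fraction and a sheet record")
  out <- list()
  for (nm in names(sets)) {
    ms <- mean_score(beta, sets[[nm]])
    row <- data.frame(sample_id = ids, set = nm, raw = ms$score,
                      corrected = NA_real_, f = f, type = type,
                      coverage = ms$coverage, out_of_range = NA,
                      stringsAsFactors = FALSE)
    if (corrected) {
      model <- fit_correction(ms$score, f, type,
                              target_compartment = sets[[nm]]$target_compartment,
                              min_n = min_n, spread_min = spread_min)
      cs <- correct_scores(ms$score, f, type, model)
      row$corrected <- cs$corrected
      row$out_of_range <- cs$out_of_range
    }
    out[[nm]] <- row
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
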