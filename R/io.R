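# Readers/writers for the plain-text artifacts every stage composes through.
# Dialect is fixed: UTF-8, tab- (matrices) or comma-separated (sheets),
# '.' decimal, "NA" for missing.

#' Read a methylation beta matrix from TSV
#'
#' Expects a header row, a first column `cpg_id` and one column per sample.
#' Values must be in \[0,1\] or `NA`; violations are reported with their CpG
#' and sample coordinates.
#'
#' @param path file path.
#' @return numeric matrix (rows CpGs, columns samples). The number of missing
#'   cells is attached as attribute `n_missing`.
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "cpg_id")
    stop("beta matrix must have a first column named 'cpg_id': ", path)
  cpgs <- as.character(df[[1]])
  if (anyDuplicated(cpgs))
    stop("duplicated cpg_id in ", path, ": ",
         paste(unique(cpgs[duplicated(cpgs)])[1:min(3, sum(duplicated(cpgs)))],
               collapse = ", "))
  if (anyDuplicated(names(df)[-1]))
    stop("duplicated sample id in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in beta matrix ", path)
  rownames(m) <- cpgs
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("beta value out of [0,1] at CpG ", cpgs[bad[1, 1]],
         ", sample ", colnames(m)[bad[1, 2]],
         " (", nrow(bad), " offending cell(s))")
  attr(m, "n_missing") <- sum(is.na(m))
  m
}

#' Write a beta matrix as TSV (6-decimal fixed precision)
#'
#' @param beta numeric matrix with CpG rownames and sample colnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)), !is.null(colnames(beta)))
  out <- apply(beta, 2, function(x)
    ifelse(is.na(x), "NA", formatC(x, format = "f", digits = 6)))
  out <- cbind(cpg_id = rownames(beta), out)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

SHEET_COLS <- c("sample_id", "tissue", "smoking_type", "age", "pack_years",
                "duration_category", "sex")
SMOKING_LABELS <- c("never", "ex", "current", "ecig", "smokeless", "nonsmoker")

#' Read / write a sample sheet (CSV)
#'
#' Columns: `sample_id`, `tissue`, `smoking_type` (never/ex/current plus the
#' extensible exposure labels ecig/smokeless/nonsmoker), `age`, `pack_years`,
#' `duration_category`, `sex`.
#'
#' @param path file path.
#' @return data frame with one record per sample.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(SHEET_COLS, names(df))
  if (length(miss) > 0)
    stop("sample sheet ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in sample sheet ", path)
  bad <- setdiff(unique(df$smoking_type), SMOKING_LABELS)
  if (length(bad) > 0)
    stop("unknown smoking_type label(s): ", paste(bad, collapse = ", "))
  df
}

#' @rdname read_sample_sheet
#' @param sheet sample sheet data frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.csv(sheet[, SHEET_COLS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a CpG set
#'
#' A named group of CpGs whose mean methylation is scored together. The
#' target compartment decides which pure-compartment intercept the
#' composition correction extrapolates to (epithelial -> f = 0, immune ->
#' f = 1). When unspecified it defaults from the name: names containing
#' "immune" target the immune compartment, all others the epithelial one.
#'
#' @param name set label (e.g. an archetype name).
#' @param cpgs character vector of member CpG ids.
#' @param target_compartment `"epithelial"`, `"immune"`, or `NULL` to derive
#'   from `name`.
#' @return an `smk_cpg_set` list.
#' @export
cpg_set <- function(name, cpgs, target_compartment = NULL) {
  if (length(cpgs) == 0) stop("CpG set '", name, "' is empty")
  if (anyDuplicated(cpgs)) stop("CpG set '", name, "' has duplicate members")
  if (is.null(target_compartment))
    target_compartment <- if (grepl("immune", name)) "immune" else "epithelial"
  target_compartment <- match.arg(target_compartment, c("epithelial", "immune"))
  structure(list(name = name, cpgs = as.character(cpgs),
                 target_compartment = target_compartment),
            class = "smk_cpg_set")
}

#' Read / write CpG set files
#'
#' Two-column tab-separated text with header `set_name<TAB>cpg_id`. Optional
#' comment lines of the form `#compartment<TAB><set_name><TAB><epithelial|immune>`
#' override the name-based default target compartment.
#'
#' @param path file path.
#' @return named list of [cpg_set()] objects.
#' @export
read_cpg_sets <- function(path) {
  lines <- readLines(path)
  comp_lines <- grep("^#compartment\t", lines, value = TRUE)
  overrides <- list()
  for (cl in comp_lines) {
    parts <- strsplit(cl, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 3) stop("malformed compartment header: ", cl)
    overrides[[parts[2]]] <- parts[3]
  }
  body <- lines[!startsWith(lines, "#")]
  df <- utils::read.delim(text = paste(body, collapse = "\n"),
                          stringsAsFactors = FALSE)
  if (!all(c("set_name", "cpg_id") %in% names(df)))
    stop("CpG set file must have columns set_name, cpg_id: ", path)
  if (anyDuplicated(df[, c("set_name", "cpg_id")]))
    stop("duplicate (set, cpg) pair in ", path)
  sets <- lapply(split(df$cpg_id, df$set_name), as.character)
  out <- lapply(names(sets), function(nm)
    cpg_set(nm, sets[[nm]], target_compartment = overrides[[nm]]))
  names(out) <- names(sets)
  out
}

#' @rdname read_cpg_sets
#' @param sets named list of [cpg_set()] objects.
#' @export
write_cpg_sets <- function(sets, path) {
  hdr <- vapply(sets, function(s)
    paste("#compartment", s$name, s$target_compartment, sep = "\t"), "")
  body <- do.call(rbind, lapply(sets, function(s)
    data.frame(set_name = s$name, cpg_id = s$cpgs, stringsAsFactors = FALSE)))
  writeLines(c(hdr, paste(names(body), collapse = "\t"),
               paste(body$set_name, body$cpg_id, sep = "\t")), path)
  invisible(path)
}

#' Read a CpG chromosome annotation (TSV: cpg_id, chromosome)
#'
#' @param path file path.
#' @return named character vector mapping CpG id to chromosome label.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cpg_id", "chromosome") %in% names(df)))
    stop("annotation must have columns cpg_id, chromosome: ", path)
  stats::setNames(as.character(df$chromosome), df$cpg_id)
}

#' Read / write cell-fraction tables (CSV)
#'
#' @param path file path.
#' @return data frame with `sample_id`, one column per compartment, and any
#'   derived `immune_proportion` / `lymphoid_proportion` columns.
#' @export
read_cell_fractions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id")
    stop("fractions file must start with sample_id: ", path)
  df
}

#' @rdname read_cell_fractions
#' @param fractions cell-fraction data frame.
#' @export
write_cell_fractions <- function(fractions, path) {
  utils::write.csv(fractions, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a delta-beta profile matrix (TSV)
#'
#' Columns: `cpg_id`, the six canonical delta-beta columns and their
#' standard errors (`se_` prefix). Written values are clipped to \[-1, 1\].
#'
#' @param path file path.
#' @return an `smk_delta_matrix` (matrix with an `se` attribute).
#' @export
read_delta_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  cols <- delta_column_names()
  if (!all(cols %in% names(df)))
    stop("delta matrix file lacks canonical columns: ", path)
  m <- as.matrix(df[, cols])
  rownames(m) <- df$cpg_id
  secols <- paste0("se_", cols)
  if (all(secols %in% names(df))) {
    se <- as.matrix(df[, secols]); dimnames(se) <- dimnames(m)
    attr(m, "se") <- se
  }
  class(m) <- c("smk_delta_matrix", class(m))
  m
}

#' @rdname read_delta_matrix
#' @param delta an `smk_delta_matrix` from [build_delta_matrix()].
#' @export
write_delta_matrix <- function(delta, path) {
  m <- pmin(pmax(unclass(delta), -1), 1)
  df <- data.frame(cpg_id = rownames(m), m, check.names = FALSE)
  se <- attr(delta, "se")
  if (!is.null(se)) {
    colnames(se) <- paste0("se_", colnames(m))
    df <- cbind(df, se)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
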