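# Grouping of delta-beta profiles into signature archetypes: agglomerative
# hierarchical clustering (Euclidean distance, Ward linkage) of the
# cross-tissue delta-beta feature matrix, followed by rule-based naming of
# cluster mean profiles.

#' Cluster the delta-beta feature matrix
#'
#' Rows are sorted lexicographically by CpG id before clustering, making the
#' result invariant to input order; missing entries (tissues without data)
#' are imputed as 0, i.e. "no evidence of effect", and flagged. All six
#' columns share the delta-beta scale, so no feature scaling is applied.
#'
#' @param delta an `smk_delta_matrix` (or plain CpG x 6 matrix).
#' @param k number of clusters; ignored when `auto_k = TRUE`.
#' @param auto_k select k in 2..8 by maximum mean silhouette width.
#' @param tau labelling threshold passed to [label_archetypes()].
#' @return an `smk_clusters` list: `assignments` (data frame `cpg_id,
#'   cluster, label, imputed`), `means` (cluster x 6 mean profiles), `sizes`,
#'   `labels`, `k`, and mean `silhouette` width (NA for k = 1).
#' @export
cluster_delta_matrix <- function(delta, k = 4, auto_k = FALSE, tau = 0.02) {
  m <- unclass(delta)
  attr(m, "se") <- NULL
  if (is.null(rownames(m))) stop("delta matrix must have CpG rownames")
  m <- m[order(rownames(m)), , drop = FALSE]
  imputed <- apply(is.na(m), 1, any)
  m[is.na(m)] <- 0
  n <- nrow(m)
  if (!auto_k && (k < 1 || k > n))
    stop("k must lie between 1 and the number of CpGs (", n, ")")
  d <- stats::dist(m)
  hc <- stats::hclust(d, method = "ward.D2")
  sil_mean <- NA_real_
  if (auto_k) {
    ks <- 2:min(8, n - 1)
    sil <- vapply(ks, function(kk)
      mean(cluster::silhouette(stats::cutree(hc, kk), d)[, "sil_width"]),
      numeric(1))
    k <- ks[which.max(sil)]
    sil_mean <- max(sil)
  }
  cl <- if (k == 1) rep(1L, n) else stats::cutree(hc, k)
  if (k > 1 && is.na(sil_mean))
    sil_mean <- mean(cluster::silhouette(cl, d)[, "sil_width"])
  means <- do.call(rbind, lapply(split(seq_len(n), cl), function(i)
    colMeans(m[i, , drop = FALSE])))
  rownames(means) <- names(split(seq_len(n), cl))
  labels <- label_archetypes(means, tau = tau)
  structure(list(
    assignments = data.frame(cpg_id = rownames(m), cluster = unname(cl),
                             label = unname(labels[as.character(cl)]),
                             imputed = unname(imputed),
                             stringsAsFactors = FALSE),
    means = means, sizes = as.integer(table(cl)), labels = labels,
    k = k, silhouette = sil_mean), class = "smk_clusters")
}

#' Name clusters after their archetype mean profile
#'
#' Rule-based assignment on the cluster mean delta-beta 6-vector, with
#' threshold `tau` separating "effect" from "no effect":
#' \itemize{
#'   \item `epithelial_hypoM`: buccal and cervical epithelial means < -tau,
#'     all immune-side means within +-tau;
#'   \item `immune_hypoM`: buccal/cervical immune, lymphoid and myeloid
#'     means < -tau, epithelial means within +-tau;
#'   \item `distal_epithelial_hyperM`: cervical epithelial > +tau, buccal
#'     epithelial within +-tau;
#'   \item `proximal_epithelial_hyperM`: buccal epithelial > +tau, cervical
#'     epithelial within +-tau;
#'   \item otherwise `unlabeled`.
#' }
#' Two clusters mapping to one archetype are kept and suffixed, with a
#' warning.
#'
#' @param means cluster x 6 matrix of mean profiles (canonical column order).
#' @param tau effect threshold on the delta-beta scale.
#' @return named character vector, one label per cluster.
#' @export
label_archetypes <- function(means, tau = 0.02) {
  stopifnot(ncol(means) == 6)
  colnames(means) <- delta_column_names()
  lab <- apply(means, 1, function(v) {
    eb <- v["delta_epi_buccal"]; ib <- v["delta_imm_buccal"]
    ec <- v["delta_epi_cervical"]; ic <- v["delta_imm_cervical"]
    ly <- v["delta_lymphoid_blood"]; my <- v["delta_myeloid_blood"]
    small <- function(x) !is.na(x) & abs(x) <= tau
    neg <- function(x) !is.na(x) & x < -tau
    pos <- function(x) !is.na(x) & x > tau
    if (neg(eb) && neg(ec) && small(ib) && small(ic) && small(ly) && small(my))
      "epithelial_hypoM"
    else if (neg(ib) && neg(ic) && neg(ly) && neg(my) && small(eb) && small(ec))
      "immune_hypoM"
    else if (pos(ec) && small(eb))
      "distal_epithelial_hyperM"
    else if (pos(eb) && small(ec))
      "proximal_epithelial_hyperM"
    else "unlabeled"
  })
  dup <- duplicated(lab) & lab != "unlabeled"
  if (any(dup)) {
    warning("multiple clusters share an archetype label; suffixing")
    for (l in unique(lab[dup])) {
      i <- which(lab == l)
      lab[i[-1]] <- paste0(l, "_", seq_along(i[-1]) + 1)
    }
  }
  lab
}

#' Convert labelled clusters to scoreable CpG sets
#'
#' @param clusters an `smk_clusters` object.
#' @param drop_unlabeled omit clusters labelled `unlabeled`.
#' @return named list of [cpg_set()] objects, one per cluster label.
#' @export
clusters_to_sets <- function(clusters, drop_unlabeled = TRUE) {
  a <- clusters$assignments
  keep <- if (drop_unlabeled) a$label != "unlabeled" else rep(TRUE, nrow(a))
  a <- a[keep, , drop = FALSE]
  groups <- split(a$cpg_id, a$label)
  out <- lapply(names(groups), function(l) cpg_set(l, groups[[l]]))
  names(out) <- names(groups)
  out
}
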