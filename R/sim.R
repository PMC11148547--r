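#' @keywords internal
#' @aliases smokesig
"_PACKAGE"

# Fixed vocabularies used throughout the pipeline.
SMK_TISSUES <- c("buccal", "cervical", "blood")
SMK_TYPES <- c("never", "ex", "current")
SMK_ARCHETYPES <- c("epithelial_hypoM", "immune_hypoM",
                    "distal_epithelial_hyperM", "proximal_epithelial_hyperM",
                    "null")

#' Compartment labels for a tissue
#'
#' Buccal and cervical samples are modelled as epithelial/immune mixtures;
#' blood as lymphoid/myeloid. The first compartment is the one whose
#' proportion is tracked as the composition covariate f (immune for
#' buccal/cervical, lymphoid for blood).
#'
#' @param tissue one of `"buccal"`, `"cervical"`, `"blood"`.
#' @return character vector of two compartment names, f-compartment first.
#' @export
tissue_compartments <- function(tissue) {
  tissue <- match.arg(tissue, SMK_TISSUES)
  if (tissue == "blood") c("lymphoid", "myeloid") else c("immune", "epithelial")
}

#' Configuration for the synthetic bulk methylation generator
#'
#' Defines the generative conditions: CpG archetype composition, smoking
#' effect sizes on the beta scale, ex-smoker attenuation, pack-year dose
#' slope, beta-distributed measurement noise, per-tissue cell-fraction
#' distributions and cohort sizes.
#'
#' @param n_cpgs total number of CpGs.
#' @param archetype_sizes named integer vector over the five archetypes
#'   (`epithelial_hypoM`, `immune_hypoM`, `distal_epithelial_hyperM`,
#'   `proximal_epithelial_hyperM`, `null`); must sum to `n_cpgs`.
#' @param effect_size smoking delta-beta magnitude per affected compartment,
#'   a scalar or a vector named by the non-null archetypes. Beta-scale,
#'   typical range 0.05-0.3.
#' @param exsmoker_attenuation fraction in \[0,1\] of the current-smoker
#'   effect that has reversed in ex-smokers (1 = full reversal). Scalar or
#'   named per archetype.
#' @param lymphoid_ratio for `immune_hypoM` CpGs, the lymphoid-compartment
#'   effect magnitude as a fraction (in \[0,1\]) of the myeloid magnitude, so
#'   myeloid >= lymphoid.
#' @param dose_slope additional delta-beta magnitude per pack-year applied in
#'   the direction of the archetype effect (0 disables dose response).
#' @param noise_precision concentration kappa of the beta measurement noise;
#'   observed values ~ Beta(m*kappa, (1-m)*kappa). `Inf` disables noise.
#' @param fraction_distributions named list of `c(shape1, shape2)` for the
#'   per-tissue f-compartment fraction (immune fraction for buccal/cervical,
#'   lymphoid for blood).
#' @param n_samples samples per tissue per smoking type.
#' @param age_range numeric length-2, uniform age range in years.
#' @param age_slope beta change per year of age applied uniformly to all
#'   CpGs (0 by default: age is a covariate, not a target).
#' @param tissues tissues to simulate.
#' @param seed integer seed driving all randomness; per-tissue substreams are
#'   derived from it so enlarging one tissue leaves the others unchanged.
#' @return a validated `smk_sim_config` list.
#' @export
sim_config <- function(n_cpgs = 500L,
                       archetype_sizes = c(epithelial_hypoM = 100L,
                                           immune_hypoM = 100L,
                                           distal_epithelial_hyperM = 100L,
                                           proximal_epithelial_hyperM = 100L,
                                           null = 100L),
                       effect_size = 0.2,
                       exsmoker_attenuation = 0.7,
                       lymphoid_ratio = 0.7,
                       dose_slope = 0,
                       noise_precision = 200,
                       fraction_distributions = list(buccal = c(2, 6),
                                                     cervical = c(3, 4),
                                                     blood = c(5, 5)),
                       n_samples = 100L,
                       age_range = c(20, 70),
                       age_slope = 0,
                       tissues = SMK_TISSUES,
                       seed = 1L) {
  tissues <- match.arg(tissues, SMK_TISSUES, several.ok = TRUE)
  if (!all(names(archetype_sizes) %in% SMK_ARCHETYPES))
    stop("unknown archetype in archetype_sizes: ",
         paste(setdiff(names(archetype_sizes), SMK_ARCHETYPES), collapse = ", "))
  sizes <- integer(length(SMK_ARCHETYPES))
  names(sizes) <- SMK_ARCHETYPES
  sizes[names(archetype_sizes)] <- as.integer(archetype_sizes)
  if (sum(sizes) != n_cpgs)
    stop("archetype_sizes must sum to n_cpgs (", sum(sizes), " != ", n_cpgs, ")")
  eff <- expand_by_archetype(effect_size, "effect_size")
  att <- expand_by_archetype(exsmoker_attenuation, "exsmoker_attenuation")
  if (any(eff <= 0) || any(eff >= 0.85))
    stop("effect_size must lie in (0, 0.85): larger effects push compartment ",
         "means outside (0,1) given the 0.05/0.95 baseline bounds")
  if (any(att < 0 | att > 1))
    stop("exsmoker_attenuation must lie in [0,1]")
  if (lymphoid_ratio < 0 || lymphoid_ratio > 1)
    stop("lymphoid_ratio must lie in [0,1]")
  if (!is.infinite(noise_precision) && noise_precision <= 0)
    stop("noise_precision must be > 0 (or Inf for noiseless output)")
  for (t in tissues) {
    p <- fraction_distributions[[t]]
    if (is.null(p) || length(p) != 2 || any(p <= 0))
      stop("fraction_distributions$", t, " must be two positive beta shapes")
  }
  structure(list(n_cpgs = as.integer(n_cpgs), archetype_sizes = sizes,
                 effect_size = eff, exsmoker_attenuation = att,
                 lymphoid_ratio = lymphoid_ratio, dose_slope = dose_slope,
                 noise_precision = noise_precision,
                 fraction_distributions = fraction_distributions,
                 n_samples = as.integer(n_samples),
                 age_range = age_range, age_slope = age_slope,
                 tissues = tissues, seed = as.integer(seed)),
            class = "smk_sim_config")
}

expand_by_archetype <- function(x, what) {
  arch <- setdiff(SMK_ARCHETYPES, "null")
  if (length(x) == 1 && is.null(names(x))) {
    out <- rep(x, length(arch)); names(out) <- arch; return(out)
  }
  if (!all(arch %in% names(x)))
    stop(what, " must be a scalar or named over all non-null archetypes")
  x[arch]
}

# Deterministic substream seed: distinct fixed offsets per (stage, tissue)
# so sampling in one tissue never perturbs another.
stream_seed <- function(seed, key) {
  keys <- c("truth", "samples_buccal", "samples_cervical", "samples_blood")
  k <- match(key, keys)
  if (is.na(k)) stop("unknown stream key: ", key)
  as.integer((as.numeric(seed) + k * 1000003) %% 2147483647)
}

#' Build the ground-truth ledger of a synthetic methylation study
#'
#' Draws baseline per-compartment mean beta values from a bimodal
#' distribution over (0.05, 0.95) and applies archetype-specific smoking
#' effects: `epithelial_hypoM` lowers the epithelial compartment of both
#' buccal and cervical tissue; `immune_hypoM` lowers the immune compartments
#' of buccal/cervical and both blood lineages (myeloid magnitude >= lymphoid);
#' `distal_epithelial_hyperM` raises cervical epithelium only;
#' `proximal_epithelial_hyperM` raises buccal epithelium only; `null` CpGs
#' are untouched. Ex-smoker means interpolate between never and current:
#' `mu(ex) = mu(never) + (1 - attenuation) * delta`.
#'
#' Baselines of affected compartments are drawn inside the band that keeps
#' the post-effect mean within (0.05, 0.95); a configuration whose effect
#' cannot fit is rejected with a diagnostic.
#'
#' @param config a [sim_config()] object.
#' @return an `smk_sim_truth` list with elements `mu` (per tissue, a
#'   CpG x compartment x smoking-type array), `delta` (per tissue, the exact
#'   current-vs-never difference `mu(current) - mu(never)`), `archetype`
#'   (named per-CpG labels) and `config`.
#' @export
build_truth <- function(config) {
  stopifnot(inherits(config, "smk_sim_config"))
  set.seed(stream_seed(config$seed, "truth"))
  n <- config$n_cpgs
  cpgs <- sprintf("cpg%05d", seq_len(n))
  archetype <- rep(SMK_ARCHETYPES, times = config$archetype_sizes)
  names(archetype) <- cpgs

  r_bimodal <- function(k) {
    lo <- stats::rbeta(k, 2, 8); hi <- stats::rbeta(k, 8, 2)
    0.05 + 0.9 * ifelse(stats::runif(k) < 0.5, lo, hi)
  }

  mu <- list(); delta <- list()
  for (tissue in config$tissues) {
    comps <- tissue_compartments(tissue)
    base <- matrix(r_bimodal(n * 2), nrow = n, ncol = 2,
                   dimnames = list(cpgs, comps))
    d <- matrix(0, n, 2, dimnames = list(cpgs, comps))
    for (a in setdiff(SMK_ARCHETYPES, "null")) {
      idx <- archetype == a
      if (!any(idx)) next
      e <- config$effect_size[[a]]
      affected <- switch(a,
        epithelial_hypoM = if (tissue != "blood")
          list(epithelial = -e),
        immune_hypoM = if (tissue == "blood")
          list(myeloid = -e, lymphoid = -e * config$lymphoid_ratio)
        else list(immune = -e),
        distal_epithelial_hyperM = if (tissue == "cervical")
          list(epithelial = e),
        proximal_epithelial_hyperM = if (tissue == "buccal")
          list(epithelial = e))
      if (is.null(affected)) next
      for (comp in names(affected)) {
        eff <- affected[[comp]]
        # redraw baseline uniformly inside the feasible band
        lo <- 0.05 + max(0, -eff) + 0.02
        hi <- 0.95 - max(0, eff) - 0.02
        if (lo >= hi)
          stop("effect_size ", abs(eff), " for archetype '", a,
               "' pushes ", tissue, "/", comp, " means outside (0,1)")
        base[idx, comp] <- stats::runif(sum(idx), lo, hi)
        d[idx, comp] <- eff
      }
    }
    att <- rep(0, n)
    nz <- archetype != "null"
    att[nz] <- config$exsmoker_attenuation[archetype[nz]]
    mu_t <- array(NA_real_, dim = c(n, 2, 3),
                  dimnames = list(cpgs, comps, SMK_TYPES))
    mu_t[, , "never"] <- base
    mu_t[, , "current"] <- base + d
    mu_t[, , "ex"] <- base + (1 - att) * d
    if (any(mu_t <= 0 | mu_t >= 1))
      stop("internal: compartment means escaped (0,1) in tissue ", tissue)
    mu[[tissue]] <- mu_t
    delta[[tissue]] <- d
  }
  structure(list(mu = mu, delta = delta, archetype = archetype,
                 cpg_ids = cpgs, config = config),
            class = "smk_sim_truth")
}

#' True compartment-specific delta-beta table
#'
#' @param truth an `smk_sim_truth` object.
#' @return matrix of exact current-vs-never effects, one row per CpG, columns
#'   in the canonical order used by [build_delta_matrix()].
#' @export
true_delta_matrix <- function(truth) {
  stopifnot(inherits(truth, "smk_sim_truth"))
  cols <- delta_column_names()
  out <- matrix(NA_real_, length(truth$cpg_ids), length(cols),
                dimnames = list(truth$cpg_ids, cols))
  map <- list(delta_epi_buccal = c("buccal", "epithelial"),
              delta_imm_buccal = c("buccal", "immune"),
              delta_epi_cervical = c("cervical", "epithelial"),
              delta_imm_cervical = c("cervical", "immune"),
              delta_lymphoid_blood = c("blood", "lymphoid"),
              delta_myeloid_blood = c("blood", "myeloid"))
  for (cn in cols) {
    t <- map[[cn]][1]
    if (!is.null(truth$delta[[t]])) out[, cn] <- truth$delta[[t]][, map[[cn]][2]]
  }
  out
}

#' Simulate bulk methylation datasets from a truth ledger
#'
#' Per sample, a tissue-appropriate f-compartment fraction is drawn (immune
#' fraction in buccal/cervical, lymphoid in blood), the expected bulk value is
#' the linear two-compartment mixture `m = f*mu_f + (1-f)*mu_other`, and the
#' observed beta value is drawn from a Beta distribution with mean `m` and
#' concentration `noise_precision` (noiseless when `Inf`). Pack-years are
#' drawn for smokers and, when `dose_slope > 0`, deepen the archetype effect
#' proportionally before mixing. Fully reproducible from the config seed.
#'
#' @param truth an `smk_sim_truth` from [build_truth()].
#' @param config optional [sim_config()]; defaults to `truth$config`.
#' @return list with per-tissue named lists `beta` (CpG x sample matrices),
#'   `sheet` (sample sheets) and `fractions` (true compartment fractions,
#'   including the derived `immune_proportion` / `lymphoid_proportion`).
#' @export
simulate_dataset <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "smk_sim_truth"))
  beta <- list(); sheet <- list(); fractions <- list()
  for (tissue in config$tissues) {
    set.seed(stream_seed(config$seed, paste0("samples_", tissue)))
    comps <- tissue_compartments(tissue)
    n_cpg <- length(truth$cpg_ids)
    per <- config$n_samples
    types <- rep(SMK_TYPES, each = per)
    ids <- sprintf("%s_%s_%03d", tissue, types,
                   unlist(lapply(SMK_TYPES, function(x) seq_len(per))))
    ns <- length(ids)
    shp <- config$fraction_distributions[[tissue]]
    f <- stats::rbeta(ns, shp[1], shp[2])
    age <- stats::runif(ns, config$age_range[1], config$age_range[2])
    pack_years <- ifelse(types == "never", 0,
                         round(stats::rgamma(ns, shape = 4, scale = 5), 1))
    duration <- rep(NA_character_, ns)
    duration[types == "ex"] <- sample(c("<=1y", "1-5y", ">5y"),
                                      sum(types == "ex"), replace = TRUE)
    mu_t <- truth$mu[[tissue]]
    d <- truth$delta[[tissue]]
    scale_type <- c(never = 0, ex = NA, current = 1)

    M <- matrix(NA_real_, n_cpg, ns, dimnames = list(truth$cpg_ids, ids))
    att <- rep(0, n_cpg)
    nz <- truth$archetype != "null"
    att[nz] <- config$exsmoker_attenuation[truth$archetype[nz]]
    for (j in seq_len(ns)) {
      sc <- if (types[j] == "ex") (1 - att) else scale_type[[types[j]]]
      dj <- d
      if (config$dose_slope != 0 && types[j] != "never")
        dj <- d + sign(d) * config$dose_slope * pack_years[j]
      mu_j <- mu_t[, , "never"] + sc * dj
      if (config$age_slope != 0)
        mu_j <- mu_j + config$age_slope * (age[j] - mean(config$age_range))
      mu_j <- pmin(pmax(mu_j, 1e-4), 1 - 1e-4)
      M[, j] <- f[j] * mu_j[, comps[1]] + (1 - f[j]) * mu_j[, comps[2]]
    }
    kap <- config$noise_precision
    obs <- if (is.infinite(kap)) M else {
      matrix(stats::rbeta(length(M), M * kap, (1 - M) * kap),
             nrow = n_cpg, dimnames = dimnames(M))
    }
    fr <- data.frame(sample_id = ids, f, 1 - f,
                     check.names = FALSE, stringsAsFactors = FALSE)
    names(fr)[2:3] <- comps
    fr[[if (tissue == "blood") "lymphoid_proportion" else "immune_proportion"]] <- f
    beta[[tissue]] <- obs
    sheet[[tissue]] <- data.frame(sample_id = ids, tissue = tissue,
                                  smoking_type = types, age = round(age, 1),
                                  pack_years = pack_years,
                                  duration_category = duration, sex = "F",
                                  stringsAsFactors = FALSE)
    fractions[[tissue]] <- fr
  }
  list(beta = beta, sheet = sheet, fractions = fractions)
}

#' Derive a deconvolution reference matrix from simulation truth
#'
#' Returns never-smoker compartment mean profiles, optionally restricted to
#' the CpGs most discriminative between the tissue's two compartments
#' (largest absolute between-compartment difference).
#'
#' @param truth an `smk_sim_truth`.
#' @param tissue tissue whose compartments the reference spans.
#' @param n_cpgs number of discriminative CpGs to keep; `NULL` keeps all.
#' @return CpG x compartment matrix of mean beta values.
#' @export
simulate_reference <- function(truth, tissue, n_cpgs = NULL) {
  stopifnot(inherits(truth, "smk_sim_truth"))
  tissue <- match.arg(tissue, truth$config$tissues)
  ref <- truth$mu[[tissue]][, , "never"]
  if (is.null(n_cpgs)) return(ref)
  if (n_cpgs > nrow(ref))
    stop("requested ", n_cpgs, " discriminative CpGs but only ",
         nrow(ref), " are available")
  disc <- abs(ref[, 1] - ref[, 2])
  keep <- order(disc, decreasing = TRUE)[seq_len(n_cpgs)]
  ref[sort(keep), , drop = FALSE]
}
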