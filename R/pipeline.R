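# End-to-end orchestration: simulate -> deconvolve -> ewas -> delta-beta ->
# cluster -> score -> evaluate, composing through plain files in a run
# directory so each stage is independently inspectable and re-runnable.

#' Default pipeline configuration
#'
#' @param out_dir run directory (created if absent).
#' @param seed integer seed for the synthetic stage.
#' @param sim a [sim_config()]; its seed is overridden by `seed`.
#' @param alpha family-wise significance level for the EWAS stage.
#' @param k number of delta-beta clusters.
#' @param n_ref_cpgs discriminative CpGs in the simulated reference.
#' @param fractions_files optional named list (per tissue) of externally
#'   computed cell-fraction CSVs; when supplied the deconvolution stage is
#'   skipped and these are used downstream.
#' @param stages character vector of stages to run, in pipeline order.
#' @return a `smk_run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L, sim = NULL, alpha = 0.05, k = 4,
                       n_ref_cpgs = 200, fractions_files = NULL,
                       stages = c("simulate", "deconvolve", "ewas", "delta",
                                  "cluster", "score", "evaluate")) {
  if (is.null(sim)) sim <- sim_config(seed = seed)
  else sim$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 alpha = alpha, k = k, n_ref_cpgs = n_ref_cpgs,
                 fractions_files = fractions_files, stages = stages),
            class = "smk_run_config")
}

#' Run the full synthetic-study pipeline
#'
#' Executes the enabled stages in order. Every stage reads only files written
#' by earlier stages (or supplied externally) and writes only files under the
#' run directory; a JSON manifest records the seed, per-stage row counts,
#' output checksums and collected warnings.
#'
#' @param config an [run_config()] object.
#' @return the run directory path, invisibly. Side effects: per-tissue beta
#'   matrices, sample sheets, true and estimated fractions, EWAS tables,
#'   the delta-beta matrix, cluster assignments and CpG sets, score tables
#'   and an evaluation summary, plus `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "smk_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(...) file.path(config$out_dir, ...)
  manifest <- list(seed = config$seed, stages = list(), warnings = list())
  notes <- character(0)
  run_stage <- function(name, fn) {
    if (!name %in% config$stages) return(invisible(NULL))
    t0 <- Sys.time()
    rows <- withCallingHandlers(fn(), warning = function(w) {
      notes <<- c(notes, paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    manifest$stages[[name]] <<- list(
      rows = rows, seconds = round(as.numeric(Sys.time() - t0, "secs"), 2))
  }
  tissues <- config$sim$tissues

  run_stage("simulate", function() {
    truth <- build_truth(config$sim)
    ds <- simulate_dataset(truth)
    for (t in tissues) {
      write_beta_matrix(ds$beta[[t]], path(paste0("beta_", t, ".tsv")))
      write_sample_sheet(ds$sheet[[t]], path(paste0("sheet_", t, ".csv")))
      write_cell_fractions(ds$fractions[[t]],
                           path(paste0("fractions_true_", t, ".csv")))
      ref <- simulate_reference(truth, t,
                                min(config$n_ref_cpgs, config$sim$n_cpgs))
      utils::write.table(data.frame(cpg_id = rownames(ref), ref),
                         path(paste0("reference_", t, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    saveRDS_truth(truth, path("truth.yaml"))
    vapply(tissues, function(t) nrow(ds$sheet[[t]]), integer(1))
  })

  read_ref <- function(t) {
    df <- utils::read.delim(path(paste0("reference_", t, ".tsv")))
    m <- as.matrix(df[, -1]); rownames(m) <- df$cpg_id; m
  }
  frac_path <- function(t) {
    if (!is.null(config$fractions_files)) config$fractions_files[[t]]
    else path(paste0("fractions_", t, ".csv"))
  }

  run_stage("deconvolve", function() {
    if (!is.null(config$fractions_files)) return(0L)
    n <- integer(0)
    for (t in tissues) {
      beta <- read_beta_matrix(path(paste0("beta_", t, ".tsv")))
      fr <- estimate_fractions(beta, read_ref(t))
      write_cell_fractions(fr, frac_path(t))
      n[t] <- nrow(fr)
    }
    n
  })

  load_tissue <- function(t) list(
    beta = read_beta_matrix(path(paste0("beta_", t, ".tsv"))),
    sheet = read_sample_sheet(path(paste0("sheet_", t, ".csv"))),
    fractions = read_cell_fractions(frac_path(t)))

  run_stage("ewas", function() {
    n <- integer(0)
    for (t in tissues) {
      d <- load_tissue(t)
      res <- run_ewas(d$beta, d$sheet, d$fractions, t)
      utils::write.table(res, path(paste0("ewas_", t, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      n[t] <- sum(!is.na(res$p_holm) & res$p_holm < config$alpha)
    }
    n
  })

  run_stage("delta", function() {
    res <- lapply(tissues, function(t)
      utils::read.delim(path(paste0("ewas_", t, ".tsv"))))
    sig <- significant_sites(res, alpha = config$alpha)
    if (length(sig) == 0) stop("no significant CpGs at alpha ", config$alpha)
    data <- lapply(tissues, load_tissue); names(data) <- tissues
    D <- build_delta_matrix(lapply(data, `[[`, "beta"),
                            lapply(data, `[[`, "sheet"),
                            lapply(data, `[[`, "fractions"), sig)
    write_delta_matrix(D, path("delta_matrix.tsv"))
    nrow(D)
  })

  run_stage("cluster", function() {
    D <- read_delta_matrix(path("delta_matrix.tsv"))
    cl <- cluster_delta_matrix(D, k = config$k)
    utils::write.table(cl$assignments, path("clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_cpg_sets(clusters_to_sets(cl), path("cpg_sets.tsv"))
    cl$k
  })

  run_stage("score", function() {
    sets <- read_cpg_sets(path("cpg_sets.tsv"))
    n <- integer(0)
    for (t in tissues) {
      d <- load_tissue(t)
      st <- score_table(d$beta, sets, d$fractions, d$sheet)
      utils::write.csv(st, path(paste0("scores_", t, ".csv")),
                       row.names = FALSE)
      n[t] <- nrow(st)
    }
    n
  })

  run_stage("evaluate", function() {
    n <- integer(0)
    for (t in tissues) {
      st <- utils::read.csv(path(paste0("scores_", t, ".csv")),
                            stringsAsFactors = FALSE)
      ev <- evaluate_scores(st)
      utils::write.csv(ev, path(paste0("evaluation_", t, ".csv")),
                       row.names = FALSE)
      n[t] <- nrow(ev)
    }
    n
  })

  outputs <- list.files(config$out_dir, full.names = TRUE)
  outputs <- outputs[!basename(outputs) %in% "manifest.json"]
  manifest$warnings <- notes
  manifest$md5 <- as.list(tools::md5sum(sort(outputs)))
  names(manifest$md5) <- basename(sort(outputs))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(config$out_dir)
}

# Truth ledger serialised as YAML (plain text, human-diffable).
saveRDS_truth <- function(truth, path) {
  obj <- list(
    archetype = as.list(truth$archetype),
    config = unclass(truth$config),
    mu = lapply(truth$mu, function(a) {
      lapply(dimnames(a)[[3]], function(ty) {
        m <- a[, , ty]
        stats::setNames(lapply(seq_len(ncol(m)), function(j)
          as.numeric(round(m[, j], 6))), colnames(m))
      }) -> l
      names(l) <- dimnames(a)[[3]]
      l
    }))
  obj$config$archetype_sizes <- as.list(obj$config$archetype_sizes)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read back a truth ledger written by the pipeline
#'
#' @param path path to `truth.yaml`.
#' @return list with `archetype` (named vector), `config` (plain list) and
#'   `mu` (per tissue, per smoking type, compartment mean vectors).
#' @export
read_truth <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$archetype <- unlist(obj$archetype)
  obj
}
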