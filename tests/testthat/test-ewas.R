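make_cohort <- function(n_per = 30, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per
  data.frame(sample_id = paste0("s", 1:n), tissue = "buccal",
             smoking_type = rep(c("never", "current"), each = n_per),
             age = runif(n, 25, 65), pack_years = 0,
             duration_category = NA, sex = "F", stringsAsFactors = FALSE)
}

make_fr <- function(sheet, seed = 2) {
  set.seed(seed)
  data.frame(sample_id = sheet$sample_id,
             immune_proportion = rbeta(nrow(sheet), 2, 6))
}

test_that("effects are recovered exactly on noiseless constructed data", {
  sheet <- make_cohort(); fr <- make_fr(sheet)
  cur <- as.numeric(sheet$smoking_type == "current")
  y <- 0.5 - 0.12 * cur + 0.001 * sheet$age + 0.2 * fr$immune_proportion
  names(y) <- sheet$sample_id
  res <- fit_cpg(y, sheet, fr)
  expect_equal(res$effect, -0.12, tolerance = 1e-10)
  expect_lt(res$p, 1e-10)
})

test_that("a constant CpG yields effect 0 and p = 1 with a flag", {
  sheet <- make_cohort(); fr <- make_fr(sheet)
  y <- rep(0.4, nrow(sheet)); names(y) <- sheet$sample_id
  res <- fit_cpg(y, sheet, fr)
  expect_equal(res$effect, 0)
  expect_equal(res$p, 1)
  expect_true(res$constant)
})

test_that("collinear covariates raise an error naming the pair", {
  sheet <- make_cohort()
  fr <- data.frame(sample_id = sheet$sample_id,
                   immune_proportion = sheet$age / 100)
  y <- runif(nrow(sheet)); names(y) <- sheet$sample_id
  expect_error(fit_cpg(y, sheet, fr),
               "collinear covariates: (age and composition|composition and age)")
})

test_that("group-size preconditions are enforced", {
  sheet <- make_cohort(n_per = 5); fr <- make_fr(sheet)
  y <- runif(10); names(y) <- sheet$sample_id
  expect_error(fit_cpg(y, sheet, fr), "at least 10 samples per smoking group")
})

test_that("Holm adjustment matches hand-derived and brute-force values", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.03), 0.03)
  expect_error(holm_adjust(c(0.1, NA)), "NA")
  expect_error(holm_adjust(c(0.1, 1.2)), "\\[0,1\\]")
  # closed-testing brute force over all rejection subsets, m <= 6 here
  set.seed(7)
  for (i in 1:20) {
    m <- sample(2:6, 1)
    p <- round(runif(m), 3)
    expect_equal(holm_adjust(p), holm_brute(p))
  }
  # smallest rejection threshold at level alpha is alpha/m
  m <- 1000
  p <- c(0.05 / m * 0.999, runif(m - 1, 0.5, 1))
  expect_lt(holm_adjust(p)[1], 0.05)
  p[1] <- 0.05 / m * 1.001
  expect_gte(holm_adjust(p)[1], 0.05)
})

test_that("EWAS on simulated smoking effects finds them and spares nulls", {
  st <- small_buccal()
  res <- run_ewas(st$ds$beta$buccal, st$ds$sheet$buccal,
                  st$ds$fractions$buccal, "buccal")
  expect_equal(nrow(res), 60)
  expect_true(all(res$p_holm >= res$p))
  expect_true(all(res$p_holm <= 1))
  arch <- st$truth$archetype[res$cpg_id]
  # large bulk effects (epithelial hypoM in an epithelial-dominant tissue)
  expect_true(all(res$p_holm[arch == "epithelial_hypoM"] < 0.05))
  expect_true(all(res$effect[arch == "epithelial_hypoM"] < 0))
  expect_true(all(res$effect[arch == "proximal_epithelial_hyperM"] > 0))
})

test_that("a strong immune effect in blood clears the EPIC-scale threshold", {
  cfg <- sim_config(n_cpgs = 20, archetype_sizes = c(immune_hypoM = 10,
                    null = 10), effect_size = 0.15, n_samples = 200,
                    tissues = "blood", seed = 21)
  st <- build_truth(cfg)
  ds <- simulate_dataset(st)
  res <- run_ewas(ds$beta$blood, ds$sheet$blood, ds$fractions$blood, "blood")
  hypo <- st$archetype[res$cpg_id] == "immune_hypoM"
  # raw p below the Holm point threshold implied by an EPIC-scale EWAS
  expect_true(all(res$p[hypo] < 7.9e-8))
})

test_that("type-I error and inflation are nominal on an all-null study", {
  cfg <- sim_config(n_cpgs = 2000, archetype_sizes = c(null = 2000),
                    n_samples = 100, tissues = "buccal", seed = 23)
  ds <- simulate_dataset(build_truth(cfg))
  res <- run_ewas(ds$beta$buccal, ds$sheet$buccal, ds$fractions$buccal,
                  "buccal")
  rate <- mean(res$p < 0.05)
  expect_gt(rate, 0.035)
  expect_lt(rate, 0.065)
  expect_gt(attr(res, "lambda"), 0.9)
  expect_lt(attr(res, "lambda"), 1.1)
})

test_that("significant sites take the union over tissues and drop sex CpGs", {
  r1 <- data.frame(cpg_id = c("a", "b", "c"), p_holm = c(0.01, 0.2, 0.03))
  r2 <- data.frame(cpg_id = c("a", "b", "c"), p_holm = c(0.5, 0.04, 0.9))
  expect_equal(significant_sites(list(r1, r2)), c("a", "b", "c"))
  ann <- c(a = "chr1", b = "chrX", c = "chr7")
  expect_equal(significant_sites(list(r1, r2), annotation = ann), c("a", "c"))
  ann2 <- c(a = "chr1", b = "X")
  expect_warning(out <- significant_sites(list(r1, r2), annotation = ann2),
                 "missing from the")
  expect_equal(out, c("a", "c"))
})

test_that("rows with missing betas are fitted on complete cases", {
  st <- small_buccal()
  beta <- st$ds$beta$buccal
  beta[1, 1:4] <- NA
  res <- run_ewas(beta, st$ds$sheet$buccal, st$ds$fractions$buccal, "buccal")
  expect_equal(res$n[1], sum(!is.na(beta[1, ])) -
                 sum(st$ds$sheet$buccal$smoking_type == "ex"))
  expect_false(is.na(res$p[1]))
})
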