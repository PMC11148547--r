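exact_lines_data <- function(n = 30) {
  f <- rep(seq(0.05, 0.65, length.out = n), 2)
  groups <- rep(c("never", "current"), each = n)
  y <- ifelse(groups == "never", 0.8 - 0.2 * f, 0.5 + 0.1 * f)
  list(y = y, f = f, groups = groups)
}

test_that("delta-beta reproduces exact line arithmetic at both intercepts", {
  d <- exact_lines_data()
  lines <- fit_group_lines(d$y, d$f, d$groups)
  expect_equal(lines$never$intercept, 0.8, tolerance = 1e-10)
  expect_equal(lines$never$slope, -0.2, tolerance = 1e-10)
  # never 0.8 - 0.2f vs current 0.5 + 0.1f: pure-epithelial effect -0.30,
  # pure-immune effect (0.6 - 0.6) = 0
  expect_equal(delta_beta(d$y, d$f, d$groups, at = 0)$delta, -0.3,
               tolerance = 1e-10)
  expect_equal(delta_beta(d$y, d$f, d$groups, at = 1)$delta, 0,
               tolerance = 1e-10)
})

test_that("identical groups give zero delta at both compartments", {
  set.seed(31)
  f <- rep(runif(40, 0, 0.8), 2)
  y <- 0.4 + 0.1 * f + rnorm(80, 0, 0.01)
  groups <- rep(c("never", "current"), each = 40)
  y[41:80] <- y[1:40]
  for (at in c(0, 1))
    expect_equal(delta_beta(y, f, groups, at = at)$delta, 0, tolerance = 1e-12)
})

test_that("swapping group labels negates the estimate", {
  set.seed(32)
  f <- runif(100, 0, 0.9)
  groups <- rep(c("never", "current"), 50)
  y <- 0.5 - 0.1 * (groups == "current") + 0.2 * f + rnorm(100, 0, 0.02)
  swapped <- ifelse(groups == "never", "current", "never")
  for (at in c(0, 1))
    expect_equal(delta_beta(y, f, groups, at = at)$delta,
                 -delta_beta(y, f, swapped, at = at)$delta, tolerance = 1e-12)
})

test_that("estimates agree with an independent lm()-based oracle", {
  set.seed(33)
  for (i in 1:10) {
    f <- runif(60, 0, 0.9)
    groups <- rep(c("never", "current"), 30)
    y <- runif(1) + runif(1, -0.3, 0.3) * f -
      0.1 * (groups == "current") + rnorm(60, 0, 0.03)
    for (at in c(0, 1))
      expect_equal(delta_beta(y, f, groups, at = at)$delta,
                   delta_oracle(y, f, groups, at), tolerance = 1e-10)
  }
})

test_that("degenerate designs are rejected", {
  d <- exact_lines_data()
  expect_error(fit_group_lines(d$y, rep(0.3, 60), d$groups),
               "composition range too narrow")
  expect_error(fit_group_lines(d$y[1:15], d$f[1:15], d$groups[1:15],
                               min_n = 20),
               "need >= 20")
})

test_that("compartment effects are recovered from simulated buccal data", {
  cfg <- sim_config(n_cpgs = 25, archetype_sizes = c(epithelial_hypoM = 25),
                    n_samples = 300, tissues = "buccal", seed = 35)
  truth <- build_truth(cfg)
  ds <- simulate_dataset(truth)
  keep <- ds$sheet$buccal$smoking_type %in% c("never", "current")
  f <- ds$fractions$buccal$immune_proportion[keep]
  groups <- ds$sheet$buccal$smoking_type[keep]
  err0 <- err1 <- numeric(25)
  for (i in 1:25) {
    y <- ds$beta$buccal[i, keep]
    # true epithelial effect -0.2, true immune effect 0
    d0 <- delta_beta(y, f, groups, at = 0)
    d1 <- delta_beta(y, f, groups, at = 1)
    err0[i] <- d0$delta - (-0.2)
    err1[i] <- d1$delta
    expect_lt(abs(err0[i]), 4.5 * d0$se)
    expect_lt(abs(err1[i]), 4.5 * d1$se)
  }
  expect_lte(sqrt(mean(err0^2)), 0.03)
  expect_lte(sqrt(mean(err1^2)), 0.03)
})

test_that("delta RMSE shrinks with sample size and meets the n=300 bound", {
  rmse_at <- function(n_per_type) {
    cfg <- sim_config(n_cpgs = 40,
                      archetype_sizes = c(epithelial_hypoM = 20, null = 20),
                      n_samples = n_per_type, tissues = "buccal", seed = 37)
    truth <- build_truth(cfg)
    ds <- simulate_dataset(truth)
    D <- build_delta_matrix(ds$beta, ds$sheet, ds$fractions, truth$cpg_ids)
    TD <- true_delta_matrix(truth)
    cols <- c("delta_epi_buccal", "delta_imm_buccal")
    sqrt(mean((D[, cols] - TD[, cols])^2))
  }
  r100 <- rmse_at(100)
  r300 <- rmse_at(300)
  expect_lt(r300, r100)
  expect_lte(r300, 0.03)
})

test_that("the assembled matrix has the canonical layout and missing flags", {
  st <- small_buccal()
  cpgs <- st$truth$cpg_ids[1:10]
  D <- build_delta_matrix(st$ds$beta, st$ds$sheet, st$ds$fractions, cpgs)
  expect_equal(colnames(D), delta_column_names())
  expect_equal(rownames(D), cpgs)
  # only buccal was simulated: cervical and blood columns are missing
  expect_true(all(is.na(D[, c("delta_epi_cervical", "delta_imm_cervical",
                              "delta_lymphoid_blood", "delta_myeloid_blood")])))
  expect_true(all(!is.na(D[, c("delta_epi_buccal", "delta_imm_buccal")])))
  expect_equal(dim(attr(D, "se")), dim(unclass(D)))
})

test_that("delta profiles match truth archetype sign patterns", {
  st <- default_study()
  sig <- st$truth$cpg_ids[st$truth$archetype != "null"]
  D <- build_delta_matrix(st$ds$beta, st$ds$sheet, st$ds$fractions, sig)
  TD <- true_delta_matrix(st$truth)[sig, ]
  dominant_sign_match <- vapply(seq_along(sig), function(i) {
    j <- which.max(abs(D[i, ]))
    sign(D[i, j]) == sign(TD[i, j]) && abs(TD[i, j]) > 0
  }, logical(1))
  expect_gte(mean(dominant_sign_match), 0.95)
})
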