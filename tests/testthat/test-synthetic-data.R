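test_that("archetype effects follow their compartment/tissue patterns", {
  truth <- default_study()$truth
  TD <- true_delta_matrix(truth)
  arch <- truth$archetype
  e <- 0.2
  # epithelial hypoM: both epithelia down, immune/blood untouched
  i <- arch == "epithelial_hypoM"
  expect_true(all(TD[i, "delta_epi_buccal"] == -e))
  expect_true(all(TD[i, "delta_epi_cervical"] == -e))
  expect_true(all(TD[i, c("delta_imm_buccal", "delta_imm_cervical",
                          "delta_lymphoid_blood", "delta_myeloid_blood")] == 0))
  # immune hypoM: immune compartments and both blood lineages down,
  # myeloid magnitude >= lymphoid
  i <- arch == "immune_hypoM"
  expect_true(all(TD[i, "delta_imm_buccal"] == -e))
  expect_true(all(TD[i, "delta_myeloid_blood"] == -e))
  expect_true(all(abs(TD[i, "delta_myeloid_blood"]) >=
                  abs(TD[i, "delta_lymphoid_blood"])))
  expect_true(all(TD[i, "delta_lymphoid_blood"] < 0))
  expect_true(all(TD[i, c("delta_epi_buccal", "delta_epi_cervical")] == 0))
  # distal hyperM: cervical epithelium only; proximal: buccal only
  i <- arch == "distal_epithelial_hyperM"
  expect_true(all(TD[i, "delta_epi_cervical"] == e))
  expect_true(all(TD[i, setdiff(colnames(TD), "delta_epi_cervical")] == 0))
  i <- arch == "proximal_epithelial_hyperM"
  expect_true(all(TD[i, "delta_epi_buccal"] == e))
  expect_true(all(TD[i, setdiff(colnames(TD), "delta_epi_buccal")] == 0))
  # null CpGs have exactly zero effect everywhere
  expect_true(all(TD[arch == "null", ] == 0))
  # exact consistency: delta = mu(current) - mu(never)
  for (t in names(truth$mu))
    expect_equal(truth$mu[[t]][, , "current"] - truth$mu[[t]][, , "never"],
                 truth$delta[[t]])
})

test_that("ex-smoker means interpolate by the attenuation fraction", {
  full <- build_truth(sim_config(n_cpgs = 50,
    archetype_sizes = c(epithelial_hypoM = 50), exsmoker_attenuation = 1,
    tissues = "buccal", seed = 3))
  expect_equal(full$mu$buccal[, , "ex"], full$mu$buccal[, , "never"])
  none <- build_truth(sim_config(n_cpgs = 50,
    archetype_sizes = c(epithelial_hypoM = 50), exsmoker_attenuation = 0,
    tissues = "buccal", seed = 3))
  expect_equal(none$mu$buccal[, , "ex"], none$mu$buccal[, , "current"])
  half <- build_truth(sim_config(n_cpgs = 50,
    archetype_sizes = c(epithelial_hypoM = 50), exsmoker_attenuation = 0.5,
    tissues = "buccal", seed = 3))
  expect_equal(half$mu$buccal[, , "ex"],
               half$mu$buccal[, , "never"] + 0.5 * half$delta$buccal)
})

test_that("invalid configurations are rejected with diagnostics", {
  expect_error(sim_config(n_cpgs = 10, archetype_sizes = c(null = 5)),
               "sum to n_cpgs")
  expect_error(sim_config(effect_size = 0.9), "effect_size")
  expect_error(sim_config(exsmoker_attenuation = 1.5), "attenuation")
  expect_error(sim_config(archetype_sizes = c(weird = 10), n_cpgs = 10),
               "unknown archetype")
})

test_that("noiseless bulk is the exact linear compartment mixture", {
  cfg <- sim_config(n_cpgs = 40, archetype_sizes = c(
    epithelial_hypoM = 10, immune_hypoM = 10,
    distal_epithelial_hyperM = 0, proximal_epithelial_hyperM = 0, null = 20),
    n_samples = 25, noise_precision = Inf, seed = 9)
  truth <- build_truth(cfg)
  ds <- simulate_dataset(truth)
  for (t in cfg$tissues) {
    comps <- tissue_compartments(t)
    sheet <- ds$sheet[[t]]
    f <- ds$fractions[[t]][[comps[1]]]
    for (j in seq_len(nrow(sheet))) {
      mu <- truth$mu[[t]][, , sheet$smoking_type[j]]
      m <- f[j] * mu[, comps[1]] + (1 - f[j]) * mu[, comps[2]]
      expect_equal(unname(ds$beta[[t]][, j]), unname(m), tolerance = 1e-12)
    }
  }
})

test_that("the same seed reproduces the dataset exactly, per tissue", {
  cfg <- sim_config(n_cpgs = 30, archetype_sizes = c(null = 30),
                    n_samples = 10, seed = 5)
  ds1 <- simulate_dataset(build_truth(cfg))
  ds2 <- simulate_dataset(build_truth(cfg))
  expect_identical(ds1, ds2)
  # per-tissue substreams: simulating only buccal gives the same buccal data
  cfg_b <- sim_config(n_cpgs = 30, archetype_sizes = c(null = 30),
                      n_samples = 10, tissues = "buccal", seed = 5)
  ds_b <- simulate_dataset(build_truth(cfg_b))
  expect_equal(ds_b$beta$buccal, ds1$beta$buccal)
})

test_that("observed betas are unbiased for the expected mixture value", {
  cfg_noisy <- sim_config(n_cpgs = 200, archetype_sizes = c(null = 200),
                          n_samples = 100, tissues = "buccal", seed = 11)
  cfg_clean <- cfg_noisy; cfg_clean$noise_precision <- Inf
  truth <- build_truth(cfg_noisy)
  obs <- simulate_dataset(truth, cfg_noisy)$beta$buccal
  m <- simulate_dataset(truth, cfg_clean)$beta$buccal
  d <- as.numeric(obs - m)
  se <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 3 * se)
  # per-cell noise scale matches Beta(m*k, (1-m)*k)
  expect_equal(stats::sd(d), mean(sqrt(m * (1 - m) / 201)), tolerance = 0.05)
})

test_that("expected bulk beta decreases with pack-years under a dose slope", {
  cfg <- sim_config(n_cpgs = 10, archetype_sizes = c(epithelial_hypoM = 10),
                    effect_size = 0.1, dose_slope = 0.002,
                    noise_precision = Inf, n_samples = 80,
                    tissues = "buccal",
                    fraction_distributions = list(buccal = c(5000, 5000)),
                    seed = 13)
  truth <- build_truth(cfg)
  ds <- simulate_dataset(truth)
  cur <- ds$sheet$buccal$smoking_type == "current"
  py <- ds$sheet$buccal$pack_years[cur]
  for (i in seq_len(10)) {
    r <- stats::cor(ds$beta$buccal[i, cur], py, method = "spearman")
    expect_lt(r, 0)
  }
})

test_that("simulated references obey the discriminative-selection rule", {
  truth <- small_buccal()$truth
  ref_all <- simulate_reference(truth, "buccal")
  expect_equal(ref_all, truth$mu$buccal[, , "never"])
  ref20 <- simulate_reference(truth, "buccal", 20)
  disc <- abs(ref_all[, 1] - ref_all[, 2])
  sel <- rownames(ref20)
  expect_gte(min(disc[sel]), max(disc[setdiff(names(disc), sel)]))
  expect_error(simulate_reference(truth, "buccal", 1000), "available")
})
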