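# Shared fixtures, built lazily once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# The default synthetic study: 3 tissues x 300 samples, 500 CpGs
# (100 per archetype + 100 null), effect 0.2, kappa = 200.
default_study <- function() fixture("default_study", function() {
  cfg <- sim_config(seed = 42)
  truth <- build_truth(cfg)
  ds <- simulate_dataset(truth)
  list(cfg = cfg, truth = truth, ds = ds)
})

# A small single-tissue (buccal) study for cheap unit tests.
small_buccal <- function() fixture("small_buccal", function() {
  cfg <- sim_config(
    n_cpgs = 60,
    archetype_sizes = c(epithelial_hypoM = 15, immune_hypoM = 15,
                        distal_epithelial_hyperM = 0,
                        proximal_epithelial_hyperM = 15, null = 15),
    n_samples = 60, tissues = "buccal", seed = 42)
  truth <- build_truth(cfg)
  ds <- simulate_dataset(truth)
  list(cfg = cfg, truth = truth, ds = ds)
})

# Brute-force Holm oracle via closed testing with Bonferroni local tests:
# adjusted p_i = max over subsets S containing i of |S| * min_{j in S} p_j,
# capped at 1. Equivalent to step-down Holm.
holm_brute <- function(p) {
  m <- length(p)
  adj <- numeric(m)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), m))
  for (i in seq_len(m)) {
    best <- 0
    for (s in seq_len(nrow(subsets))) {
      S <- unlist(subsets[s, ])
      if (!S[i]) next
      best <- max(best, sum(S) * min(p[S]))
    }
    adj[i] <- min(1, best)
  }
  adj
}

# Brute-force AUC by pair enumeration.
auc_brute <- function(scores, labels) {
  cases <- scores[labels]; controls <- scores[!labels]
  tot <- 0
  for (x in cases) for (y in controls)
    tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(cases) * length(controls))
}

# Independent lm()-based delta-beta oracle.
delta_oracle <- function(y, f, groups, at) {
  fits <- lapply(c("current", "never"), function(g) {
    stats::lm(y[groups == g] ~ f[groups == g])
  })
  v <- vapply(fits, function(m) sum(stats::coef(m) * c(1, at)), numeric(1))
  v[1] - v[2]
}
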