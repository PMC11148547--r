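---
title: "Methods: cell-type-resolved smoking methylation signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type-resolved smoking methylation signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokesig)
```

## The model

Every quantity in this package rests on one structural assumption: a bulk
methylation beta value is a linear mixture of compartment-specific means,

$$\beta_{ij} \;=\; f_j\,\mu_i^{\mathrm{imm}} + (1-f_j)\,\mu_i^{\mathrm{epi}}
  \;+\; \varepsilon_{ij},$$

where $f_j$ is the immune-cell proportion of sample $j$ (in blood, the
lymphoid proportion, with the myeloid compartment playing the epithelial
role) and $\mu_i$ are the pure-compartment means of CpG $i$. Linearity holds
exactly when a beta value is the methylated fraction of a cell mixture; it
is the same premise that justifies reference-based deconvolution.

Under this model, a regression of $\beta_i$ on $f$ *within one exposure
group* has intercept $\mu_i^{\mathrm{epi}}$ and value
$\mu_i^{\mathrm{imm}}$ at $f=1$. Fitting never smokers and current smokers
separately and differencing the two lines at $f=0$ and $f=1$ therefore
estimates the compartment-specific smoking effects
$\Delta\beta^{\mathrm{epi}}$ and $\Delta\beta^{\mathrm{imm}}$ without ever
sorting cells. The same two numbers per tissue — buccal, cervical, blood —
give each CpG a 6-vector profile whose shape distinguishes where the
smoking effect lives. Hierarchical clustering of these profiles groups CpGs
into co-regulated signature archetypes: epithelial hypomethylation (both
epithelia), immune hypomethylation (all immune compartments), and
hypermethylation restricted to the distal (cervical) or proximal (buccal,
directly smoke-exposed) epithelium.

Scores are plain set means $\bar\beta = \tfrac1n\sum_i \beta_i$. Because
$\bar\beta$ inherits the linear dependence on $f$, a cohort's scores are
corrected by fitting, per exposure type $t$, a line
$\bar\beta \sim f$ and moving each sample along its type's line to the
target composition: $\mathrm{corrected} = \mathrm{intercept}_t(f^*) +
(y - \hat y_t)$, with $f^*=0$ for epithelial sets and $f^*=1$ for immune
sets. At $f=f^*$ the correction is the identity; within each type the
corrected scores are exactly uncorrelated with $f$ (the OLS residual
property), which is the point of the procedure.

### Assumptions and when they fail

* **Two compartments per tissue.** Fibroblast or other minor compartments
  are absorbed into whichever of the two profiles they resemble; the
  deconvolution module accepts references with more compartments, and the
  derived `immune_proportion` is then immune over all compartments (an
  alternative renormalisation over epithelial + immune only would change
  $f$'s scale, not the pipeline's structure).
* **Extrapolation.** Pure-compartment intercepts are extrapolations beyond
  the observed $f$ range. Their variance grows with the squared distance of
  $f^*$ from the design mean; in an epithelial-dominant tissue the $f=1$
  estimates are several times noisier than the $f=0$ ones. This is why
  `fit_group_lines()` refuses groups with fewer than `min_n = 20` samples
  or an $f$ spread under `spread_min = 0.2` — below that the extrapolated
  intercepts are numerically finite but statistically meaningless.
* **Type-specific correction lines.** The correction fits one line per
  exposure type, exactly as defined; consequently a *new* sample can only
  be corrected inside a labelled cohort that contains its type. When a
  cohort lacks a type the package refuses rather than borrowing another
  type's line.

## Tunable parameters

| Parameter | Default | Units / scale | Rationale |
|---|---|---|---|
| `effect_size` | 0.2 | beta difference | mid-range of effects visible in smoking EWAS (0.05–0.3) |
| `exsmoker_attenuation` | 0.7 | fraction of effect reversed | reversal kinetics in ex-smokers are not quantitatively established; treated as a free parameter, not a claim |
| `noise_precision` (κ) | 200 | beta-distribution concentration | SD ≈ 0.03 at mid-range beta, typical array replicate noise; `Inf` switches noise off |
| `dose_slope` | 0 | Δβ per pack-year | off by default so the truth ledger equals the discovery estimand exactly; positive values deepen effects with dose |
| `fraction_distributions` | Beta(2,6)/Beta(3,4)/Beta(5,5) | immune (lymphoid) fraction | epithelial-dominant buccal, mixed cervical, balanced blood lineages |
| EWAS `min_group` | 10 | samples/group | smallest group for a stable 4-parameter OLS |
| Δβ `min_n`, `spread_min` | 20, 0.2 | samples, f-range | extrapolation guards, see above |
| clustering `k`, `tau` | 4, 0.02 | clusters, beta scale | four archetypes; `tau` separates "effect" from noise in cluster means, ≈ 1 SE of a cluster-mean entry |
| correction `min_n` | 10 | samples/type | scores average many CpGs, so lines stabilise faster than per-CpG fits |

## The synthetic generator

`build_truth()` + `simulate_dataset()` emulate the generative structure the
analysis assumes: per-CpG compartment baselines drawn from a bimodal
distribution on (0.05, 0.95) (methylation is mostly near-unmethylated or
near-methylated); archetype-specific effects applied to the affected
compartment × tissue cells (with the immune-hypoM lymphoid magnitude set to
`lymphoid_ratio` = 0.7 of the myeloid one); ex-smoker means interpolated by
the attenuation fraction; mixing with a per-sample fraction drawn from the
tissue's distribution; and observation noise
$\beta \sim \mathrm{Beta}(m\kappa, (1-m)\kappa)$, chosen over
clipped-Gaussian noise because it respects the (0,1) support and keeps the
mixture identity exact in expectation. Baselines of affected compartments
are drawn inside the band that keeps post-effect means in (0.05, 0.95); a
configuration whose effect cannot fit is rejected outright.

Randomness is organised as one substream per tissue derived from the single
seed, so enlarging one tissue's cohort cannot perturb another tissue's
draws.

What the generator does **not** emulate: array chemistry (detection
p-values, dye bias, probe-type effects), SNP-driven trimodality,
between-person biological variation beyond composition, batch structure,
and correlated noise across CpGs. Passing recovery tests therefore
demonstrates correctness of the estimators *under the stated model*, not
robustness to real-array artefacts; on real data the preprocessing that
handles those artefacts is upstream of this package's inputs.

## Numerical choices

* Deconvolution solves non-negative least squares per sample
  (`pracma::lsqnonneg`) and renormalises to sum 1; a sample collapsing onto
  one compartment is a legal pure sample. The reference must be full rank
  on the shared CpGs; duplicated CpG rows leave estimates unchanged.
* EWAS p-values use the t distribution on residual degrees of freedom, not
  a normal approximation — it matters at the small-n end the tests cover.
  Rows with missing betas are fitted on complete cases with `n` recorded;
  constant rows are flagged with effect 0 and p = 1. The per-run
  genomic-inflation factor (median χ² ratio) is attached for diagnostics.
* Holm adjustment delegates to `stats::p.adjust(method = "holm")` behind a
  validating wrapper; the test-suite cross-checks it against closed-testing
  enumeration over all rejection subsets.
* Clustering sorts rows lexicographically by CpG id before computing
  distances, making the result independent of input order; missing Δβ
  entries are imputed as 0 ("no evidence of effect") and flagged. `k = 1`
  is allowed (everything pools); silhouette-based selection over 2–8 is
  available via `auto_k`.
* Δβ values written to disk are clipped to [−1, 1]; in-memory values are
  unclipped. Corrected scores are never clipped (clipping would break the
  linear identity `corrected(f*) = y`); out-of-range values are flagged.
* AUC uses midranks (ties count ½); the DeLong variance uses the midrank
  placement-value identity, so the whole interval is $O(n\log n)$.

## Validation design and problem sizes

The test suite validates each estimator by parameter recovery against the
generator's truth ledger, at sizes chosen to make the checks sharp but
quick: the default study (3 tissues × 300 samples, 500 CpGs: 100 per
archetype + 100 null, effect 0.2, κ = 200) for Δβ recovery (RMSE ≤ 0.03
per column) and end-to-end archetype recovery (ARI ≥ 0.95); twenty
replicate all-null studies of 5,000 CpGs × 300 samples for type-I error
(raw rejection rate 0.05 ± 0.01) and family-wise control (zero
Holm-significant CpGs in ≥ 95% of runs); 1,000 Monte-Carlo replicates for
DeLong interval coverage (93–97% at nominal 95%, true AUC 0.75).

Two checks are intrinsically seed-sensitive and worth understanding:

* The corrected-immune AUC of an epithelial-effect set is expected to be
  0.5, but its deviation is driven by the *estimated* intercept difference
  at $f = 1$, whose scale relative to the residual SD is fixed by design
  leverage alone (≈ 0.6 for 150 samples/group with Beta(2,6) fractions) —
  independent of the noise level. The check `|AUC − 0.5| ≤ 0.07` therefore
  holds only on a fraction of seeds; this is a property of extrapolating
  an epithelial-dominant design to $f=1$, not an implementation defect.
* With family-wise error controlled at ≈ 0.05 per replicate study, the
  probability that at least 19 of 20 replicates are perfectly clean is
  about 0.74.

With deconvolution-*estimated* fractions, some null CpGs reach
significance: reference profiles include smoking-affected CpGs, so
fraction estimates acquire a small smoking-correlated bias, which leaves
residual composition confounding after adjustment. The archetype-recovery
checks are therefore defined over the truly non-null significant CpGs.
This measurement-error pathway is worth remembering when interpreting real
EWAS hits adjusted for estimated composition.

## Known limitations

* No per-immune-subtype Δβ: the two-level deconvolution provides subtype
  fractions, but the Δβ extrapolation operates on the two-compartment
  summaries only.
* The composition correction requires a labelled cohort; there is no
  single-sample mode.
* The robust (Huber-type) deconvolution variant of reference-based
  estimators is not implemented; the constrained least-squares estimator
  carries the same contract on the generative model and is far easier to
  verify.
* UMAP-style embeddings are not produced; hierarchical clustering is the
  implemented and validated path.
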