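---
title: "Methods: antioxidant-capacity biomarker discovery with acbtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: antioxidant-capacity biomarker discovery with acbtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acbtools)
```

## The problem and the model

Sensitivity of cancer cells to ROS-inducing drugs is governed not by any
single antioxidant gene but by the coordinated expression of the whole
redox-buffering axis: NADPH regeneration, glutathione synthesis and
recycling, the thioredoxin system, and carbonyl/quinone detoxification.
`acbtools` encodes the corresponding discovery pipeline:

1. **Per-layer association.** For every feature $g$ of an omics layer
   (expression in $\log_2(\mathrm{TPM}+1)$, or normalized protein), the
   sample Pearson correlation $r_g$ between the feature and
   $\ln \mathrm{EC}_{50}$, with the two-sided p-value from
   $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom. Missing
   entries are dropped pairwise; features that are constant (or have
   fewer than 4 complete pairs) are skipped and logged, never silently
   reported as $r = 0$.
2. **Rank combination.** Within each layer, features are ranked by
   ascending p (average ranks on ties). The expression and proteomics
   layers are then restricted to their shared genes, *re-ranked within
   that overlap universe*, and the two ranks averaged. Selection keeps
   genes with average rank strictly below a cutoff (default 38, the
   stringent threshold that defines the packaged 15-gene `ACB15` set).
3. **Scoring.** A sample's signature score is the unweighted arithmetic
   mean of the signature genes' expression on the common
   $\log_2(\mathrm{TPM}+1)$ scale. Z-scoring is used only for heatmap
   displays (`zscore_genes`), never for scoring, because cross-entity
   comparisons against a reference cell line's absolute level require
   unscaled common units.
4. **Compound similarity.** Each compound is mapped to the vector of
   per-signature-gene correlations with its response (AUC) across the
   panel; compounds are ranked by the Euclidean distance of that vector
   to the reference drug's vector, and enrichment of reactive-annotated
   compounds at small distances is quantified by a ROC construction and
   by fold enrichment below a cutoff.

The sensitive direction is positive throughout: the signature is
*repressed* in sensitive lines, so low score accompanies low
$\mathrm{EC}_{50}$ and gene-level correlations with
$\ln \mathrm{EC}_{50}$ are positive.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `transform` | `"ln"` | — | EC50 is correlated on the natural-log scale; AUC passes through unchanged |
| `avg_rank_cutoff` | 38 | rank | strict upper bound for signature selection |
| `p_cutoff` (methylation screen) | 0.001 | — | strict per-feature screen for a single layer |
| `hill_bounds` | (-10, 10) | — | Hill-slope box for 4PL fitting |
| `flat_tol` | 1e-6 | viability % | below this response range, "no dose response" |
| `n_nearest` / `cutoff` | — | count / distance | enrichment set definition (strict `<` for distance) |

No multiple-testing correction enters selection: the method selects by
rank, not by FDR, which makes the cutoff a direct statement about list
position rather than error rate. (A BH-adjusted column can be added for
reporting from the returned p-values with `p.adjust`.)

## The synthetic generator

`generate_panel()` emulates the study design the pipeline targets: a
panel of 31 cell lines by 2,000 genes carrying a planted block of 15
co-regulated genes whose mean correlates with $\ln \mathrm{EC}_{50}$ at
$r = 0.86$, plus a proteomics layer that is the expression layer with
independent Gaussian noise (SD 0.5 by default).

The planted block loads on one latent standard-normal factor $z$:
$g_j = 6 + \sqrt{w}\,z + \sqrt{1-w}\,\varepsilon_j$ with pairwise
correlation $w$ (`within_block_r`, default 0.6). The block mean then
correlates with $z$ at
$\rho_{\max} = \sqrt{wk/(wk + 1 - w)}$ for block size $k$, and
$\ln \mathrm{EC}_{50} = \alpha z + \sqrt{1-\alpha^2}\,u$ with
$\alpha = r_\mathrm{target}/\rho_{\max}$ calibrates the score–sensitivity
correlation *analytically* — no rejection sampling, so generation is
deterministic and fast, and an unattainable `target_r` (beyond
$\rho_{\max}$) errors out instead of silently falling short. EC50 values
are $e^{\ln \mathrm{EC}_{50}}$ micromolar (geometric mean 1 µM, log-SD 1),
strictly positive. Background genes are independent $N(5, 1)$ noise on the
$\log_2(\mathrm{TPM}+1)$ scale ("standard" SD-1 noise; the positive means
keep the floor at 0 from effectively ever binding, since negative values
are more than 5 SDs out). One master seed drives everything, with fixed
offsets per component (panel: seed+1, compound library: seed+2), so
identical configurations are byte-identical.

`generate_compound_library()` gives reactive compounds AUC vectors that
are noisy increasing transforms of the panel's signature score (signal and
noise in a 1:1 ratio by default, `auc_noise_sd = 1`) and inert compounds
independent noise, both affinely mapped to a CTRP-like AUC scale (8 ± 2);
the designated reference compound's AUC is a rescaling of the panel's
$\ln \mathrm{EC}_{50}$ itself. Note one deliberate asymmetry: reactive
compounds track the *score* while the reference tracks *measured
sensitivity*; the two coincide only as `target_r` approaches 1, so a
zero-noise reactive compound approaches — but does not exactly reach —
the reference's correlation vector unless the planted correlation is
near-perfect.

`generate_dose_response()` draws replicate viabilities from the 4PL model
plus Gaussian noise, and `generate_growth_counts()` inverts the GR formula
in closed form ($x_c = x_0\,2^{\log_2(\mathrm{GR}+1)\log_2 f}$ for control
fold-growth $f$), so `compute_gr()` round-trips exactly when noise is off.

**What the generator does not emulate.** Real expression data have
gene-specific means/variances, heavy tails, batch structure and
library-size artifacts; real proteomics coverage is partial and missing
not-at-random; methylation β-value distributions and RNS/ROS assay
readouts are not simulated at all. Passing tests on this generator
demonstrate that the machinery is correct and calibrated under its stated
model, not that the biological signal in any particular dataset is as
clean.

## Numerical choices

- **4PL fitting** uses bounded Levenberg–Marquardt in the
  $(\,\mathrm{bottom},\ \mathrm{span},\ \log_{10}\mathrm{EC}_{50},\
  \mathrm{hill}\,)$ parametrization, span $\ge 0$ enforcing
  top $\ge$ bottom. Start values: top/bottom from the extremes of
  per-concentration mean viability, $\mathrm{EC}_{50}$ at the
  concentration nearest the half-range, hill $=1$;
  $\log_{10}\mathrm{EC}_{50}$ is boxed to $[\min c/100,\ \max c \times
  100]$. Because the model depends on concentration only through
  $\log_{10} c - \log_{10}\mathrm{EC}_{50}$ and start/bounds shift with
  the data, rescaling all concentrations by $k$ scales the fitted EC50 by
  exactly $k$. Non-convergence returns the best-found parameters with
  `converged = FALSE`; a hard optimizer failure falls back to bounded
  quasi-Newton from the same start. Curves whose mean-viability range is
  below `flat_tol` abort with "no dose response" rather than returning an
  arbitrary EC50.
- **p-values** at $|r| = 1$ are floored at the smallest representable
  positive double instead of 0, keeping downstream rank computations
  well-defined.
- **Tie-breaks** are deterministic everywhere: average ranks on tied
  p-values, lexicographic compound id on tied distances, lexicographic
  gene symbol in greedy reduction, and items sorted by id before
  clustering.
- **ROC area.** The stored curve is the screening construction (x = rank
  fraction, y = cumulative fraction of reactive compounds recovered, plus
  a within-prefix precision column), but the summary `roc_auc` is the
  standard threshold-sweep area over (FPR, TPR) with tied distances
  grouped. The two disagree as summaries — a perfect ranking scores
  $1 - R/2N$ under the rank-fraction construction but exactly 1 under the
  standard sweep — and the standard definition was chosen so that perfect
  separation, label reversal and random rankings behave canonically and
  the value matches a brute-force confusion-matrix sweep.
- **Relative distance** is distance divided by the maximum observed
  distance in the profiled library; it is reported for orientation only
  and never used for cutoffs, which are always on absolute distance
  (strict `<`) or on a nearest-k count.
- **Greedy reduction** stops when no single removal improves $|r|$ or two
  genes remain. The published 11-gene reduction is the *outcome* fixture
  (`ACB11`); the iteration rule itself is this package's reconstruction,
  since only the outcome, not the protocol, is public.

## Problem sizes in the test suite

The suite validates calibration at the sizes where the checks are
sharpest while staying quick: 25 panels of 200 samples by 2,000 genes for
signature recovery, a 50-sample by 2,000-gene panel for null p-value
calibration, 25 end-to-end compound screens at the published class
balance (543 compounds, 125 reactive) on 31-sample panels, 20 noisy
dose-response fits, 20 reduction replicates, and brute-force oracle
comparisons (complete-linkage agglomeration at $n \le 12$, 10,000-sample
permutation nulls at $n = 10$). The full suite and the acceptance script
each run in well under a minute on one CPU.

## Known limitations

- Methylation is screened per-layer by p-value only; it is never
  rank-combined with expression/proteomics (by design, matching the
  two-layer combination rule), and metabolomics is likewise analyzed with
  the same machinery but reported separately.
- Euclidean distance on partially missing correlation vectors is
  undefined here; compounds with undefined entries are dropped with a
  log, not imputed.
- `fit_4pl` reports EC50 from viability curves; GR-based potency metrics
  (GR50 fitting) are out of scope, as is any drug-combination synergy
  analysis.
- Gene identifiers are plain HGNC symbols with no alias resolution
  (AIFM2 is the symbol used for FSP1); cross-platform unit harmonization
  (e.g. RPKM to $\log_2(\mathrm{TPM}+1)$ via `rpkm_to_log2tpm`) is the
  caller's responsibility before cross-cohort scoring.
- The OxD computation is the two-point control normalization; full
  instrument-corrected probe equations are not reproduced.
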