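# acbtools

Biomarker discovery for redox-targeting (ROS-inducing) drugs in cancer
cell-line panels.

Drugs that push cancer cells over their oxidative-stress threshold —
TXNRD1 inhibitors, ferroptosis inducers, other electrophilic compounds —
keep failing in unstratified trials because there is no good marker for
which tumors can and cannot buffer the insult. One successful strategy is
to screen a panel of cell lines with the drug, correlate every gene's
expression (and protein level) with the measured sensitivity, and combine
the evidence across omics layers into a small multi-gene signature of
*antioxidant capacity*: cells that constitutively repress the whole
NADPH-regeneration / glutathione / thioredoxin / detoxification axis are
the sensitive ones. `acbtools` implements that whole analysis as a tested,
reusable R pipeline, together with the assay metrics that feed it and a
synthetic-data generator with planted ground truth so every stage can be
validated without any external download.

## What it computes

**Rank-combined association.** For each gene *g* and each omics layer, the
Pearson correlation r(x_g, ln EC50) with its two-sided p-value from
t = r sqrt((n-2)/(1-r^2)). Genes are ranked by ascending p within each
layer (average ties), ranks are averaged across the expression and
proteomics layers over their shared genes, and the signature is the set of
genes with average rank strictly below a cutoff (default 38). The packaged
`ACB15` signature (ME1, PGD, UGDH, GCLM, GSR, SLC7A11, TXN, AIFM2, CBR1,
BLVRB, AKR1C1, AKR1C3, PTGR1, ALDH3A1, CYP4F11) and its `ACB11` reduction
are available via `load_builtin_signature()`.

**Signature scoring and reduction.** A sample's score is the unweighted
mean log2(TPM+1) expression of the signature genes. `reduce_signature()`
performs greedy backward elimination, dropping at each step the gene whose
removal most improves |r(score, ln EC50)|. `responder_fraction()` computes,
per cancer entity, the fraction of tumors scoring at or below a sensitive
reference cell line.

**Compound similarity in signature-correlation space.** Every compound in
a screen is represented by the vector of correlations between each
signature gene's expression and the compound's AUC across the panel; the
Euclidean distance of that vector to the reference drug's vector ranks
compounds by mechanism similarity, and `roc_reactive()` /
`fold_enrichment()` quantify how strongly chemically reactive compounds
(Michael acceptors and similar electrophiles) concentrate at small
distances.

**Assay metrics.** `fit_4pl()` fits the four-parameter logistic
v = bottom + (top-bottom)/(1 + 10^(hill (log10 c - log10 EC50)))
("log(inhibitor) versus response, variable slope") and returns a classed
model object with `coef`/`predict`/`plot`/`residuals` methods.
`compute_gr()` evaluates the normalized growth rate
GR = 2^(log2(x_c/x0)/log2(x_ctrl/x0)) - 1 from nuclei counts, and
`compute_oxd()` normalizes a ratiometric roGFP2 readout between its DTT
(fully reduced, 0) and diamide (fully oxidized, 1) controls.

## Worked example

```r
library(acbtools)

cfg    <- synthetic_config(n_samples = 31, n_genes = 2000, seed = 1)
bundle <- generate_panel(cfg)            # expression + proteomics + EC50

ae <- associate_layer(bundle$expression, bundle$sensitivity)   # ln EC50
ap <- associate_layer(bundle$proteomics, bundle$sensitivity)
ca <- combine_layers(ae, ap)
print(ca, n = 5)
#> <combined_assoc> 2000 shared features, ranked by average rank
#>   feature_id r_expr r_prot  avg_r    p_expr    p_prot rank_expr rank_prot avg_rank
#> 1     g00392 0.8062 0.7839 0.7951 4.392e-08 1.823e-07         5         1        3
#> 2     g00710 0.8262 0.7764 0.8013 1.041e-08 2.845e-07         3         3        3
#> ...

sig <- select_signature(ca, avg_rank_cutoff = 38, name = "planted")
sum(bundle$truth %in% sig$genes)
#> 15                                    # all planted genes recovered

score <- score_samples(bundle$expression, sig)
cor(score, log(as.numeric(bundle$sensitivity)))
#> 0.877                                 # vs the planted target r = 0.86

lib <- generate_compound_library(bundle, sig, cfg)   # 543 compounds, 125 reactive
rk  <- rank_by_distance(compound_profiles(bundle$expression, sig, lib))
roc_reactive(rk)
#> <roc_enrichment> 543 compounds (125 reactive), ROC AUC = 1.000
fold_enrichment(rk, n_nearest = 33)$fold_enrichment
#> 4.34                                  # 33/33 nearest compounds reactive
```

Positive correlations are the sensitive direction throughout: the
signature genes are repressed in sensitive (low-EC50) lines, so low score
and low ln EC50 go together.

A thin command-line wrapper over the same functions ships in
`inst/cli/acb.R` (`Rscript acb.R simulate|associate|select|score|reduce|
fit-ec50|entity|drugsim ...`).

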