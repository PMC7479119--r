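# chezodr

Sequence-based prediction of **continuous protein disorder** expressed as
CheZOD Z-scores.

Most disorder predictors emit a binary order/disorder call. NMR chemical
shifts support something better: the CheZOD Z-score, a per-residue,
continuous measure of local order derived from secondary chemical shifts —
near 0 for fully disordered residues, above ~11 for regular secondary
structure, with Z = 8.0 the conventional order/disorder threshold.
`chezodr` is for structural bioinformaticians who want to train, apply and
evaluate a predictor of this continuum from sequence alone.

The package provides:

* **Database handling** — FASTA and a flat CheZOD per-residue Z-score
  format, the staged balancing filters (`accept_candidate()`, driven by
  the disorder content f_IDR5 and the assignment completeness ACSR) and
  greedy 50%-identity stripping used to build balanced training databases.
* **Featurization** — a frozen, versioned schema of 130 per-residue
  sequence features (windowed amino-acid composition, entropy, charge,
  hydropathy, Chou–Fasman propensities, hydrophobic clusters, repeats and
  short-linear-motifs), plus 27 optional alignment-profile features.
* **The regressor** — a feed-forward network (linear first hidden layer
  with an L2 activity penalty and training-time Gaussian noise, ReLU
  stack, linear output) trained with Adam on residue-level MSE in a
  10-fold cross-validation ensemble. Predictions are the 10-model mean
  `Z_pred`; the 10-model spread `s_Z` is calibrated against realized blind
  errors to give an expected error `Z_err`.
* **Disorder probabilities** — a two-component skew-normal mixture fitted
  to the pooled Z-score distribution,

  d(x) = f_D ψ(x; μ_D, σ_D, α_D) + (1 − f_D) ψ(x; μ_O, σ_O, α_O),

  with ψ the skew-normal density; a predicted Z with uncertainty Z_err is
  converted to a disorder probability p_D by integrating each component
  against the Gaussian uncertainty kernel, using a reference disordered
  fraction f_Dref = 0.333.
* **Evaluation** — Pearson/Spearman correlations, confusion counts, MCC,
  ROC and precision-recall areas (positive class = disordered), per-amino-
  acid Z distributions, and permutation feature importance.
* **Synthetic data** — a seeded generator of CheZOD-like databases with
  known segment structure and a learnable composition→disorder signal, so
  the whole pipeline is testable end to end without downloads.

## Worked example

Train an ensemble on a synthetic database and predict a new sequence:

```r
library(chezodr)

cfg <- synthetic_config(n_entries = 200, seed = 1)
db  <- generate_database(cfg)
ens <- train_ensemble(db, network_spec(), seed = 1)

# blind cross-validated performance
blind <- ens$blind[!is.na(ens$blind$z_obs), ]
correlations(blind$z_obs, blind$z_pred)
#> $pearson
#> [1] 0.7016292
#>
#> $spearman
#> [1] 0.5968929

# mixture of the pooled Z-scores and disorder probabilities
mix <- fit_mixture(pooled_zscores(db), seed = 1)
mix
#> <disorder_mixture> f_D = 0.3410
#>   disordered: mu 0.997 sigma 2.032 alpha 1.995
#>   ordered:    mu 10.951 sigma 1.961 alpha -1.943

entry <- generate_entry(cfg, "query", seed = 99)
res <- predict_ensemble(ens, entry)
res$p_d <- disorder_probability(res$z_pred, res$z_err, mix)
head(res, 3)
#>   resnum aa z_pred   s_z z_err    p_d
#> 1      1  K  1.415 1.843 2.063 0.9865
#> 2      2  S  1.495 1.805 2.063 0.9853
#> 3      3  P  2.013 1.647 2.063 0.9752
```

The blind Pearson correlation of 0.70 says the ensemble recovers most of
the planted composition→disorder signal. In the prediction, `z_pred` is
the ensemble-mean predicted Z-score (here ~1.4–2.0: strong disorder),
`s_z` the ensemble spread, `z_err` its calibrated expected absolute
error, and `p_d` the probability that the residue is disordered under the
fitted mixture (here ≈ 0.99).

## Command line

A thin CLI over the same functions ships at `inst/scripts/chezodr`
(subcommands `simulate`, `db-stats`, `db-filter`, `featurize`, `train`,
`predict`, `fit-mixture`, `eval`).

See the vignette `vignettes/disorder-prediction.Rmd` for the full model
description, design decisions and limitations.
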