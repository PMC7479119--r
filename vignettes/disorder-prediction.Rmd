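---
title: "Predicting continuous protein disorder from sequence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting continuous protein disorder from sequence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Intrinsically disordered proteins and regions (IDPs/IDRs) lack a stable
three-dimensional structure under native conditions, yet the degree of local
order varies continuously: structured domains contain flexible loops, and
disordered regions contain residual, fractionally populated structure. The
CheZOD Z-score quantifies this continuum per residue from NMR secondary
chemical shifts: values near 0 indicate full disorder, values above ~11
regular secondary structure, with 8.0 the conventional order/disorder
threshold. `chezodr` implements a sequence-based predictor of these
Z-scores: a per-residue feature representation, a cross-validated
feed-forward regression ensemble with calibrated uncertainty, and a
skew-normal mixture model that converts a predicted Z-score into a
probability of disorder.

## Database construction

Training data are CheZOD-style databases: protein sequences with one
observed Z-score per residue (missing values allowed for unassigned
residues). Two per-entry statistics drive database balancing:

* `f_IDR5`, the fraction of residues with Z < 5 — a disorder-content
  measure (`f_idr5()`);
* ACSR, the average number of assigned chemical shifts per residue — a
  data-completeness measure.

`accept_candidate()` implements the staged balancing rules (a seed stage
requiring `f_IDR5 > 0.5` and `ACSR > 2`, four progressively order-richer
stages with stricter ACSR demands, and a final structured-protein stage),
and `strip_identity()` removes sequence redundancy: entries are processed
greedily in input order and kept only if their pairwise identity to every
already-kept and reference entry stays at or below 50%. Identity is defined
as identical aligned positions under global alignment (match 1, mismatch 0,
linear gap −1, via `Biostrings::pairwiseAlignment`) divided by the shorter
sequence length. The alignment scheme and the greedy order are deliberate
design choices — the balancing procedure is order-dependent by nature, and
input order (the database's own order) is the only order that does not
require an extra convention. Boundary `f_IDR5` values (exactly 0.3, say)
satisfy no interval stage: all inequalities are strict, matching how the
rules are stated.

## Sequence features

Each residue is described by 130 sequence-intrinsic columns, extended to
157 when a multiple sequence alignment is supplied. The exact column list
is frozen in a versioned manifest (`feature_manifest()`, version 1,
mirrored in `inst/extdata/feature_manifest_v1.tsv`) so trained models and
feature matrices stay compatible. Groups:

* **composition** (89): frequencies of the 20 amino acids in sliding
  windows of 5, 11 and 21 residues; whole-sequence frequencies; windowed
  fractions of disorder-promoting (G,P,S,Q,E,K), order-promoting
  (W,I,F,Y,L,V) and aromatic residues.
* **physchem** (20): windowed Shannon entropy (bits), net charge at pH 7
  (K,R = +1; D,E = −1; H = +0.1), Kyte–Doolittle hydropathy, isoelectric
  point and Vihinen flexibility; lengths of the same-sign charge runs
  covering the residue; relative position, log distance to the nearer
  terminus, log sequence length.
* **structure** (17): windowed Chou–Fasman helix, sheet and turn
  propensities; a β-aggregation channel (hydropathy rescaled to [0,1],
  attenuated by side-chain charge, zeroed at Pro/Gly, then
  window-averaged) that plays the role of an aggregation-propensity
  predictor; hydrophobic-cluster length, distance to the nearest cluster
  and windowed cluster density from the binary V,I,L,F,M,Y,W mask (runs of
  at least two masked residues count as clusters).
* **pattern** (4): exact tandem repeats (period 1–6, at least 3 copies):
  indicator and copy count; overlap counts of a small bundled set of
  ELM-style short-linear-motif regular expressions (version 1); a
  low-complexity flag (window-21 entropy below 2.5 bits).
* **evolution** (27, optional): per query position of the alignment, the
  20 profile frequencies (rows weighted uniformly; gaps and unknowns
  excluded), profile entropy, gap fraction, query–profile agreement, the
  number of aligned rows, windowed profile entropy (windows 5 and 11), and
  conservation of the query's hydrophobicity class.

Windows are centred, truncated at the termini (no padding — inventing
boundary residues would bias terminal features), and normalized by the
number of valid residues they contain; unknown residues (`X`) are excluded
from both numerator and denominator. Window widths {5, 11, 21} span
local-to-segment context and are configurable. Features are standardized by
the mean and standard deviation of the training residues
(`fit_normalizer()`); training-constant columns are emitted as zeros.

## The regressor and the cross-validation ensemble

The regressor is a feed-forward network: a linear first hidden layer whose
response carries an L2 activity penalty (coefficient 1e-4 by default) and,
during training only, additive Gaussian noise with standard deviation 0.1;
then ReLU hidden layers; then a linear scalar output. Hidden widths default
to (40, 10, 25, 40, 8) without evolutionary features and
(128, 80, 20, 15, 10) with them. Training minimizes residue-level mean
squared error with Adam (learning rate 1e-4) for 100 epochs, batching 50
whole sequences per update; the train and test MSE are recorded after every
epoch and the weights at the test-MSE-optimal epoch are kept. "Batch of
50" is read as 50 sequences — the network consumes whole-protein feature
matrices — and "100 iterations" as 100 full passes; both are configurable
in `network_spec()`. Hidden layers use He initialization (Glorot for the
linear first layer); the output layer starts at zero weights with its bias
at the training-target mean, so that early training signal aligns
predictions with targets rather than fighting random initial output
variation — with a conservative learning rate and comparatively few
updates per training run, this initialization matters.

`train_ensemble()` runs the 10-fold protocol: entries are split randomly
into 10 folds of near-equal size; model *n* uses fold *n* for validation
(blind prediction), fold *n − 1* for testing (epoch selection; fold 10 for
model 1, the wraparound forced by disjointness), and the remaining 8 folds
for training. Each model fits its own normalizer on its training folds
only, so neither test nor validation residues leak into the normalization
statistics. The ensemble prediction for a new sequence is the mean of the
10 per-model predictions; their population standard deviation `s_Z`
estimates the precision. For database entries, only the model whose
validation fold contains the entry contributes its (blind) prediction.

Per-model seeds derive deterministically from the master seed, so the
whole procedure is reproducible end to end.

## Uncertainty calibration

Blind predictions supply pairs of precision (`s_Z`) and realized error
(|Z_obs − Z_pred|). `calibrate_error()` bins `s_Z` into deciles, averages
the absolute error per bin, and enforces a monotone non-decreasing mapping
by isotonic regression (`stats::isoreg`); lookups clamp to the end bins.
The calibrated `Z_err` feeds the disorder-probability integral below. The
spread is computed across all 10 models (each applying its own
normalizer): it measures ensemble disagreement, while the error comes from
the blind model only.

## The skew-normal mixture and disorder probabilities

Pooled observed Z-scores are strongly bimodal and are modelled as a
two-component skew-normal mixture

$$ d(x) = f_D\,\psi(x;\mu_D,\sigma_D,\alpha_D) +
          (1-f_D)\,\psi(x;\mu_O,\sigma_O,\alpha_O), $$

where $\psi(x;\mu,\sigma,\alpha) = (2/\sigma)\,\phi(z)\,\Phi(\alpha z)$
with $z = (x-\mu)/\sigma$ is the standard skew-normal density.
`fit_mixture()` maximizes the likelihood numerically (BFGS on an
unconstrained parametrization: log scales, logit weight) from five seeded
starts, initialized by moments of the data split at Z = 8 and jittered
across restarts; the lower-mean component is labelled disordered.
Degenerate outcomes — a component weight beyond 0.01/0.99 or component
means closer than half the pooled standard deviation — are flagged as
single-component data. Goodness of fit is summarized by the discrete
Hellinger distance between binned data and the model's bin masses; the
default binning (width 0.5 over [−6, 17]) is configurable because the
statistic is binning-sensitive.

A predicted Z-score with calibrated uncertainty is converted into a
probability of disorder by integrating each component against a Gaussian
uncertainty kernel:

$$ p_D = \frac{\pi_D}{\pi_D + \pi_O},\qquad
   \pi_S = w_S \int \psi(Z;\mu_S,\sigma_S,\alpha_S)\,
           \phi\!\left(\frac{Z - Z_{pred}}{Z_{err}}\right)\,dZ, $$

with state weights $w_D = f_{Dref} = 0.333$ and $w_O = 1 - f_{Dref}$, a
reference disordered fraction representing a generic proteome rather than
the balanced training database. The integral uses a fixed grid over
Z ∈ [−25, 35] with step 0.01 (the kernel's normalization cancels in the
ratio); kernels narrower than the grid step — including `Z_err = 0` —
evaluate the closed-form posterior ratio at `Z_pred` instead.

Two printed-form ambiguities in the source equations were resolved to the
standard statistical objects: the skew-normal density is used with its
$1/\sigma$ scale factor and a single factor 2, and the two states carry
complementary weights ($f_{Dref}$, $1 - f_{Dref}$) rather than the same
$f_D$ factor, without which the ratio would be constant in the weight.

**A monotonicity caveat.** $p_D$ is *not* globally monotone in $Z_{pred}$:
left of the disordered component's mode both component densities rise (the
disordered one faster), and far into the right tail the ordered
component's skew-suppressed tail falls below the disordered component's
Gaussian tail, so the posterior reverses at extreme Z where the mixture
carries negligible mass (density below ~1e-6). Through the decision
region — Z between roughly 3 and 12, spanning the 8.0 threshold — the
probability decreases monotonically for mixtures in the fitted regime, and
the test suite asserts exactly that.

## The synthetic data generator

`generate_database()` produces CheZOD-like databases with known ground
truth so that featurization, training, calibration, mixture fitting and
evaluation are all testable without downloads. Each entry alternates
latent ordered/disordered segments via a two-state Markov chain whose
leave rates are scaled so the stationary disordered fraction equals the
generative mixture's $f_D$ (default 0.36) while the mean stay probability
matches the persistence parameter (default 0.95, giving segments of a few
dozen residues). Residue letters are drawn from state-biased compositions:
disorder-promoting residues (G,P,S,Q,E,K) are enriched fourfold in
disordered segments and bulky hydrophobics (W,I,F,Y,L,V) in ordered ones,
echoing the observed per-amino-acid disorder propensities and making the
sequence-to-Z mapping learnable. Z-scores are drawn from the segment
state's skew-normal component (defaults: disordered μ = 1, σ = 2, α = +2;
ordered μ = 11, σ = 2, α = −2), using AR(1)-correlated standard-normal
innovations (lag-1 correlation 0.8) in the two-Gaussian skew-normal
representation. Serial correlation in the innovations makes Z vary
smoothly along the chain, as real profiles do, while preserving the
skew-normal marginal *exactly* — a moving average of finished draws would
shrink the marginal spread and pull the pooled histogram away from the
generative mixture. Entry lengths are uniform on 80–200 residues and
n = 200 entries is the default database size; at that size the pooled
histogram matches the generative mixture to a Hellinger distance below
0.05 and the full 10-model ensemble trains in minutes on one CPU, which is
the problem size the end-to-end tests and the acceptance script use.

What the generator does *not* emulate: long-range sequence correlations,
genuine evolutionary conservation (its toy MSAs are mutated copies of the
query), proline-specific context effects, and the ACSR/assignment
structure of real NMR data (ACSR values are drawn uniformly). Passing
end-to-end tests therefore demonstrate that the pipeline learns a planted
composition→disorder signal under realistic noise, not that it reaches
published accuracy on real proteins.

## Evaluation

`correlations()` (Pearson/Spearman, average ranks for ties),
`confusion_at_threshold()`, `mcc()` (0 by convention when a denominator
factor vanishes), `roc_auc()` (threshold sweep with ties grouped,
trapezoidal area — equal to the Mann–Whitney identity, which the tests
assert), `pr_auc()` (step interpolation, so constant scores score the
prevalence), and `per_aa_cdf()` implement the evaluation layer. The
positive class is disordered (Z < 8) throughout. Z-like scores are
evaluated by correlation directly; probability outputs by rank metrics.

`permutation_importance()` ranks features by the drop in squared Pearson
correlation when one feature column is shuffled (5 repetitions) while all
others stay fixed, computed per cross-validation model on its own blind
validation fold and averaged.

## Numerical choices and limitations

* Mixture likelihood evaluations floor densities at 1e-300; degenerate
  parameter points (non-positive or non-finite scales) are rejected with a
  large penalty rather than an error so BFGS line searches can recover.
* Calibration bins are s_Z deciles; with heavy ties, empty intervals route
  to the nearest populated bin. Fewer residues than bins reduce the bin
  count with a warning.
* `interpret_zscore()` uses half-open, lower-inclusive category boundaries
  ([3, 8), [8, 11)); `classify_disorder()` calls exactly 8.0 ordered,
  consistent with the strict inequality in `f_IDR5`.
* Identity stripping is order-dependent (greedy); a different input order
  can keep a different member of a redundant group.
* The training-run count at desk scale (tens of sequence batches) is far
  smaller than at full database scale; the zero-initialized output layer
  compensates, but absolute MSE levels remain initialization-sensitive
  even though correlations are stable.
* The 157-feature schema is a reconstruction honouring the stated groups
  and counts; it is versioned so that alternative schemas can coexist
  without breaking trained models.
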