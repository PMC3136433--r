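---
title: "Methods: PUK-SVM screening for cell-penetrating peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PUK-SVM screening for cell-penetrating peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Cell-penetrating peptides (CPPs) are short peptides (roughly 5–43 residues in
the compiled reference sets) that cross cell membranes, which makes them
candidate drug-delivery vehicles. Experimentally validated examples are
scarce and heavily imbalanced: the bundled reference data contain 111 known
CPPs but only 34 peptides experimentally shown *not* to penetrate, most of
them close analogs of known CPPs. `cppscreen` implements a complete in-silico
screening method around this data: physicochemical descriptors, training-set
construction under five imbalance strategies, a support vector machine with
the Pearson VII universal kernel trained by sequential minimal optimization,
scatter-search wrapper feature selection, and a candidate
generation/screening workflow.

# Descriptors

Every peptide is mapped to a fixed, ordered panel of 61 descriptors
(`feature_names()`): length, net/positive/negative charge, isoelectric
point, molecular weight, hydropathicity (GRAVY), the 20 per-residue counts,
the 20 per-residue percentages, four residue-group percentages, five further
mean property scales, net donated side-chain hydrogen bonds, and
Chou–Fasman secondary-structure fractions.

Design choices worth knowing:

* **Charge counting** is integer: positives are K, R and H (histidine counts,
  matching the residue classification used throughout the reference data),
  negatives are D and E; termini are excluded from the counts but included in
  the isoelectric-point model. Net charge is their difference.
* **Isoelectric point** solves the Henderson–Hasselbalch net-charge equation
  (free termini plus side chains C, D, E, H, K, R, Y, EMBOSS pKa set:
  N-term 8.6, C-term 3.6, C 8.5, D 3.9, E 4.1, H 6.5, K 10.8, R 12.5,
  Y 10.1) by bisection on pH ∈ \[0, 14\] to 0.001 pH. The charge is strictly
  decreasing in pH, so the root exists and is unique.
* **Property scales** are data, not code (`residue_scale()`):
  hydropathicity is Kyte–Doolittle, hydrophobicity the Eisenberg consensus,
  lipophilicity and the water–octanol partition coefficient the
  Fauchère–Pliska π values (kept as two panel entries because the panel
  definition lists both), amphiphilicity the Mitaku index, steric bulk the
  Charton parameter, side-chain bulk the Zimmerman bulkiness. All scale
  features are arithmetic means over residues (the GRAVY convention). Any
  complete 20-entry vector can be substituted.
* **Molecular weight** uses average residue masses plus one water,
  unmodified termini — the convention of standard peptide property
  calculators. C-terminal amidation recorded for the synthesized validation
  peptides is treated as metadata and never enters descriptors.
* **Net donated hydrogen bonds** is the sum over residues of side-chain
  donors minus acceptors from a packaged lookup (R +5, K +3, C/W +1, M −1,
  D/E −4, others 0); the backbone is excluded. The table is a swappable
  resource because published variants differ in detail.
* **Secondary structure** assigns each residue the state with the maximal
  Chou–Fasman propensity (ties broken helix > sheet > coil, which only
  matters for cysteine, whose sheet and coil propensities are equal). A
  per-residue propensity argmax is deliberately self-contained and
  deterministic; it is a coarse stand-in for a trained secondary-structure
  predictor and the three fraction features should be read accordingly.
* **Residue groups** partition the alphabet (positive K/R/H, negative D/E,
  polar uncharged S/T/N/Q/Y/C, hydrophobic A/V/L/I/M/F/W/P/G) so the four
  group percentages are well defined and sum to 100.
* **Normalization** is per-feature min–max to \[0, 1\], fitted on training
  rows only; constant features map to 0 and held-out values outside the
  training range are clamped. Inside cross-validation the normalizer is
  re-fitted per fold on the training part only.

# Training sets under class imbalance

`build_dataset()` implements five strategies: `unbalanced` (111 + 34),
`random_neg` (111 positives vs 111 Markov-generated peptides assumed
negative), `biological_neg` (111 vs 111 drawn without replacement from a
biological peptide pool), `oversample_neg` (111 vs 111 drawn with
replacement from the 34 known negatives) and `subsample_pos` (ten balanced
68-row sets of 34 resampled positives vs the 34 negatives).
With-replacement draws are uniform over source rows — no weighting scheme is
defensible from the available information. Rows are shuffled once under the
dataset seed; the shuffle belongs to the dataset, so downstream folds are
reproducible. Provenance tags keep the source peptide id for every row,
including resampled duplicates.

The packaged `biological_neg` pool is *synthetic*: background-model peptides
standing in for a real biological peptide set (the original set of 411
proteome-derived peptides is not reconstructible as an exact list). Real use
should supply a genuine pool via `read_fasta()`. Note that with resampled
datasets, duplicated rows appear on both sides of a cross-validation split;
reported CV accuracies for `oversample_neg` and `subsample_pos` are
optimistic in exactly the same way as the original reporting convention and
should be compared only within that convention.

# The classifier

The core estimator is a binary soft-margin SVM with the Pearson VII
universal kernel

$$K(x, z) = \frac{1}{\left[1 + \left(2\sqrt{2^{1/\omega}-1}\,\lVert x - z\rVert/\sigma\right)^2\right]^{\omega}}$$

with ω the tailing exponent (ω = 1 Lorentzian, large ω approaches Gaussian)
and σ the half-width. Defaults are ω = 1, σ = 1, C = 1 — the conventional
defaults of the kernel's reference implementation; no hyperparameter search
is prescribed by the method. The dual problem is solved by sequential
minimal optimization, implemented in C++ with a full error cache: the outer
loop examines KKT violators, the second choice maximizes |E₁ − E₂| over
non-bound multipliers, and remaining tie-breaks are randomized from an
explicit seed so training is reproducible and independent of R's global RNG.
With a PSD kernel the pair curvature η ≥ 0; the η = 0 edge (duplicate rows)
falls back to endpoint comparison of the dual objective. The solver stops
when a full sweep finds no violator at tolerance `tol` (default 1e-3;
oracle-comparison tests tighten this to 1e-8, where the dual objective
matches an exhaustive active-set enumeration to ~1e-15 relative).

Decision values \(f(x) = \sum_i \alpha_i y_i K(x_i, x) + b\) are the
canonical output; the label is CPP iff f(x) > 0, with exact zero assigned to
NON_CPP. No probability calibration is attempted. `cpp_classifier()` bundles
subset restriction + normalizer + SVM so that prediction from raw sequences
is one call, and serializes losslessly to versioned JSON (17 significant
digits, so reloaded models reproduce decisions bit for bit).

# Wrapper feature selection

`scatter_search()` searches subset space with the cross-validated accuracy
of the wrapped PUK-SVM (same family as the final classifier) as objective.
Structure: a seeded random initial population, hill-climb improvement by
single-feature add/remove (first improving move, step-capped), a reference
set split half by quality and half by diversity (greedy max–min Hamming
distance on indicator vectors), and pairwise combination in which features
shared by both parents are kept and features in exactly one parent survive
with probability 1/2. Termination: reference set unchanged for a full
generation, or the generation cap. Scores are memoized per subset; every
evaluation shares one fold seed (`cv_seed`) so candidates are comparable and
any reported score can be reproduced by `evaluate_subset()`. Ties prefer
fewer features, then lexicographic names.

The published description of the method fixes none of the search's budget
parameters, and selected-subset identity is not reproducible in principle
(the search is stochastic and the objective is nearly flat across many
subsets). The package default (`scatter_config()`: refset 10, population 40,
20 generations, 5 inner folds) is a faithful desk-scale rendering of the
algorithm. For the bundled end-to-end runs, `default_selection_config()`
applies a reduced budget chosen once for single-CPU interactivity —
population 16 / 5 folds / 5 generations for datasets up to 100 rows, and
population 12 / 3 folds / 3 generations above that (inner folds are fewer
than the 10 used for final reporting; final accuracies always come from
10-fold `cross_validate()`).

# Evaluation

`cross_validate()` uses stratified folds (with 34 negatives among 145 rows,
unstratified 10-fold splitting can produce folds with no negative at all),
pools out-of-fold predictions into a single confusion matrix, and reports
accuracy, per-class accuracies, class-weighted TPR/FPR, and ROC area. The
weighted TPR is algebraically identical to accuracy/100 — the panel follows
the reporting convention of the common machine-learning toolkits. ROC area
is the rank (Mann–Whitney) AUC of the pooled decision values, class-weighted
(which for two classes equals the plain AUC; the package computes both
one-vs-rest AUCs explicitly). Display rounding is half-up to two decimals;
computation is always full precision.

# Candidate generation and screening

The generator is a 0th-order Markov model: residues i.i.d. from a
20-dimensional frequency vector, lengths uniform on an inclusive range
(default 12–26). The packaged default frequency table is a representative
vertebrate (chicken-like) proteome composition, so screening needs no
external proteome; `estimate_frequencies()` rebuilds the model from any
user-supplied FASTA. Sampling is reproducible from an explicit seed and
leaves the global RNG untouched.

`screen_candidates()` composes generation, featurization and prediction,
ranks candidates by decreasing decision value and shortlists the extremes
(most-positive predicted CPPs, most-negative predicted non-CPPs). Extremity
is a documented convention — the original synthesis selection rule among
predictions was not recorded. Each run emits a manifest (seeds, generator,
model settings) sufficient to replay it exactly.

# What the synthetic checks do and do not show

The test suite validates the machinery against independent oracles:
an exhaustive dual-QP enumeration for the SMO solver, a 1e-4 pH grid scan
for the isoelectric point, chi-square goodness of fit for the generator at
n = 10,000, planted-informative-feature recovery (2 of 22 features, n = 200,
≥ 90% of seeds) for the scatter search, and closed-form/symmetry/PSD
identities for the kernel. Synthetic datasets have i.i.d. uniform features
and noiseless planted labels; real peptide descriptors are strongly
correlated (counts vs percentages vs charge) and labels are noisy, so
passing these checks demonstrates correctness of the algorithms, not
field performance. The end-to-end checks reproduce the published
cross-validation panel only within tolerance bands, seed-averaged (five
seeds for the 222-row datasets, the ten datasets for the subsampled
strategy), because the original fold assignments, solver settings and
search budgets are unknown.

# Known limitations

* Only the 20 canonical residues are handled; modified or non-canonical
  residues are rejected, not approximated.
* The secondary-structure fractions are propensity-argmax assignments, not
  predictions from a trained model.
* The hydrogen-bond table and property-scale choices follow standard
  published scales but the exact tables behind the original descriptor set
  are not fully documented; all are swappable data resources.
* Training is quadratic in dataset size (dense Gram matrix); the intended
  regime is the few-hundred-row scale of curated CPP data.
* Reported CV accuracy on resampled (duplicate-containing) datasets is
  biased upward; use `random_neg`/`biological_neg` style held-out designs
  for honest generalization estimates.
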