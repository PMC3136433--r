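# cppscreen

In-silico screening for **cell-penetrating peptides (CPPs)** — short
peptides able to cross cell membranes and carry cargo into cells. Validated
examples are scarce and imbalanced (the bundled reference data hold 111
known CPPs but only 34 experimentally confirmed non-penetrating analogs),
which makes naive classifiers trivially optimistic: predicting "CPP" for
everything already scores 76.55% on the compiled set. `cppscreen` is for
computational biologists and peptide chemists who want to rank candidate
sequences for synthesis with that imbalance handled explicitly.

The package implements the full method end to end:

* **Descriptors** — a fixed panel of 61 physicochemical features per
  peptide: length, integer charge counts (positives K/R/H, negatives D/E),
  isoelectric point (Henderson–Hasselbalch bisection, EMBOSS pKa set),
  average-mass molecular weight, GRAVY and five further residue-scale
  means, per-residue counts and percentages, residue-group percentages, net
  donated side-chain hydrogen bonds, and Chou–Fasman secondary-structure
  fractions; min–max normalized to [0, 1] on training data.
* **Dataset construction** — five class-imbalance strategies: unbalanced,
  balanced with Markov-random negatives, balanced with biological-pool
  negatives, balanced by oversampling the known negatives, and ten balanced
  sets subsampling the positives.
* **Classifier** — a soft-margin SVM with the Pearson VII universal kernel

  K(x, z) = 1 / [1 + (2·√(2^{1/ω} − 1)·‖x − z‖ / σ)²]^ω,

  trained by sequential minimal optimization (C++ core, seeded and
  deterministic), defaults ω = σ = C = 1. Decision values f(x) = Σᵢ αᵢyᵢ
  K(xᵢ, x) + b rank candidates; f > 0 is called CPP.
* **Feature selection** — scatter search over feature subsets, scored by
  cross-validated accuracy of the wrapped PUK-SVM (quality + diversity
  reference set, add/remove hill climbs, seeded combination).
* **Evaluation** — stratified k-fold cross-validation with pooled confusion
  matrices, class-weighted TPR/FPR and rank-based ROC area, plus
  majority-class baselines.
* **Screening** — generate candidates from a 0th-order Markov model of
  amino-acid composition (lengths uniform on 12–26), classify, rank, and
  shortlist extremes for synthesis, with a replayable run manifest.

## Worked example

```r
library(cppscreen)

load_bundled("cpp111")
#> <peptide_collection 'cpp111'> 111 peptides (CPP:111, NON_CPP:0, UNKNOWN:0)
majority_baseline(111, 34)
#> [1] 76.55172

## balance by resampling the 34 known negatives up to 111, then select
## features and cross-validate the PUK-SVM
d <- build_dataset("oversample_neg", seed = 1)
#> <cpp_dataset> strategy: oversample_neg, 222 rows (111 CPP / 111 NON_CPP), seed 1
sub <- scatter_search(d, default_selection_config(d, seed = 1))
sub$score            # inner-CV accuracy of the selected subset
#> [1] 0.8739
cross_validate(d, k = 10, seed = 1, features = sub$features)
#> Accuracy            91.44%
#>   CPP accuracy      90.99%
#>   Non-CPP accuracy  91.89%
#> True Positive Rate  0.9144
#> False Positive Rate 0.0856
#> ROC area            0.9718

## the same model family tested once on the unbalanced 145-peptide set
model <- cpp_classifier(d, features = sub$features, seed = 1)
evaluate_on(model, build_dataset("unbalanced"))
#> Accuracy            95.17%
#>   CPP accuracy      96.40%
#>   Non-CPP accuracy  91.18%
#> ...
```

The 10-fold CV accuracy (91.44% here; ~90% averaged over seeds) shows that
a balanced training set lets the PUK-SVM separate known CPPs from their
non-penetrating analogs, far above the 76.55% imbalance floor; the single
pass over the unbalanced compiled set is higher still because that set is
dominated by positives the model has seen.

For bulk screening, train on biological-pool negatives and rank random
candidates:

```r
m2 <- cpp_classifier(build_dataset("biological_neg", seed = 1), seed = 1)
screen_candidates(m2, n = 250, seed = 42, shortlist = c(4, 2))
#> <screening_result> 250 candidates: 6 predicted CPP, 244 predicted non-CPP
#> shortlist:
#>        id               sequence   label    decision rank
#>  cand0101           TSRRSKRRNKEA     CPP  0.39824126    1
#>  cand0007          PKTACTRRHVALA     CPP  0.13678919    2
#>  cand0238           ITMTALRRVPIK     CPP  0.08435764    3
#>  cand0190    CRAATMVLSQATVKGARVL     CPP  0.03702907    4
#>  cand0235 ETCGKFSYVSANLEPRINNDKP NON_CPP -1.17991264  250
#>  cand0149   GRLLPPIFEISEYQSCNVRF NON_CPP -1.15097049  249
```

Only 6 of 250 random peptides are called CPP, and the shortlisted positives
are the arginine/lysine-rich candidates — the charge and hydrogen-bonding
profile the selected features keep pointing at.

A thin command-line front end wraps the same functions
(`inst/cli/cppscreen.R`): `data`, `features`, `generate`, `build`, `train`,
`predict`, `screen`, `evaluate` subcommands.

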