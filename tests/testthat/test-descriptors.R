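test_that("composition counts and percents obey conservation", {
  comp <- aa_composition("RRRRRRRRR")
  expect_identical(unname(comp$counts[["R"]]), 9L)
  expect_equal(unname(comp$percents[["R"]]), 100)
  expect_true(all(comp$counts[setdiff(names(comp$counts), "R")] == 0))

  comp <- aa_composition("PMLKE")
  expect_true(all(comp$counts[c("P", "M", "L", "K", "E")] == 1))
  expect_true(all(comp$percents[c("P", "M", "L", "K", "E")] == 20))

  for (s in random_sequences(20, seed = 11)) {
    comp <- aa_composition(s)
    expect_identical(sum(comp$counts), nchar(s))
    expect_equal(sum(comp$percents), 100)
  }
})

test_that("charge counting uses K/R/H positive, D/E negative, no termini", {
  expect_equal(charge_features("RRRRRRRRR"),
               list(positive = 9L, negative = 0L, net = 9L))
  expect_equal(charge_features("PMLKE"),
               list(positive = 1L, negative = 1L, net = 0L))
  expect_equal(charge_features("TCSSNCQTCPCSSNNCQ"),
               list(positive = 0L, negative = 0L, net = 0L))
  expect_equal(charge_features("HHH")$positive, 3L) # histidine counts
})

test_that("isoelectric point matches a fine grid-scan oracle", {
  # termini-only case and a strongly basic case first
  for (s in c("GGGGGGGGGGGG", "RRRRRRRRR")) {
    expect_equal(isoelectric_point(s), pi_grid_oracle(s), tolerance = 2e-3)
  }
  expect_gt(isoelectric_point("RRRRRRRRR"), 11)
  for (s in random_sequences(25, seed = 7)) {
    expect_equal(isoelectric_point(s), pi_grid_oracle(s), tolerance = 2e-3)
  }
})

test_that("appending a basic residue never decreases pI", {
  for (s in random_sequences(10, seed = 3)) {
    expect_gte(isoelectric_point(paste0(s, "K")) + 1e-3, isoelectric_point(s))
  }
})

test_that("molecular weight equals residue-mass sums plus one water", {
  expect_equal(molecular_weight("G"), 75.07)
  expect_equal(molecular_weight("GG"), 132.12)
  # condensation identity
  for (i in 1:5) {
    s1 <- random_sequences(1, seed = i)
    s2 <- random_sequences(1, seed = i + 100)
    expect_equal(molecular_weight(paste0(s1, s2)),
                 molecular_weight(s1) + molecular_weight(s2) - 18.02)
  }
})

test_that("scale means follow the GRAVY convention", {
  expect_equal(scale_mean("RRRRRRRRR", "hydropathicity"), -4.5)
  expect_equal(scale_mean("IIIII", "hydropathicity"), 4.5)
  # homopolymer mean equals the residue value for every registered scale
  for (nm in residue_scale()) {
    sc <- residue_scale(nm)
    expect_equal(scale_mean("WWWW", sc), unname(sc[["W"]]))
  }
})

test_that("net donated hydrogen bonds are additive with backbone excluded", {
  expect_equal(net_donated_hbonds("GGGGGGGG"), 0)
  expect_equal(net_donated_hbonds("RRRRRRRRR"),
               9 * unname(residue_scale("net_hbond_donated")[["R"]]))
  s1 <- "ARNDW"
  s2 <- "KKEECM"
  expect_equal(net_donated_hbonds(paste0(s1, s2)),
               net_donated_hbonds(s1) + net_donated_hbonds(s2))
})

test_that("secondary-structure fractions sum to 100 and follow the argmax rule", {
  expect_equal(unname(secondary_structure_fractions("AAAAAA")[["helix"]]), 100)
  expect_equal(unname(secondary_structure_fractions("GGGG")[["coil"]]), 100)
  for (s in random_sequences(15, seed = 5)) {
    ss <- secondary_structure_fractions(s)
    expect_equal(sum(ss), 100, tolerance = 1e-9)
  }
})

test_that("feature vectors have 61 consistent, finite entries on all fixtures", {
  nm <- feature_names()
  expect_length(nm, 61)
  expect_false(anyDuplicated(nm) > 0)
  for (ds in c("cpp111", "noncpp34", "validation13")) {
    X <- peptide_features(load_bundled(ds))
    expect_identical(ncol(X), 61L)
    expect_true(all(is.finite(X)))
    # cross-consistency of the panel with the single-feature operations
    expect_equal(unname(X[, "net_charge"]),
                 vapply(load_bundled(ds)$peptides,
                        function(p) charge_features(p)$net, numeric(1)))
    pct <- X[, paste0("percent_", c("polar", "positive", "negative",
                                    "hydrophobic"))]
    expect_equal(unname(rowSums(pct)), rep(100, nrow(X)), tolerance = 1e-9)
  }
})

test_that("descriptors are pure functions of the sequence", {
  v1 <- compute_feature_vector("GWTLNSAGYLLGKINLKALAALAKKIL")
  v2 <- compute_feature_vector(parse_peptide("GWTLNSAGYLLGKINLKALAALAKKIL", "x"))
  expect_identical(v1, v2)
})

test_that("min-max normalization maps training data to [0,1] and clamps", {
  set.seed(42)
  X <- cbind(a = runif(30, -5, 5), b = rnorm(30), const = rep(2, 30))
  np <- fit_normalizer(X)
  Xs <- apply_normalizer(np, X)
  expect_equal(unname(apply(Xs[, 1:2], 2, min)), c(0, 0))
  expect_equal(unname(apply(Xs[, 1:2], 2, max)), c(1, 1))
  expect_true(all(Xs[, "const"] == 0))
  # clamping of held-out values
  held <- apply_normalizer(np, cbind(a = c(-100, 100), b = c(0, 0),
                                     const = c(9, 9)))
  expect_equal(unname(held[, "a"]), c(0, 1))
  # invertibility on non-constant columns
  back <- sweep(sweep(Xs[, 1:2], 2, np$max[1:2] - np$min[1:2], "*"),
                2, np$min[1:2], "+")
  expect_equal(unname(back), unname(X[, 1:2]), tolerance = 1e-12)
  expect_error(fit_normalizer(X[0, , drop = FALSE]), "EmptyInput")
})
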