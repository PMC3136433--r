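test_that("PUK kernel has unit diagonal, symmetry, and the closed-form value", {
  set.seed(1)
  for (i in 1:10) {
    x <- runif(5); z <- runif(5)
    expect_equal(puk_kernel(x, x), 1)
    expect_equal(puk_kernel(x, z), puk_kernel(z, x))
    expect_true(puk_kernel(x, z) > 0 && puk_kernel(x, z) <= 1)
  }
  # omega = 1, sigma = 1, ||x-z|| = 0.5: 2^(1/1)-1 = 1 so K = 1/(1+1) = 0.5
  expect_equal(puk_kernel(c(0, 0), c(0.3, 0.4)), 0.5)
  expect_error(puk_kernel(1:3, 1:4), "DimensionError")
})

test_that("PUK Gram matrices are symmetric positive semi-definite", {
  set.seed(2)
  for (rep in 1:5) {
    X <- matrix(runif(30 * 4), 30)
    K <- puk_gram(X, omega = sample(c(0.5, 1, 2), 1),
                  sigma = sample(c(0.5, 1, 2), 1))
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("cross Gram agrees with pairwise kernel evaluation", {
  set.seed(3)
  X <- matrix(runif(12), 4)
  Z <- matrix(runif(9), 3)
  K <- puk_gram(X, Z, omega = 2, sigma = 0.7)
  for (i in 1:4) for (j in 1:3) {
    expect_equal(K[i, j], puk_kernel(X[i, ], Z[j, ], omega = 2, sigma = 0.7))
  }
})

test_that("SMO solves a separable pair and respects the dual constraint", {
  x <- rbind(c(0, 0), c(1, 1))
  fit <- cpp_svm(x, c(-1, 1))
  expect_identical(unname(predict(fit, x)), c("NON_CPP", "CPP"))
  expect_lt(abs(sum(fit$alpha * fit$y)), 1e-8)
  expect_error(cpp_svm(x, c(1, 1)), "DegenerateLabels")
})

test_that("SMO objective matches the brute-force dual QP oracle", {
  set.seed(42)
  for (rep in 1:20) {
    n <- 6
    x <- matrix(runif(n * 2), n)
    y <- sample(c(-1, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- -y[1]
    C <- sample(c(0.5, 1, 2), 1)
    fit <- cpp_svm(x, y, C = C, tol = 1e-8, seed = rep)
    oracle <- qp_enumeration_oracle(puk_gram(x), y, C)
    expect_equal(fit$objective, oracle$objective,
                 tolerance = 1e-6 * max(1, abs(oracle$objective)))
  }
})

test_that("duplicating every training row leaves the decision function unchanged", {
  set.seed(7)
  x <- matrix(runif(20), 10)
  y <- rep(c(-1, 1), 5)
  grid <- matrix(runif(40), 20)
  f1 <- decision_values(cpp_svm(x, y, tol = 1e-6), grid)
  # duplicated problem with halved C has the same solution set
  f2 <- decision_values(cpp_svm(rbind(x, x), c(y, y), C = 0.5, tol = 1e-6),
                        grid)
  expect_equal(f1, f2, tolerance = 1e-4)
})

test_that("KKT conditions hold at the solver tolerance", {
  set.seed(8)
  x <- matrix(runif(60 * 3), 60)
  y <- ifelse(x[, 1] + rnorm(60, sd = 0.2) > 0.5, 1, -1)
  if (length(unique(y)) < 2) y[1] <- -y[1]
  tol <- 1e-3
  fit <- cpp_svm(x, y, tol = tol)
  m <- y * decision_values(fit, x)
  a <- fit$alpha
  eps <- 1e-8
  expect_true(all(m[a < eps] >= 1 - tol - 1e-6))
  expect_true(all(abs(m[a > eps & a < fit$C - eps] - 1) <= tol + 1e-6))
  expect_true(all(m[a > fit$C - eps] <= 1 + tol + 1e-6))
})

test_that("relabeling the classes flips decision values exactly", {
  set.seed(9)
  x <- matrix(runif(30), 15)
  y <- rep(c(-1, 1), c(7, 8))
  grid <- matrix(runif(20), 10)
  f_pos <- decision_values(cpp_svm(x, y, tol = 1e-6, seed = 3), grid)
  f_neg <- decision_values(cpp_svm(x, -y, tol = 1e-6, seed = 3), grid)
  expect_equal(f_pos, -f_neg, tolerance = 1e-6)
})

test_that("a charge-trained model ranks polycationic above neutral peptides", {
  d <- build_dataset("unbalanced")
  m <- cpp_classifier(d, features = c("net_charge", "positive_charge",
                                      "percent_positive"))
  hot <- predict(m, parse_peptide("RRRRRRRRR", "r9"), type = "decision")
  cold <- predict(m, parse_peptide("TCSSNCQTCPCSSNNCQ", "neg1"),
                  type = "decision")
  expect_gt(hot, cold)
})

test_that("models serialize to JSON and reload with identical predictions", {
  d <- build_dataset("oversample_neg", seed = 4)
  m <- cpp_classifier(d, features = c("net_charge", "isoelectric_point",
                                      "hydropathicity"))
  probe <- load_bundled("validation13")
  tmp <- withr::local_tempfile(fileext = ".json")
  write_model(m, tmp)
  m2 <- read_model(tmp)
  expect_identical(predict(m, probe, type = "decision"),
                   predict(m2, probe, type = "decision"))
})
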