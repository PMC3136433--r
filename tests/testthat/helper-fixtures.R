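# Shared helpers: synthetic datasets with known structure and the
# brute-force dual-QP oracle used to check the SMO solver.

# A cpp_dataset whose class is sign(f1 + f2 - 1) with pure-noise features.
make_planted_dataset <- function(n = 200, n_noise = 20, seed = 1) {
  set.seed(seed)
  p <- 2 + n_noise
  x <- matrix(runif(n * p), n)
  colnames(x) <- paste0("f", seq_len(p))
  y <- ifelse(x[, 1] + x[, 2] > 1, "CPP", "NON_CPP")
  structure(list(x = x, labels = y, strategy = "synthetic", seed = seed,
                 provenance = paste0("r", seq_len(n)),
                 sequences = rep("", n)),
            class = "cpp_dataset")
}

# A trivially separable two-cluster dataset.
make_separable_dataset <- function(n = 40, seed = 1) {
  set.seed(seed)
  half <- n %/% 2
  x <- rbind(matrix(rnorm(half * 2, mean = 0, sd = 0.1), half),
             matrix(rnorm(half * 2, mean = 3, sd = 0.1), half))
  colnames(x) <- c("f1", "f2")
  structure(list(x = x, labels = rep(c("NON_CPP", "CPP"), each = half),
                 strategy = "synthetic", seed = seed,
                 provenance = paste0("r", seq_len(2 * half)),
                 sequences = rep("", 2 * half)),
            class = "cpp_dataset")
}

# Exact maximizer of the SVM dual on tiny instances by enumerating every
# active-set configuration (each alpha in {0, C, interior}) and solving the
# equality-constrained stationarity system for the interior block. All
# candidates are feasible, and the true optimum's configuration is among
# them, so the best objective found is the global optimum.
qp_enumeration_oracle <- function(K, y, C) {
  n <- length(y)
  Q <- K * tcrossprod(y)
  best <- -Inf
  best_alpha <- NULL
  for (code in 0:(3^n - 1)) {
    st <- (code %/% 3^(0:(n - 1))) %% 3 # 0 = at 0, 1 = at C, 2 = interior
    S <- which(st == 2)
    B <- which(st == 1)
    a <- numeric(n)
    a[B] <- C
    if (length(S)) {
      A <- rbind(cbind(Q[S, S, drop = FALSE], y[S]), c(y[S], 0))
      rhs <- c(1 - (if (length(B)) Q[S, B, drop = FALSE] %*% a[B] else
                      rep(0, length(S))),
               -sum(y[B] * a[B]))
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      aS <- sol[seq_along(S)]
      if (any(aS < -1e-9) || any(aS > C + 1e-9)) next
      a[S] <- pmin(pmax(aS, 0), C)
    }
    if (abs(sum(a * y)) > 1e-8) next
    obj <- sum(a) - 0.5 * drop(t(a) %*% Q %*% a)
    if (obj > best) {
      best <- obj
      best_alpha <- a
    }
  }
  list(objective = best, alpha = best_alpha)
}

# Grid-scan oracle for the isoelectric point, independent of the bisection:
# evaluates the Henderson-Hasselbalch net charge on a dense pH grid directly
# from the pKa table.
pi_grid_oracle <- function(seq, step = 1e-4) {
  counts <- aa_composition(seq)$counts
  pka <- cppscreen:::PKA_SET
  basic_n <- c(Nterm = 1, counts["R"], counts["K"], counts["H"])
  acidic_n <- c(Cterm = 1, counts["D"], counts["E"], counts["C"], counts["Y"])
  basic_pka <- pka[c("Nterm", "R", "K", "H")]
  acidic_pka <- pka[c("Cterm", "D", "E", "C", "Y")]
  ph <- seq(0, 14, by = step)
  pos <- drop((1 / (1 + 10^(outer(ph, basic_pka, "-")))) %*% basic_n)
  neg <- drop((1 / (1 + 10^(outer(ph, acidic_pka, function(p, k) k - p)))) %*%
                acidic_n)
  charge <- pos - neg
  ph[which.min(abs(charge))]
}

random_sequences <- function(n, seed, min_len = 5, max_len = 30) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(cppscreen:::AA_ALPHABET, sample(min_len:max_len, 1),
                 replace = TRUE), collapse = "")
  }, character(1))
}
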