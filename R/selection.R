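# Wrapper feature-subset selection by scatter search. Candidate subsets are
# scored by stratified k-fold CV accuracy of the wrapped PUK-SVM; the
# reference set keeps a quality half and a diversity half (max-min Hamming
# distance on subset indicator vectors), refreshed by pairwise combination
# and single-feature hill-climb improvement.

#' Scatter-search configuration
#'
#' @param b Reference-set size (even, >= 4); half quality, half diversity.
#' @param pop_size Initial population size.
#' @param max_generations Generation cap.
#' @param folds Inner wrapper CV folds (final reporting uses 10-fold CV via
#'   [cross_validate()]; the inner loop trades folds for speed).
#' @param improvement_steps Cap on hill-climb steps per candidate.
#' @param move_cap Number of single-feature add/remove moves examined per
#'   hill-climb step (sampled without replacement from all legal moves).
#' @param seed Search seed.
#' @param cv_seed Fold seed shared by every subset evaluation, so scores are
#'   comparable and memoizable.
#' @param C,omega,sigma Wrapped SVM settings.
#' @return A `scatter_config` list.
#' @export
scatter_config <- function(b = 10L, pop_size = 4L * b, max_generations = 20L,
                           folds = 5L, improvement_steps = 3L, move_cap = 61L,
                           seed = 1L, cv_seed = seed, C = 1, omega = 1,
                           sigma = 1) {
  stopifnot(b >= 4L, b %% 2L == 0L, folds >= 2L, pop_size >= b,
            max_generations >= 1L)
  structure(list(b = as.integer(b), pop_size = as.integer(pop_size),
                 max_generations = as.integer(max_generations),
                 folds = as.integer(folds),
                 improvement_steps = as.integer(improvement_steps),
                 move_cap = as.integer(move_cap), seed = as.integer(seed),
                 cv_seed = as.integer(cv_seed), C = C, omega = omega,
                 sigma = sigma),
            class = "scatter_config")
}

#' Cross-validated accuracy of a feature subset
#'
#' The wrapper objective: mean stratified k-fold CV accuracy (in \[0, 1\]) of
#' the PUK-SVM restricted to `features`. Deterministic given (`seed`,
#' `features`, `dataset`).
#'
#' @param dataset A `cpp_dataset`.
#' @param features Non-empty character vector of descriptor names.
#' @param folds Number of stratified folds.
#' @param seed Fold seed.
#' @param C,omega,sigma Wrapped SVM settings.
#' @return Accuracy in \[0, 1\].
#' @export
evaluate_subset <- function(dataset, features, folds = 5L, seed = 1L, C = 1,
                            omega = 1, sigma = 1) {
  if (!length(features)) stop("EmptySubset: no features to evaluate",
                              call. = FALSE)
  cross_validate(dataset, k = folds, seed = seed, features = features,
                 C = C, omega = omega, sigma = sigma)$accuracy / 100
}

# Candidate ordering: higher score, then fewer features, then lexicographic.
.cand_key <- function(cand) {
  list(score = cand$score, size = length(cand$features),
       names = paste(sort(cand$features), collapse = ","))
}

.cand_better <- function(a, b) {
  ka <- .cand_key(a); kb <- .cand_key(b)
  if (ka$score != kb$score) return(ka$score > kb$score)
  if (ka$size != kb$size) return(ka$size < kb$size)
  ka$names < kb$names
}

.cand_sort <- function(cands) {
  score <- vapply(cands, `[[`, numeric(1L), "score")
  size <- vapply(cands, function(c) length(c$features), integer(1L))
  nm <- vapply(cands, function(c) paste(sort(c$features), collapse = ","),
               character(1L))
  cands[order(-score, size, nm)]
}

.hamming <- function(f1, f2, all_feats) {
  sum(xor(all_feats %in% f1, all_feats %in% f2))
}

# Reference-set update rule: quality half = best b/2 candidates under the
# (score, size, name) order; diversity half = greedy max-min Hamming distance
# to the set chosen so far, over subset indicator vectors.
.refset_select <- function(cands, b, pool) {
  keys <- vapply(cands, function(c) paste(sort(c$features), collapse = ","),
                 character(1L))
  cands <- .cand_sort(cands[!duplicated(keys)])
  b1 <- min(b %/% 2L, length(cands))
  refset <- cands[seq_len(b1)]
  rest <- cands[-seq_len(b1)]
  while (length(refset) < b && length(rest)) {
    dists <- vapply(rest, function(c) {
      min(vapply(refset, function(r) .hamming(c$features, r$features, pool),
                 numeric(1L)))
    }, numeric(1L))
    pick <- which.max(dists)
    refset[[length(refset) + 1L]] <- rest[[pick]]
    rest <- rest[-pick]
  }
  refset
}

#' Desk-scale scatter-search configuration for a dataset
#'
#' The package's standard search budget, scaled to the dataset: small
#' datasets (at most `small_n` rows) are cheap to cross-validate and get a
#' deeper search (population 16, 5 inner folds, 5 generations); larger ones
#' use a tighter budget (population 12, 3 inner folds, 3 generations) so
#' that a full selection-plus-evaluation run stays interactive on one CPU.
#'
#' @param dataset A `cpp_dataset` (or an integer row count).
#' @param seed Search seed.
#' @param small_n Row-count threshold between the two budgets.
#' @return A [scatter_config()].
#' @export
default_selection_config <- function(dataset, seed = 1L, small_n = 100L) {
  n <- if (inherits(dataset, "cpp_dataset")) nrow(dataset$x) else dataset
  if (n <= small_n) {
    scatter_config(b = 6L, pop_size = 16L, max_generations = 5L, folds = 5L,
                   improvement_steps = 3L, move_cap = 20L, seed = seed)
  } else {
    scatter_config(b = 6L, pop_size = 12L, max_generations = 3L, folds = 3L,
                   improvement_steps = 2L, move_cap = 12L, seed = seed)
  }
}

#' Scatter-search wrapper feature selection
#'
#' Searches the space of descriptor subsets for the one maximizing the
#' cross-validated accuracy of the wrapped PUK-SVM. An initial seeded random
#' population is hill-climbed (single-feature add/remove, first improving
#' move), the best and most diverse candidates form the reference set, and
#' pairwise combinations (features in both parents kept, features in one
#' parent kept with probability 1/2) are improved and merged back until the
#' reference set stabilizes or the generation cap is hit. Scores are
#' memoized; ties prefer fewer features, then lexicographic order.
#'
#' @param dataset A `cpp_dataset`.
#' @param config A [scatter_config()].
#' @param features Candidate feature pool (default: all 61 descriptors).
#' @return Object of class `subset_candidate`: `features`, `score` (inner-CV
#'   accuracy in \[0, 1\]), `evaluations`, `trace` (per-generation best
#'   score), `config`.
#' @export
scatter_search <- function(dataset, config = scatter_config(),
                           features = colnames(dataset$x)) {
  stopifnot(inherits(dataset, "cpp_dataset"), inherits(config, "scatter_config"))
  pool <- features
  p <- length(pool)
  memo <- new.env(parent = emptyenv())
  evals <- 0L
  score_subset <- function(feats) {
    key <- paste(sort(feats), collapse = ",")
    if (!is.null(memo[[key]])) return(memo[[key]])
    s <- evaluate_subset(dataset, feats, folds = config$folds,
                         seed = config$cv_seed, C = config$C,
                         omega = config$omega, sigma = config$sigma)
    evals <<- evals + 1L
    memo[[key]] <- s
    s
  }
  new_cand <- function(feats) {
    feats <- pool[pool %in% feats] # canonical order
    list(features = feats, score = score_subset(feats))
  }
  improve <- function(cand) {
    for (step in seq_len(config$improvement_steps)) {
      moves <- c(setdiff(pool, cand$features), cand$features) # adds then drops
      moves <- sample(moves)
      moves <- moves[seq_len(min(length(moves), config$move_cap))]
      improved <- FALSE
      for (m in moves) {
        feats <- if (m %in% cand$features) setdiff(cand$features, m)
                 else c(cand$features, m)
        if (!length(feats)) next
        cand2 <- new_cand(feats)
        if (.cand_better(cand2, cand)) { cand <- cand2; improved <- TRUE; break }
      }
      if (!improved) break
    }
    cand
  }
  update_refset <- function(cands) .refset_select(cands, config$b, pool)

  rng <- .seeded_rng(config$seed)
  on.exit(rng$restore(), add = TRUE)

  population <- lapply(seq_len(config$pop_size), function(i) {
    size <- sample.int(p, 1L)
    improve(new_cand(sample(pool, size)))
  })
  refset <- update_refset(population)
  best <- .cand_sort(refset)[[1L]]
  trace <- data.frame(generation = 0L, best_score = best$score,
                      evaluations = evals)

  for (gen in seq_len(config$max_generations)) {
    children <- list()
    for (i in seq_len(length(refset) - 1L)) {
      for (j in seq((i + 1L), length(refset))) {
        shared <- intersect(refset[[i]]$features, refset[[j]]$features)
        only <- setdiff(union(refset[[i]]$features, refset[[j]]$features),
                        shared)
        feats <- c(shared, only[stats::runif(length(only)) < 0.5])
        if (!length(feats)) feats <- sample(c(shared, only), 1L)
        children <- c(children, list(improve(new_cand(feats))))
      }
    }
    old_keys <- vapply(refset, function(c) paste(sort(c$features), collapse = ","),
                       character(1L))
    refset <- update_refset(c(refset, children))
    new_keys <- vapply(refset, function(c) paste(sort(c$features), collapse = ","),
                       character(1L))
    cand_best <- .cand_sort(refset)[[1L]]
    if (.cand_better(cand_best, best)) best <- cand_best
    trace <- rbind(trace, data.frame(generation = gen, best_score = best$score,
                                     evaluations = evals))
    if (setequal(old_keys, new_keys)) break
  }

  structure(list(features = best$features, score = best$score,
                 evaluations = evals, trace = trace, config = config,
                 refset = lapply(refset, `[`, c("features", "score"))),
            class = "subset_candidate")
}

#' @export
print.subset_candidate <- function(x, ...) {
  cat(sprintf("<subset_candidate> %d features, inner-CV accuracy %.4f (%d evaluations)\n",
              length(x$features), x$score, x$evaluations))
  cat(" ", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}
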