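# Training-set construction under the five class-imbalance strategies.

DATASET_STRATEGIES <- c("unbalanced", "random_neg", "biological_neg",
                        "oversample_neg", "subsample_pos")

#' Build a labeled training dataset
#'
#' Constructs a training dataset of 61-descriptor rows and binary labels
#' under one of five class-imbalance strategies:
#'
#' * `unbalanced`: all positives + all known negatives as given
#'   (145 rows with the bundled fixtures).
#' * `random_neg`: positives balanced 1:1 against random peptides from a
#'   0th-order Markov frequency model, assumed non-penetrating.
#' * `biological_neg`: positives balanced 1:1 against peptides drawn without
#'   replacement from a biological peptide pool, assumed non-penetrating.
#' * `oversample_neg`: positives balanced by drawing the same number of
#'   negatives with replacement from the known negatives.
#' * `subsample_pos`: ten balanced datasets, each pairing `n_neg` positives
#'   drawn with replacement against all known negatives.
#'
#' Rows are positives-then-negatives, then shuffled once under `seed`; the
#' shuffle is part of the dataset so downstream folds are deterministic.
#' With-replacement draws are uniform over source rows.
#'
#' @param strategy One of `"unbalanced"`, `"random_neg"`, `"biological_neg"`,
#'   `"oversample_neg"`, `"subsample_pos"`.
#' @param positives [peptide_collection()] of positive examples (default: the
#'   bundled 111 CPPs).
#' @param negatives [peptide_collection()] of known negatives (default: the
#'   bundled 34 non-penetrating analogs).
#' @param pool Peptide pool for `biological_neg` (default: the packaged
#'   synthetic stand-in pool).
#' @param model [residue_frequency_model()] for `random_neg` (default: the
#'   packaged background model).
#' @param seed Integer seed controlling all sampling.
#' @param n_datasets Number of datasets for `subsample_pos`.
#' @return A `cpp_dataset` (list with `x` 61-column matrix, `labels`
#'   character vector, `strategy`, `seed`, `provenance` source-id tags,
#'   `sequences`), or a list of ten `cpp_dataset`s for `subsample_pos`.
#' @examples
#' d <- build_dataset("unbalanced")
#' table(d$labels)
#' @export
build_dataset <- function(strategy, positives = load_bundled("cpp111"),
                          negatives = load_bundled("noncpp34"),
                          pool = NULL, model = NULL, seed = 1L,
                          n_datasets = 10L) {
  strategy <- match.arg(strategy, DATASET_STRATEGIES)
  rng <- .seeded_rng(seed)
  on.exit(rng$restore(), add = TRUE)
  n_pos <- length(positives)

  if (strategy == "subsample_pos") {
    n_sub <- length(negatives)
    out <- lapply(seq_len(n_datasets), function(k) {
      idx <- sample.int(n_pos, n_sub, replace = TRUE)
      .assemble_dataset(positives$peptides[idx], negatives, strategy,
                        seed = seed, index = k)
    })
    return(out)
  }

  neg_coll <- switch(strategy,
    unbalanced = negatives,
    random_neg = {
      if (is.null(model)) model <- default_frequency_model()
      if (!inherits(model, "residue_frequency_model"))
        stop("MissingGenerator: random_neg needs a residue_frequency_model",
             call. = FALSE)
      sample_peptides(model, n = n_pos, seed = sample.int(.Machine$integer.max, 1L))
    },
    biological_neg = {
      if (is.null(pool)) pool <- synthetic_peptide_pool()
      if (length(pool) < n_pos)
        stop("PoolTooSmall: pool has ", length(pool), " peptides, need ",
             n_pos, call. = FALSE)
      pool[sample.int(length(pool), n_pos, replace = FALSE)]
    },
    oversample_neg = negatives$peptides[sample.int(length(negatives), n_pos,
                                                   replace = TRUE)])
  .assemble_dataset(positives, neg_coll, strategy, seed = seed)
}

# Featurize, relabel, shuffle. Accepts collections or plain peptide lists
# (with-replacement draws repeat peptides, so ids may repeat); provenance
# keeps the source peptide id for every row.
.assemble_dataset <- function(pos, neg, strategy, seed, index = NULL) {
  if (inherits(pos, "peptide_collection")) pos <- pos$peptides
  if (inherits(neg, "peptide_collection")) neg <- neg$peptides
  pos_x <- peptide_features(pos)
  neg_x <- peptide_features(neg)
  x <- rbind(pos_x, neg_x)
  labels <- c(rep("CPP", nrow(pos_x)), rep("NON_CPP", nrow(neg_x)))
  prov <- c(vapply(pos, `[[`, character(1L), "id"),
            vapply(neg, `[[`, character(1L), "id"))
  seqs <- c(vapply(pos, `[[`, character(1L), "sequence"),
            vapply(neg, `[[`, character(1L), "sequence"))
  ord <- sample.int(nrow(x))
  rownames(x) <- make.unique(prov, sep = "_dup")
  structure(list(x = x[ord, , drop = FALSE], labels = labels[ord],
                 strategy = strategy, seed = seed, index = index,
                 provenance = prov[ord], sequences = seqs[ord]),
            class = "cpp_dataset")
}

#' @export
print.cpp_dataset <- function(x, ...) {
  cat(sprintf("<cpp_dataset> strategy: %s%s, %d rows (%d CPP / %d NON_CPP), seed %d\n",
              x$strategy, if (!is.null(x$index)) paste0(" #", x$index) else "",
              nrow(x$x), sum(x$labels == "CPP"), sum(x$labels == "NON_CPP"),
              x$seed))
  invisible(x)
}

# +1/-1 response used by the SVM (positive class = CPP).
dataset_y <- function(d) ifelse(d$labels == "CPP", 1, -1)
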