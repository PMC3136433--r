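# 0th-order Markov (i.i.d. residue) peptide generator.

# Packaged default background amino-acid frequencies: a representative
# vertebrate proteome composition (chicken-like), normalized to sum 1. Used
# when no proteome is supplied.
DEFAULT_AA_FREQ <- local({
  f <- c(A = 6.9, R = 5.3, N = 3.6, D = 4.9, C = 2.3, Q = 4.4, E = 6.9,
         G = 6.4, H = 2.5, I = 4.6, L = 9.6, K = 5.6, M = 2.4, F = 3.6,
         P = 5.7, S = 8.2, T = 5.3, W = 1.1, Y = 2.7, V = 6.1)
  (f / sum(f))[AA_ALPHABET]
})

#' Residue frequency model
#'
#' A 0th-order Markov model over the 20 amino acids: i.i.d. residue sampling
#' from a fixed frequency vector, with peptide lengths drawn uniformly from
#' an inclusive integer range.
#'
#' @param frequencies Named non-negative numeric vector over the 20 residues;
#'   normalized to sum 1.
#' @param length_range Integer pair `c(lo, hi)`, inclusive.
#' @param source Free-text provenance of the frequencies.
#' @return Object of class `residue_frequency_model`.
#' @export
residue_frequency_model <- function(frequencies,
                                    length_range = c(12L, 26L),
                                    source = "user") {
  stopifnot(all(AA_ALPHABET %in% names(frequencies)))
  f <- as.numeric(frequencies[AA_ALPHABET])
  if (any(f < 0) || any(!is.finite(f))) {
    stop("InvalidModel: frequencies must be finite and non-negative", call. = FALSE)
  }
  if (sum(f) <= 0) stop("InvalidModel: all frequencies are zero", call. = FALSE)
  lr <- as.integer(length_range)
  stopifnot(length(lr) == 2L, lr[1L] >= 1L, lr[2L] >= lr[1L])
  structure(list(frequencies = stats::setNames(f / sum(f), AA_ALPHABET),
                 length_range = lr, source = source),
            class = "residue_frequency_model")
}

#' @export
print.residue_frequency_model <- function(x, ...) {
  cat(sprintf("<residue_frequency_model> source: %s, lengths %d-%d\n",
              x$source, x$length_range[1L], x$length_range[2L]))
  print(round(x$frequencies, 4))
  invisible(x)
}

#' Packaged default background model
#'
#' The packaged vertebrate (chicken-like) proteome amino-acid composition
#' with the default length range 12-26, so candidate generation needs no
#' external proteome.
#'
#' @param length_range Integer pair `c(lo, hi)`.
#' @return A [residue_frequency_model()].
#' @export
default_frequency_model <- function(length_range = c(12L, 26L)) {
  residue_frequency_model(DEFAULT_AA_FREQ, length_range,
                          source = "packaged vertebrate proteome composition")
}

#' Estimate residue frequencies from sequences
#'
#' Maximum-likelihood (count-based) amino-acid frequencies from a peptide
#' collection or a FASTA file, e.g. a proteome, for use as the background of
#' the random-peptide generator.
#'
#' @param x A [peptide_collection()], character vector of sequences, or path
#'   to a FASTA file.
#' @param length_range Length range for the resulting model.
#' @return A [residue_frequency_model()].
#' @export
estimate_frequencies <- function(x, length_range = c(12L, 26L)) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) x <- read_fasta(x)
  seqs <- if (inherits(x, "peptide_collection")) collection_sequences(x)
          else as.character(x)
  seqs <- seqs[nzchar(seqs)]
  if (!length(seqs)) stop("EmptyInput: no sequences to count", call. = FALSE)
  ch <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1L]]
  counts <- table(factor(ch, levels = AA_ALPHABET))
  residue_frequency_model(stats::setNames(as.numeric(counts), AA_ALPHABET) /
                            length(ch),
                          length_range, source = "estimated")
}

#' Sample random peptides from a frequency model
#'
#' Draws `n` peptides: each length uniform on the model's inclusive range,
#' residues i.i.d. from the model frequencies. Fully reproducible under
#' `seed`; the global RNG state is left untouched.
#'
#' @param model A [residue_frequency_model()].
#' @param n Number of peptides.
#' @param seed Integer seed.
#' @param prefix Id prefix for the generated peptides.
#' @return A [peptide_collection()] labeled `UNKNOWN`.
#' @examples
#' sample_peptides(default_frequency_model(), n = 3, seed = 1)
#' @export
sample_peptides <- function(model, n, seed, prefix = "rand") {
  stopifnot(inherits(model, "residue_frequency_model"), n >= 1L)
  rng <- .seeded_rng(seed)
  on.exit(rng$restore(), add = TRUE)
  lo <- model$length_range[1L]; hi <- model$length_range[2L]
  lens <- sample(lo:hi, n, replace = TRUE)
  peps <- lapply(seq_len(n), function(i) {
    seq <- paste(sample(AA_ALPHABET, lens[i], replace = TRUE,
                        prob = model$frequencies), collapse = "")
    parse_peptide(seq, id = sprintf("%s%04d", prefix, i), label = "UNKNOWN",
                  source = model$source)
  })
  peptide_collection(peps, name = sprintf("%s_n%d_seed%d", prefix, n, seed))
}

# Scoped RNG: set a local seed, and restore whatever global state existed.
.seeded_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  list(restore = function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
}
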