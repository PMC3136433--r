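# End-to-end screening: generate candidates, featurize, classify, rank, and
# shortlist the extremes for synthesis.

#' Screen random candidate peptides with a trained classifier
#'
#' Generates `n` candidate peptides from a 0th-order Markov frequency model,
#' predicts each with the trained classifier, ranks all candidates by
#' decreasing decision value, and returns a synthesis shortlist: the
#' `shortlist[1]` predicted CPPs with the most positive decision values and
#' the `shortlist[2]` predicted non-CPPs with the most negative ones. If
#' fewer predictions than requested exist on either side, the shortlist is
#' truncated and `shortfall` records it.
#'
#' @param model A trained [cpp_classifier()].
#' @param generator A [residue_frequency_model()].
#' @param n Number of candidates to generate.
#' @param seed Generator seed (the run is fully reproducible given the model
#'   and the two seeds recorded in the manifest).
#' @param shortlist Integer pair `c(n_pos, n_neg)`.
#' @return Object of class `screening_result`: `candidates` data frame (id,
#'   sequence, label, decision, rank), `shortlist` data frame, `counts`,
#'   `shortfall`, `manifest`.
#' @examples
#' d <- build_dataset("unbalanced")
#' m <- cpp_classifier(d, features = c("net_charge", "percent_positive"))
#' screen_candidates(m, n = 25, seed = 7, shortlist = c(2, 1))
#' @export
screen_candidates <- function(model, generator = default_frequency_model(),
                              n = 250L, seed = 42L, shortlist = c(4L, 2L)) {
  stopifnot(inherits(model, "cpp_classifier"),
            inherits(generator, "residue_frequency_model"),
            n >= 1L, length(shortlist) == 2L, all(shortlist >= 0L),
            n >= sum(shortlist))
  cands <- sample_peptides(generator, n = n, seed = seed, prefix = "cand")
  dec <- predict(model, cands, type = "decision")
  label <- ifelse(dec > 0, "CPP", "NON_CPP")
  ord <- order(dec, decreasing = TRUE)
  df <- data.frame(id = collection_ids(cands),
                   sequence = collection_sequences(cands),
                   label = label, decision = dec,
                   stringsAsFactors = FALSE)[ord, ]
  df$rank <- seq_len(n)
  rownames(df) <- NULL
  pos_avail <- sum(df$label == "CPP")
  neg_avail <- sum(df$label == "NON_CPP")
  n_pos <- min(shortlist[1L], pos_avail)
  n_neg <- min(shortlist[2L], neg_avail)
  top <- df[df$label == "CPP", ][seq_len(n_pos), ]
  bottom <- df[df$label == "NON_CPP", ]
  bottom <- bottom[rev(seq_len(nrow(bottom)))[seq_len(n_neg)], ]
  short <- rbind(top, bottom)
  shortfall <- c(pos = shortlist[1L] - n_pos, neg = shortlist[2L] - n_neg)
  if (any(shortfall > 0)) {
    warning("ShortlistUnderflow: requested ", shortlist[1L], "+", shortlist[2L],
            " but only ", pos_avail, " CPP / ", neg_avail,
            " non-CPP predictions available", call. = FALSE)
  }
  structure(list(candidates = df, shortlist = short,
                 counts = c(CPP = pos_avail, NON_CPP = neg_avail),
                 shortfall = shortfall,
                 manifest = list(n = n, generator_seed = seed,
                                 generator_source = generator$source,
                                 length_range = generator$length_range,
                                 model_strategy = model$strategy,
                                 model_features = model$features,
                                 shortlist_request = shortlist)),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening_result> %d candidates: %d predicted CPP, %d predicted non-CPP\n",
              nrow(x$candidates), x$counts[["CPP"]], x$counts[["NON_CPP"]]))
  cat("shortlist:\n")
  print(x$shortlist[, c("id", "sequence", "label", "decision", "rank")],
        row.names = FALSE)
  invisible(x)
}

#' Write a screening result and its run manifest
#'
#' Writes the ranked candidate table as TSV and the reproducibility manifest
#' (seeds, generator, model settings) as JSON alongside it.
#'
#' @param x A `screening_result`.
#' @param path Output TSV path; the manifest goes to `<path>.manifest.json`.
#' @return `path`, invisibly.
#' @export
write_screening <- function(x, path) {
  stopifnot(inherits(x, "screening_result"))
  utils::write.table(x$candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(x$manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
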