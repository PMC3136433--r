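#' Create a validated peptide
#'
#' Parses a raw amino-acid sequence into a canonical `peptide` object. The
#' sequence is upper-cased and validated against the 20 canonical one-letter
#' codes; any other character (including B, J, O, U, X, Z, digits, punctuation)
#' is an error, never silently dropped.
#'
#' @param raw Character scalar, the amino-acid sequence. Surrounding whitespace
#'   is stripped.
#' @param id Character scalar identifier.
#' @param label One of `"CPP"`, `"NON_CPP"`, `"UNKNOWN"`.
#' @param source Free-text provenance tag.
#' @return An object of class `peptide` with fields `id`, `sequence`, `label`,
#'   `source`.
#' @examples
#' parse_peptide("RKKRRQRRR", id = "tat9", label = "CPP")
#' @export
parse_peptide <- function(raw, id = "peptide", label = "UNKNOWN", source = "") {
  stopifnot(is.character(raw), length(raw) == 1L)
  label <- match.arg(label, PEPTIDE_LABELS)
  seq <- toupper(gsub("\\s", "", raw))
  if (!nzchar(seq)) {
    stop("EmptySequence: peptide '", id, "' has an empty sequence", call. = FALSE)
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% AA_ALPHABET))
  if (length(bad)) {
    stop("InvalidResidue: illegal character '", chars[bad[1L]],
         "' at position ", bad[1L], " in peptide '", id, "'", call. = FALSE)
  }
  structure(list(id = as.character(id), sequence = seq, label = label,
                 source = as.character(source)),
            class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  cat(sprintf("<peptide %s> %s (%d aa, %s)\n", x$id, x$sequence,
              nchar(x$sequence), x$label))
  invisible(x)
}

#' Build a peptide collection
#'
#' An ordered list of [parse_peptide()] objects with unique ids and a name.
#'
#' @param peptides List of `peptide` objects.
#' @param name Collection name.
#' @return An object of class `peptide_collection`.
#' @export
peptide_collection <- function(peptides, name = "collection") {
  stopifnot(is.list(peptides), length(peptides) > 0L)
  ok <- vapply(peptides, inherits, logical(1L), what = "peptide")
  if (!all(ok)) stop("all elements must be peptide objects", call. = FALSE)
  ids <- vapply(peptides, `[[`, character(1L), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate peptide ids in collection: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  structure(list(peptides = peptides, name = name), class = "peptide_collection")
}

#' @export
length.peptide_collection <- function(x) length(x$peptides)

#' @export
`[.peptide_collection` <- function(x, i) {
  peps <- x$peptides[i]
  ids <- make.unique(vapply(peps, `[[`, character(1L), "id"), sep = "_dup")
  for (k in seq_along(peps)) peps[[k]]$id <- ids[k]
  peptide_collection(peps, name = x$name)
}

#' @export
print.peptide_collection <- function(x, ...) {
  labs <- table(factor(collection_labels(x), levels = PEPTIDE_LABELS))
  cat(sprintf("<peptide_collection '%s'> %d peptides (%s)\n", x$name,
              length(x), paste(names(labs), labs, sep = ":", collapse = ", ")))
  invisible(x)
}

#' @rdname peptide_collection
#' @param x A `peptide_collection`.
#' @export
collection_sequences <- function(x) {
  vapply(x$peptides, `[[`, character(1L), "sequence")
}

#' @rdname peptide_collection
#' @export
collection_ids <- function(x) vapply(x$peptides, `[[`, character(1L), "id")

#' @rdname peptide_collection
#' @export
collection_labels <- function(x) vapply(x$peptides, `[[`, character(1L), "label")

#' Bundled peptide datasets
#'
#' Loads one of the packaged reference datasets: `cpp111`, the 111 known
#' cell-penetrating peptides compiled from the literature and commercial
#' vendors (all labeled `CPP`); `noncpp34`, the 34 known non-penetrating CPP
#' analogs and peptide hormones (all labeled `NON_CPP`); or `validation13`,
#' the 13 peptides synthesized for experimental validation. For
#' `validation13` the C-terminal amidation ("-NH2") of the synthesized forms
#' is recorded as metadata (`amidated`), not as part of the sequence; labels
#' map experimental roles conservatively: positive controls are `CPP`,
#' negative controls and the known non-penetrating analog are `NON_CPP`, and
#' peptides whose role was only a model prediction are `UNKNOWN`.
#'
#' @param name One of `"cpp111"`, `"noncpp34"`, `"validation13"`.
#' @return A [peptide_collection()]. For `validation13`, each peptide carries
#'   attributes `role` and `amidated`.
#' @examples
#' length(load_bundled("cpp111"))
#' @export
load_bundled <- function(name = c("cpp111", "noncpp34", "validation13")) {
  if (!is.character(name) || length(name) != 1L ||
      !(name %in% c("cpp111", "noncpp34", "validation13"))) {
    stop("UnknownDataset: '", paste(name, collapse = ","),
         "' (expected cpp111, noncpp34 or validation13)", call. = FALSE)
  }
  if (name == "validation13") {
    path <- system.file("extdata", "validation13.tsv", package = "cppscreen",
                        mustWork = TRUE)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    label <- ifelse(tab$role == "Control(+)", "CPP",
             ifelse(tab$role %in% c("Control(-)", "Known Non-CPP-CPP Analog"),
                    "NON_CPP", "UNKNOWN"))
    peps <- lapply(seq_len(nrow(tab)), function(i) {
      p <- parse_peptide(tab$sequence[i], id = tab$name[i], label = label[i],
                         source = "validation13")
      attr(p, "role") <- tab$role[i]
      attr(p, "amidated") <- tab$amidated[i]
      p
    })
    return(peptide_collection(peps, name = "validation13"))
  }
  file <- paste0(name, ".txt")
  label <- if (name == "cpp111") "CPP" else "NON_CPP"
  path <- system.file("extdata", file, package = "cppscreen", mustWork = TRUE)
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("id", "sequence"))
  peps <- lapply(seq_len(nrow(tab)), function(i) {
    parse_peptide(tab$sequence[i], id = tab$id[i], label = label, source = name)
  })
  peptide_collection(peps, name = name)
}

#' Read and write peptide FASTA files
#'
#' Thin wrappers around seqinr's FASTA reader/writer that return/accept
#' [peptide_collection()] objects and enforce the canonical amino-acid
#' alphabet. Writing then reading reproduces ids and sequences exactly;
#' multi-line records are concatenated on read.
#'
#' @param path File path.
#' @param label Label assigned to every record read.
#' @param x Collection to write.
#' @return `read_fasta` returns a [peptide_collection()]; `write_fasta`
#'   returns `path` invisibly.
#' @export
read_fasta <- function(path, label = "UNKNOWN") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                       forceDNAtolower = FALSE),
    error = function(e) stop("ParseError: ", conditionMessage(e), call. = FALSE))
  if (!length(recs)) stop("ParseError: no FASTA records in ", path, call. = FALSE)
  peps <- lapply(seq_along(recs), function(i) {
    parse_peptide(as.character(recs[[i]]), id = names(recs)[i], label = label,
                  source = basename(path))
  })
  peptide_collection(peps, name = tools::file_path_sans_ext(basename(path)))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "peptide_collection"), length(x) > 0L)
  seqinr::write.fasta(as.list(collection_sequences(x)),
                      names = collection_ids(x), file.out = path, nbchar = 60)
  invisible(path)
}

#' Synthetic stand-in pool of biological-like peptides
#'
#' Deterministically generates a pool of peptides from the packaged
#' amino-acid background frequency model, mimicking a set of short biological
#' peptides (lengths 12-26). This is a synthetic stand-in for a user-supplied
#' pool of real biological peptides (e.g. a proteome-derived peptide set) so
#' that the "balanced with biological negatives" training strategy is usable
#' out of the box; for real screening supply your own pool via [read_fasta()].
#'
#' @param n Pool size.
#' @param seed Integer seed; the default gives the packaged reference pool.
#' @return A [peptide_collection()] labeled `UNKNOWN`.
#' @export
synthetic_peptide_pool <- function(n = 411, seed = 4111226) {
  pool <- sample_peptides(default_frequency_model(), n = n, seed = seed,
                          prefix = "pool")
  pool$name <- "synthetic_pool"
  for (i in seq_along(pool$peptides)) {
    pool$peptides[[i]]$label <- "UNKNOWN"
    pool$peptides[[i]]$source <- "synthetic_pool"
  }
  pool
}
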