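# The 61-descriptor panel. Order is fixed: global properties, 20 residue
# counts, 20 residue percentages, 4 group percentages, mean-scale properties,
# net donated hydrogen bonds, secondary-structure fractions.

.pep_chars <- function(p) {
  seq <- if (inherits(p, "peptide")) p$sequence else as.character(p)
  strsplit(seq, "", fixed = TRUE)[[1L]]
}

#' Canonical descriptor names
#'
#' The fixed, ordered names of the 61 peptide descriptors computed by
#' [peptide_features()].
#'
#' @return Character vector of length 61.
#' @export
feature_names <- function() {
  c("length", "net_charge", "positive_charge", "negative_charge",
    "isoelectric_point", "molecular_weight", "hydropathicity",
    paste0("count_", AA_ALPHABET), paste0("percent_", AA_ALPHABET),
    "percent_polar", "percent_positive", "percent_negative",
    "percent_hydrophobic", "hydrophobicity", "lipophilicity",
    "amphiphilicity", "octanol_partition", "steric_bulk", "side_chain_bulk",
    "net_hbond_donated", "percent_helix", "percent_coil", "percent_sheet")
}

#' Amino-acid composition
#'
#' Per-residue counts and percentages over the 20 canonical residues.
#'
#' @param p A `peptide` or a plain sequence string.
#' @return List with integer `counts` (sums to the length) and `percents`
#'   (sums to 100), both named by residue.
#' @export
aa_composition <- function(p) {
  ch <- .pep_chars(p)
  counts <- table(factor(ch, levels = AA_ALPHABET))
  counts <- stats::setNames(as.integer(counts), AA_ALPHABET)
  list(counts = counts, percents = 100 * counts / length(ch))
}

#' Integer charge counts
#'
#' Counts of positively charged residues (K, R, H), negatively charged
#' residues (D, E), and their difference. Termini are not counted here (they
#' do enter the isoelectric point).
#'
#' @inheritParams aa_composition
#' @return List with `positive`, `negative`, `net` (integers).
#' @export
charge_features <- function(p) {
  cc <- aa_composition(p)$counts
  pos <- sum(cc[RESIDUE_GROUPS$positive])
  neg <- sum(cc[RESIDUE_GROUPS$negative])
  list(positive = pos, negative = neg, net = pos - neg)
}

# Henderson-Hasselbalch net charge of the peptide at a given pH, including
# free termini, under the packaged pKa set.
.net_charge_at_ph <- function(counts, pH, pka = PKA_SET) {
  basic <- c(Nterm = 1, R = unname(counts["R"]), K = unname(counts["K"]),
             H = unname(counts["H"]))
  acidic <- c(Cterm = 1, D = unname(counts["D"]), E = unname(counts["E"]),
              C = unname(counts["C"]), Y = unname(counts["Y"]))
  pos <- sum(basic / (1 + 10 ^ (pH - pka[names(basic)])))
  neg <- sum(acidic / (1 + 10 ^ (pka[names(acidic)] - pH)))
  pos - neg
}

#' Isoelectric point
#'
#' pH at which the Henderson-Hasselbalch net charge of the peptide (free N-
#' and C-termini plus the ionizable side chains C, D, E, H, K, R, Y under the
#' EMBOSS pKa set) is zero, located by bisection on \[0, 14\].
#'
#' @inheritParams aa_composition
#' @param tol Bisection tolerance in pH units.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(p, tol = 0.001) {
  counts <- aa_composition(p)$counts
  lo <- 0; hi <- 14
  # charge is strictly decreasing in pH, positive at 0 and negative at 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (.net_charge_at_ph(counts, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Molecular weight
#'
#' Average-mass molecular weight in Daltons: sum of residue masses plus one
#' water for the free acid/amine termini. Unmodified peptide assumed.
#'
#' @inheritParams aa_composition
#' @return Mass in Da.
#' @export
molecular_weight <- function(p) {
  ch <- .pep_chars(p)
  sum(RESIDUE_MASS[ch]) + WATER_MASS
}

#' Mean residue-scale value
#'
#' Arithmetic mean of a per-residue property scale over the sequence (the
#' GRAVY convention). With the default hydropathicity scale this is GRAVY.
#'
#' @inheritParams aa_composition
#' @param scale Named numeric vector over the 20 residues, or a name accepted
#'   by [residue_scale()].
#' @return Mean scale value.
#' @export
scale_mean <- function(p, scale = "hydropathicity") {
  if (is.character(scale)) scale <- residue_scale(scale)
  stopifnot(all(AA_ALPHABET %in% names(scale)))
  ch <- .pep_chars(p)
  mean(scale[ch])
}

#' Net donated side-chain hydrogen bonds
#'
#' Sum over residues of (side-chain donor count minus side-chain acceptor
#' count) from the packaged lookup table; the backbone is excluded. Additive
#' over concatenation by construction.
#'
#' @inheritParams aa_composition
#' @return Net donated hydrogen bonds (signed).
#' @export
net_donated_hbonds <- function(p) {
  ch <- .pep_chars(p)
  sum(NET_HBOND_DONATED[ch])
}

#' Secondary-structure state fractions
#'
#' Assigns each residue the conformational state (helix, sheet, coil) with
#' the maximal Chou-Fasman propensity and returns the percentage of residues
#' in each state. Ties are broken in the fixed order helix > sheet > coil.
#'
#' @inheritParams aa_composition
#' @return Named numeric vector `c(helix, coil, sheet)` summing to 100.
#' @export
secondary_structure_fractions <- function(p) {
  ch <- .pep_chars(p)
  state <- rownames(CHOU_FASMAN)[apply(CHOU_FASMAN[, ch, drop = FALSE], 2L,
                                       which.max)]
  tab <- table(factor(state, levels = c("helix", "coil", "sheet")))
  100 * stats::setNames(as.numeric(tab), names(tab)) / length(ch)
}

#' Compute the 61-descriptor vector for one peptide
#'
#' @inheritParams aa_composition
#' @return Named numeric vector of length 61, ordered as [feature_names()].
#' @export
compute_feature_vector <- function(p) {
  ch <- .pep_chars(p)
  comp <- aa_composition(p)
  chg <- charge_features(p)
  ss <- secondary_structure_fractions(p)
  grp <- vapply(RESIDUE_GROUPS, function(g) sum(comp$counts[g]), numeric(1L))
  v <- c(length(ch), chg$net, chg$positive, chg$negative,
         isoelectric_point(p), molecular_weight(p),
         scale_mean(p, KD_HYDROPATHY),
         comp$counts, comp$percents,
         100 * grp[["polar"]] / length(ch),
         100 * grp[["positive"]] / length(ch),
         100 * grp[["negative"]] / length(ch),
         100 * grp[["hydrophobic"]] / length(ch),
         scale_mean(p, EISENBERG_HYDROPHOBICITY),
         scale_mean(p, FAUCHERE_PLISKA_PI),
         scale_mean(p, MITAKU_AMPHIPHILICITY),
         scale_mean(p, FAUCHERE_PLISKA_PI),
         scale_mean(p, CHARTON_STERIC),
         scale_mean(p, ZIMMERMAN_BULKINESS),
         net_donated_hbonds(p),
         ss[["helix"]], ss[["coil"]], ss[["sheet"]])
  stats::setNames(as.numeric(v), feature_names())
}

#' Descriptor matrix for a peptide collection
#'
#' @param x A [peptide_collection()] (or list of peptides).
#' @return Numeric matrix, one row per peptide (rownames = ids), 61 columns
#'   named as [feature_names()].
#' @export
peptide_features <- function(x) {
  peps <- if (inherits(x, "peptide_collection")) x$peptides else x
  m <- t(vapply(peps, compute_feature_vector, numeric(61L)))
  rownames(m) <- vapply(peps, `[[`, character(1L), "id")
  m
}

#' Min-max feature normalization
#'
#' `fit_normalizer` learns per-feature minima and maxima from a training
#' matrix; `apply_normalizer` rescales to \[0, 1\] as (x - min)/(max - min).
#' Constant features map to 0; held-out values outside the training range are
#' clamped to \[0, 1\]. Fit only on training rows.
#'
#' @param X Numeric feature matrix.
#' @return `fit_normalizer`: object of class `minmax_normalizer` with fields
#'   `min`, `max`; `apply_normalizer`: rescaled matrix of the same shape.
#' @export
fit_normalizer <- function(X) {
  if (is.null(dim(X)) || nrow(X) == 0L) {
    stop("EmptyInput: cannot fit a normalizer on an empty matrix", call. = FALSE)
  }
  structure(list(min = apply(X, 2L, min), max = apply(X, 2L, max),
                 names = colnames(X)),
            class = "minmax_normalizer")
}

#' @rdname fit_normalizer
#' @param params A `minmax_normalizer`.
#' @export
apply_normalizer <- function(params, X) {
  stopifnot(inherits(params, "minmax_normalizer"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L, dimnames = list(NULL, names(X)))
  stopifnot(ncol(X) == length(params$min))
  rng <- params$max - params$min
  Xs <- sweep(X, 2L, params$min, "-")
  Xs <- sweep(Xs, 2L, ifelse(rng > 0, rng, 1), "/")
  Xs[, rng == 0] <- 0
  Xs[Xs < 0] <- 0
  Xs[Xs > 1] <- 1
  Xs
}
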