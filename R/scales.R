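# Residue property tables. Each scale maps the 20 canonical residues to a
# real number; the registry is data, so any entry can be swapped by the user
# without touching descriptor code.

.scale <- function(...) {
  v <- c(...)
  stopifnot(length(v) == 20L, all(sort(names(v)) == sort(AA_ALPHABET)))
  v[AA_ALPHABET]
}

# Kyte & Doolittle (1982) hydropathy
KD_HYDROPATHY <- .scale(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

# Eisenberg et al. (1984) consensus hydrophobicity
EISENBERG_HYDROPHOBICITY <- .scale(
  A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29, Q = -0.85, E = -0.74,
  G = 0.48, H = -0.40, I = 1.38, L = 1.06, K = -1.50, M = 0.64, F = 1.19,
  P = 0.12, S = -0.18, T = -0.05, W = 0.81, Y = 0.26, V = 1.08)

# Fauchere & Pliska (1983) side-chain octanol/water partition (pi)
FAUCHERE_PLISKA_PI <- .scale(
  A = 0.31, R = -1.01, N = -0.60, D = -0.77, C = 1.54, Q = -0.22, E = -0.64,
  G = 0.00, H = 0.13, I = 1.80, L = 1.70, K = -0.99, M = 1.23, F = 1.79,
  P = 0.72, S = -0.04, T = 0.26, W = 2.25, Y = 0.96, V = 1.22)

# Mitaku et al. (2002) amphiphilicity index
MITAKU_AMPHIPHILICITY <- .scale(
  A = 0.00, R = 2.45, N = 0.00, D = 0.00, C = 0.00, Q = 1.25, E = 1.27,
  G = 0.00, H = 1.45, I = 0.00, L = 0.00, K = 3.67, M = 0.00, F = 0.04,
  P = 0.00, S = 0.00, T = 0.00, W = 6.93, Y = 5.06, V = 0.00)

# Charton (1981) steric parameter (upsilon) of the side chain
CHARTON_STERIC <- .scale(
  A = 0.52, R = 0.68, N = 0.76, D = 0.76, C = 0.62, Q = 0.68, E = 0.68,
  G = 0.00, H = 0.70, I = 1.02, L = 0.98, K = 0.68, M = 0.78, F = 0.70,
  P = 0.36, S = 0.53, T = 0.70, W = 0.70, Y = 0.70, V = 0.76)

# Zimmerman et al. (1968) bulkiness
ZIMMERMAN_BULKINESS <- .scale(
  A = 11.50, R = 14.28, N = 12.82, D = 11.68, C = 13.46, Q = 14.45, E = 13.57,
  G = 3.40, H = 13.69, I = 21.40, L = 21.40, K = 15.71, M = 16.25, F = 19.80,
  P = 17.43, S = 9.47, T = 15.77, W = 21.67, Y = 18.03, V = 21.57)

# Average residue masses (Da); a condensed residue, so peptide mass adds one
# water for the free termini.
RESIDUE_MASS <- .scale(
  A = 71.08, R = 156.19, N = 114.10, D = 115.09, C = 103.14, Q = 128.13,
  E = 129.12, G = 57.05, H = 137.14, I = 113.16, L = 113.16, K = 128.17,
  M = 131.19, F = 147.18, P = 97.12, S = 87.08, T = 101.10, W = 186.21,
  Y = 163.18, V = 99.13)
WATER_MASS <- 18.02

# Side-chain net donated hydrogen bonds (donors minus acceptors); backbone
# excluded. A swappable resource like the scales above.
NET_HBOND_DONATED <- .scale(
  A = 0, R = 5, N = 0, D = -4, C = 1, Q = 0, E = -4, G = 0, H = 0, I = 0,
  L = 0, K = 3, M = -1, F = 0, P = 0, S = 0, T = 0, W = 1, Y = 0, V = 0)

# Chou & Fasman (1978) conformational propensities
CHOU_FASMAN <- local({
  m <- rbind(
    helix = .scale(A = 1.42, R = 0.98, N = 0.67, D = 1.01, C = 0.70, Q = 1.11,
                   E = 1.51, G = 0.57, H = 1.00, I = 1.08, L = 1.21, K = 1.16,
                   M = 1.45, F = 1.13, P = 0.57, S = 0.77, T = 0.83, W = 1.08,
                   Y = 0.69, V = 1.06),
    sheet = .scale(A = 0.83, R = 0.93, N = 0.89, D = 0.54, C = 1.19, Q = 1.10,
                   E = 0.37, G = 0.75, H = 0.87, I = 1.60, L = 1.30, K = 0.74,
                   M = 1.05, F = 1.38, P = 0.55, S = 0.75, T = 1.19, W = 1.37,
                   Y = 1.47, V = 1.70),
    coil  = .scale(A = 0.66, R = 0.95, N = 1.56, D = 1.46, C = 1.19, Q = 0.98,
                   E = 0.74, G = 1.56, H = 0.95, I = 0.47, L = 0.59, K = 1.01,
                   M = 0.60, F = 0.60, P = 1.52, S = 1.43, T = 0.96, W = 0.96,
                   Y = 1.14, V = 0.50))
  m
})

# EMBOSS pKa set used for the isoelectric point
PKA_SET <- c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1, H = 6.5,
             K = 10.8, R = 12.5, Y = 10.1)

# Residue groups: a partition of the 20 residues, so group percentages are
# well defined and every residue is counted exactly once.
RESIDUE_GROUPS <- list(
  positive    = c("K", "R", "H"),
  negative    = c("D", "E"),
  polar       = c("S", "T", "N", "Q", "Y", "C"),
  hydrophobic = c("A", "V", "L", "I", "M", "F", "W", "P", "G"))

#' Residue property scale registry
#'
#' Returns one of the packaged 20-residue property scales by name, or the
#' list of available names. Scales are plain named numeric vectors and can be
#' replaced by any complete 20-entry vector in functions that accept a
#' `scale` argument.
#'
#' @param name Scale name; omit to list available scales.
#' @return Named numeric vector over the 20 canonical residues, or a
#'   character vector of names.
#' @examples
#' residue_scale("hydropathicity")[["R"]]
#' @export
residue_scale <- function(name) {
  registry <- list(
    hydropathicity  = KD_HYDROPATHY,
    hydrophobicity  = EISENBERG_HYDROPHOBICITY,
    lipophilicity   = FAUCHERE_PLISKA_PI,
    amphiphilicity  = MITAKU_AMPHIPHILICITY,
    octanol_partition = FAUCHERE_PLISKA_PI,
    steric_bulk     = CHARTON_STERIC,
    side_chain_bulk = ZIMMERMAN_BULKINESS,
    residue_mass    = RESIDUE_MASS,
    net_hbond_donated = NET_HBOND_DONATED)
  if (missing(name)) return(names(registry))
  if (!name %in% names(registry)) {
    stop("unknown scale '", name, "'; see residue_scale() for choices",
         call. = FALSE)
  }
  registry[[name]]
}
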