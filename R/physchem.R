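# Molecular weight (average masses) and isoelectric point (Bjellqvist pKa,
# bisection on the net-charge function).

# Average residue masses, Da (monomer minus water).
AA_AVG_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01524

# Bjellqvist pKa set (simplified: fixed termini).
PKA <- list(
  nterm = 7.50, cterm = 3.55,
  positive = c(K = 10.00, R = 12.00, H = 5.98),
  negative = c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00))

#' Average molecular mass of a protein
#'
#' Sum of average residue masses plus one water; additive over concatenation
#' up to one water mass.
#'
#' @param aa_seq Amino-acid string (20 standard residues; X is rejected).
#' @return Mass in Da.
#' @export
protein_mw <- function(aa_seq) {
  chars <- strsplit(toupper(aa_seq), "", fixed = TRUE)[[1]]
  if (any(!chars %in% names(AA_AVG_MASS))) {
    stop("sequence contains non-standard residues: ",
         paste(unique(chars[!chars %in% names(AA_AVG_MASS)]), collapse = ","))
  }
  sum(AA_AVG_MASS[chars]) + WATER_MASS
}

#' Net charge of a protein at a given pH
#'
#' Henderson–Hasselbalch per ionizable group, free N and C termini, Bjellqvist
#' pKa values. Strictly decreasing in pH, so the pI root is unique.
#'
#' @param aa_seq Amino-acid string.
#' @param ph pH value (vectorized).
#' @return Net charge (elementary charges).
#' @export
net_charge <- function(aa_seq, ph) {
  chars <- strsplit(toupper(aa_seq), "", fixed = TRUE)[[1]]
  counts <- table(chars)
  pos_frac <- function(pka) 1 / (1 + 10^(ph - pka))
  neg_frac <- function(pka) -1 / (1 + 10^(pka - ph))
  q <- pos_frac(PKA$nterm) + neg_frac(PKA$cterm)
  for (res in names(PKA$positive)) {
    n <- counts[res]
    if (!is.na(n)) q <- q + n * pos_frac(PKA$positive[[res]])
  }
  for (res in names(PKA$negative)) {
    n <- counts[res]
    if (!is.na(n)) q <- q + n * neg_frac(PKA$negative[[res]])
  }
  unname(q)
}

#' Isoelectric point by bisection
#'
#' Bisects the net-charge function on pH 0–14 until `|charge| < tol`.
#'
#' @param aa_seq Amino-acid string (X rejected).
#' @param tol Convergence tolerance on the net charge.
#' @return pI in pH units.
#' @export
protein_pi <- function(aa_seq, tol = 1e-4) {
  chars <- strsplit(toupper(aa_seq), "", fixed = TRUE)[[1]]
  if (any(!chars %in% names(AA_AVG_MASS))) {
    stop("pI undefined for non-standard residues")
  }
  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    q <- net_charge(aa_seq, mid)
    if (abs(q) < tol || (hi - lo) < 1e-12) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
}

#' Molecular weight and isoelectric point
#'
#' @param prot A [protein_record()] or amino-acid string.
#' @return Named numeric vector `c(mw_da =, pi =)`.
#' @export
physchem_properties <- function(prot) {
  aa <- if (is.character(prot)) prot else prot$aa_seq
  c(mw_da = protein_mw(aa), pi = protein_pi(aa))
}
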