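# Unified nearest-neighbour duplex parameters (kcal/mol; cal/mol/K),
# keyed by the sense-strand dinucleotide; the complementary dinucleotide
# shares the same stack.
NN_DH <- c(AA = -7.6, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
           CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
NN_DS <- c(AA = -21.3, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
NN_INIT_DH <- 0.2; NN_INIT_DS <- -5.7        # duplex initiation
NN_TERM_AT_DH <- 2.2; NN_TERM_AT_DS <- 6.9   # per terminal A:T pair
GAS_CONSTANT <- 1.987                        # cal/mol/K

canonical_dinuc <- function(d) {
  miss <- !(d %in% names(NN_DH))
  d[miss] <- revcomp(d[miss])
  d
}

#' Oligonucleotide melting temperature (nearest-neighbour model)
#'
#' Unified nearest-neighbour thermodynamics for a DNA oligo annealing to
#' its perfect complement, with entropic monovalent-salt correction
#' (`0.368 * (n-1) * ln[Na+]`) and the total-strand-concentration term for
#' a primer in excess over template. Defaults match typical RACE priming
#' conditions: 50 mM monovalent cation, 200 nM oligo.
#'
#' @param oligo Character vector of oligo sequences, 5' to 3' (ACGT only,
#'   length >= 8).
#' @param conc_nM Oligo concentration in nanomolar.
#' @param na_mM Monovalent cation concentration in millimolar.
#' @return Melting temperatures in degrees Celsius.
#' @examples
#' melting_temperature("GCGCGCATATGCGCGCATATGCGCG")
#' @export
melting_temperature <- function(oligo, conc_nM = 200, na_mM = 50) {
  vapply(toupper(oligo), function(s) {
    b <- chars(s)
    if (length(b) < 8) abort("oligo shorter than 8 nt")
    if (!all(b %in% c("A", "C", "G", "T")))
      abort("oligo contains ambiguous bases")
    d <- canonical_dinuc(paste0(b[-length(b)], b[-1]))
    dH <- NN_INIT_DH + sum(NN_DH[d]) +
      NN_TERM_AT_DH * sum(b[c(1, length(b))] %in% c("A", "T"))
    dS <- NN_INIT_DS + sum(NN_DS[d]) +
      NN_TERM_AT_DS * sum(b[c(1, length(b))] %in% c("A", "T"))
    dS <- dS + 0.368 * (length(b) - 1) * log(na_mM / 1000)
    dH * 1000 / (dS + GAS_CONSTANT * log(conc_nM * 1e-9)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

#' GC fraction of sequences
#'
#' @param x Character vector of DNA sequences.
#' @return Fraction of G/C bases per sequence.
#' @export
gc_fraction <- function(x) {
  vapply(toupper(x), function(s) {
    b <- chars(s)
    mean(b %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

# Vectorized Tm/GC over all windows of width k in a sequence.
# Returns a data frame with start (0-based), tm, gc. Windows containing
# non-ACGT characters (e.g. the mask symbol) get NA.
window_thermo <- function(seq, k, conc_nM = 200, na_mM = 50) {
  b <- chars(toupper(seq))
  n <- length(b)
  if (n < k) return(data.frame(start = integer(), tm = numeric(), gc = numeric()))
  ok <- b %in% c("A", "C", "G", "T")
  d <- paste0(b[-n], b[-1])
  dok <- ok[-n] & ok[-1]
  d[dok] <- canonical_dinuc(d[dok])
  dh <- ifelse(dok, NN_DH[d], NA_real_)
  ds <- ifelse(dok, NN_DS[d], NA_real_)
  csH <- cumsum(c(0, ifelse(is.na(dh), 0, dh)))
  csS <- cumsum(c(0, ifelse(is.na(ds), 0, ds)))
  bad <- cumsum(c(0, as.integer(is.na(dh))))
  gcc <- cumsum(c(0, as.integer(b %in% c("G", "C"))))
  starts <- seq_len(n - k + 1L)
  nbad <- bad[starts + k - 1L] - bad[starts]
  sumH <- csH[starts + k - 1L] - csH[starts]
  sumS <- csS[starts + k - 1L] - csS[starts]
  at_term <- (b[starts] %in% c("A", "T")) + (b[starts + k - 1L] %in% c("A", "T"))
  dH <- NN_INIT_DH + sumH + NN_TERM_AT_DH * at_term
  dS <- NN_INIT_DS + sumS + NN_TERM_AT_DS * at_term +
    0.368 * (k - 1) * log(na_mM / 1000)
  tm <- dH * 1000 / (dS + GAS_CONSTANT * log(conc_nM * 1e-9)) - 273.15
  gc <- (gcc[starts + k] - gcc[starts]) / k
  tm[nbad > 0] <- NA_real_
  gc[nbad > 0] <- NA_real_
  data.frame(start = starts - 1L, tm = tm, gc = gc)
}
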