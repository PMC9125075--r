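# Primer melting temperature.  Nearest-neighbor model with the unified
# duplex parameters (Allawi & SantaLucia 1997/2004 set), entropy salt
# correction, at 50 mM Na+ and 0.25 uM total primer by default; short
# oligos (< 14 nt) fall back to the Wallace 2(A+T)+4(G+C) rule.

NN_DH <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
)
NN_DS <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
)

#' Primer melting temperature
#'
#' @param seq Primer sequence (concrete DNA).
#' @param na_molar Monovalent cation concentration (mol/L).
#' @param primer_molar Total primer concentration (mol/L); the effective
#'   annealing concentration is `primer_molar / 4` (primer in excess over
#'   template, non-self-complementary).
#' @return Tm in degrees Celsius.
#' @examples
#' tm_nn("TCATTGACCTACGGTTGC")
#' @export
tm_nn <- function(seq, na_molar = 0.05, primer_molar = 0.25e-6) {
  seq <- check_dna(seq, "primer", allow_ambiguity = FALSE)
  n <- nchar(seq)
  if (n < 2L) stop("primer too short for a Tm")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (n < 14L) {
    return(2 * sum(chars %in% c("A", "T")) + 4 * sum(chars %in% c("G", "C")))
  }
  pairs <- paste0(chars[-n], chars[-1L])
  dh <- sum(NN_DH[pairs])
  ds <- sum(NN_DS[pairs])
  for (term in chars[c(1L, n)]) {
    if (term %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (n - 1L) * log(na_molar)
  r_gas <- 1.987
  dh * 1000 / (ds + r_gas * log(primer_molar / 4)) - 273.15
}
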