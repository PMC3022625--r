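# Nearest-neighbor duplex thermodynamics for primer design.
#
# Unified NN parameters (SantaLucia 1998, PNAS 95:1460): dH in kcal/mol,
# dS in cal/(mol K), one entry per stacked dinucleotide on the top strand.
# The table is closed under reverse complement, which makes Tm exactly
# strand-symmetric.
.NN_DH <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.NN_DS <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# Duplex initiation per terminal base pair.
.INIT_DH <- c(A = 2.3, T = 2.3, G = 0.1, C = 0.1)
.INIT_DS <- c(A = 4.1, T = 4.1, G = -2.8, C = -2.8)

.GAS_R <- 1.98722  # cal/(mol K)

#' Thermodynamic parameter set for melting-temperature prediction
#'
#' Bundles the nearest-neighbor parameter table identifier with the reaction
#' conditions used for the salt correction and the strand-concentration term.
#' Defaults reflect a standard multiplex PCR buffer (50 mM KCl, 5 mM MgCl2)
#' and 0.25 uM primer.
#'
#' Divalent magnesium is folded into an equivalent monovalent concentration
#' with the common `mono + 120*sqrt(Mg)` (mM) rule, and the entropy is
#' corrected by `0.368 * (n-1) * ln[Na+eq]` where `n` is the oligo length.
#'
#' @param table NN parameter table id; only `"santalucia1998"` is shipped.
#' @param primer_conc_M total single-strand concentration (mol/L).
#' @param monovalent_mM monovalent cation concentration (mM).
#' @param mg_mM free magnesium concentration (mM).
#' @return an object of class `tm_params`.
#' @export
tm_params <- function(table = "santalucia1998", primer_conc_M = 2.5e-7,
                      monovalent_mM = 50, mg_mM = 5) {
  table <- match.arg(table)
  stopifnot(primer_conc_M > 0, monovalent_mM > 0, mg_mM >= 0)
  structure(list(table = table, primer_conc_M = primer_conc_M,
                 monovalent_mM = monovalent_mM, mg_mM = mg_mM),
            class = "tm_params")
}

#' Nearest-neighbor melting temperature
#'
#' Predicts the duplex melting temperature of each primer against its perfect
#' complement: `Tm = 1000*dH / (dS' + R*ln(C/4)) - 273.15`, where `dH`/`dS`
#' are the summed stacking plus initiation terms and `dS'` carries the
#' salt correction (see [tm_params()]). Deterministic, vectorised, and exactly
#' symmetric under reverse complement.
#'
#' @param seq character vector of primer sequences (ACGT, length >= 8).
#' @param params a [tm_params()] object.
#' @return numeric vector of melting temperatures in degrees Celsius.
#' @export
#' @examples
#' melting_temperature("AGCGTAGCTGGGATCCAGCA")
melting_temperature <- function(seq, params = tm_params()) {
  if (length(seq) == 0L) return(numeric(0))
  assert_dna(seq, "primer sequence")
  n <- nchar(seq)
  if (any(n < 8L))
    stop("primer sequences must be at least 8 nt (got ", min(n), ")",
         call. = FALSE)
  stopifnot(inherits(params, "tm_params"))

  na_eq <- (params$monovalent_mM + 120 * sqrt(params$mg_mM)) / 1000
  ct_term <- .GAS_R * log(params$primer_conc_M / 4)

  first <- substr_v(seq, 1L, 1L)
  last  <- substr_v(seq, n, n)
  vapply(seq_along(seq), function(i) {
    s <- seq[[i]]
    k <- n[[i]]
    din <- substring(s, 1:(k - 1L), 2:k)
    dh <- sum(.NN_DH[din]) + .INIT_DH[[first[[i]]]] + .INIT_DH[[last[[i]]]]
    ds <- sum(.NN_DS[din]) + .INIT_DS[[first[[i]]]] + .INIT_DS[[last[[i]]]]
    ds <- ds + 0.368 * (k - 1L) * log(na_eq)
    1000 * dh / (ds + ct_term) - 273.15
  }, numeric(1))
}
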