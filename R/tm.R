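# Unified nearest-neighbor parameters for DNA/DNA duplexes
# (Allawi & SantaLucia 1997 stacks; SantaLucia 1998 unified initiation terms).
# dH in kcal/mol, dS in cal/(mol K).
NN_DH <- c("AA" = -7.9, "TT" = -7.9, "AT" = -7.2, "TA" = -7.2,
           "CA" = -8.5, "TG" = -8.5, "GT" = -8.4, "AC" = -8.4,
           "CT" = -7.8, "AG" = -7.8, "GA" = -8.2, "TC" = -8.2,
           "CG" = -10.6, "GC" = -9.8, "GG" = -8.0, "CC" = -8.0)
NN_DS <- c("AA" = -22.2, "TT" = -22.2, "AT" = -20.4, "TA" = -21.3,
           "CA" = -22.7, "TG" = -22.7, "GT" = -22.4, "AC" = -22.4,
           "CT" = -21.0, "AG" = -21.0, "GA" = -22.2, "TC" = -22.2,
           "CG" = -27.2, "GC" = -24.4, "GG" = -19.9, "CC" = -19.9)
NN_INIT <- list("GC" = c(dH = 0.1, dS = -2.8),
                "AT" = c(dH = 2.3, dS = 4.1))
GAS_CONSTANT <- 1.987  # cal/(mol K)

#' Primer melting temperature
#'
#' Computes the melting temperature of a primer annealing region. The default
#' nearest-neighbor model uses the unified DNA/DNA parameter set with the
#' entropic salt correction dS' = dS + 0.368 (N-1) ln[Na+] and
#' Tm = 1000 dH / (dS' + R ln(Ct/4)) - 273.15, where Ct is the total primer
#' concentration. The Wallace rule (2(A+T) + 4(G+C)) and a GC-fraction
#' formula (81.5 + 16.6 log10[Na+] + 0.41 %GC - 600/N) are available as
#' closed-form alternatives.
#'
#' @param seq primer sequence (strict DNA; degenerate bases are an error
#'   because their Tm is undefined).
#' @param method \code{"nearest-neighbor"} (default), \code{"wallace"} or
#'   \code{"gc-fraction"}.
#' @param na monovalent cation concentration, mol/L (default 0.05).
#' @param primerConc total primer concentration, mol/L (default 5e-7).
#' @return Melting temperature in degrees Celsius.
#' @examples
#' meltingTemperature("AAAAAAAAAAAAAAA", method = "wallace")  # 30
#' @export
meltingTemperature <- function(seq,
                               method = c("nearest-neighbor", "wallace",
                                          "gc-fraction"),
                               na = 0.05, primerConc = 5e-7) {
  method <- match.arg(method)
  seq <- validateSequence(seq, "strict-dna")
  n <- nchar(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  gc <- sum(chars %in% c("G", "C"))
  if (method == "wallace")
    return(2 * (n - gc) + 4 * gc)
  if (method == "gc-fraction")
    return(81.5 + 16.6 * log10(na) + 0.41 * (100 * gc / n) - 600 / n)
  if (n < 2L)
    stop("nearest-neighbor Tm requires at least 2 bases", call. = FALSE)
  steps <- paste0(chars[-n], chars[-1L])
  dH <- sum(NN_DH[steps])
  dS <- sum(NN_DS[steps])
  for (endBase in chars[c(1L, n)]) {
    init <- if (endBase %in% c("G", "C")) NN_INIT[["GC"]] else NN_INIT[["AT"]]
    dH <- dH + init[["dH"]]
    dS <- dS + init[["dS"]]
  }
  dS <- dS + 0.368 * (n - 1) * log(na)
  1000 * dH / (dS + GAS_CONSTANT * log(primerConc / 4)) - 273.15
}
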