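# Average residue masses (Da), Expasy convention, plus one water per chain.
RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01524

# Bjellqvist pKa values as used by the ProtParam algorithm.
PK_POSITIVE <- c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98)
PK_NEGATIVE <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
PK_NTERM_BY_RESIDUE <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82,
                         V = 7.44, E = 7.7)
PK_CTERM_BY_RESIDUE <- c(D = 4.55, E = 4.75)

# Gill-von Hippel molar extinction coefficients at 280 nm (M^-1 cm^-1).
EPS_TRP <- 5500
EPS_TYR <- 1490
EPS_CYSTINE <- 125

aaCounts <- function(protein) {
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  table(factor(chars, levels = AA20))
}

#' Molecular weight of a protein
#'
#' Sum of average residue masses plus one water, as computed by the ProtParam
#' algorithm.
#'
#' @param protein protein sequence (20 one-letter codes).
#' @return Molecular weight in Da.
#' @examples
#' molecularWeight("GG")  # ~132.12
#' @export
molecularWeight <- function(protein) {
  protein <- validateSequence(protein, "protein")
  if (!nzchar(protein)) stop("empty protein sequence", call. = FALSE)
  cnt <- aaCounts(protein)
  sum(cnt * RESIDUE_MASS[names(cnt)]) + WATER_MASS
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the termini and the D, E, C, Y, H, K, R
#' side chains with the Bjellqvist pKa set (residue-specific terminal pKa
#' values where defined).
#'
#' @param protein protein sequence.
#' @param pH pH value (may be a vector).
#' @return Net charge (same length as \code{pH}).
#' @export
chargeAtPh <- function(protein, pH) {
  protein <- validateSequence(protein, "protein")
  cnt <- aaCounts(protein)
  first <- substr(protein, 1L, 1L)
  last <- substr(protein, nchar(protein), nchar(protein))
  pkN <- if (first %in% names(PK_NTERM_BY_RESIDUE))
    PK_NTERM_BY_RESIDUE[[first]] else PK_POSITIVE[["Nterm"]]
  pkC <- if (last %in% names(PK_CTERM_BY_RESIDUE))
    PK_CTERM_BY_RESIDUE[[last]] else PK_NEGATIVE[["Cterm"]]
  pos <- c(Nterm = 1, K = unname(cnt["K"]), R = unname(cnt["R"]),
           H = unname(cnt["H"]))
  posPk <- c(Nterm = pkN, K = PK_POSITIVE[["K"]], R = PK_POSITIVE[["R"]],
             H = PK_POSITIVE[["H"]])
  neg <- c(Cterm = 1, D = unname(cnt["D"]), E = unname(cnt["E"]),
           C = unname(cnt["C"]), Y = unname(cnt["Y"]))
  negPk <- c(Cterm = pkC, D = PK_NEGATIVE[["D"]], E = PK_NEGATIVE[["E"]],
             C = PK_NEGATIVE[["C"]], Y = PK_NEGATIVE[["Y"]])
  vapply(pH, function(p) {
    sum(pos / (1 + 10^(p - posPk))) - sum(neg / (1 + 10^(negPk - p)))
  }, numeric(1))
}

#' Isoelectric point
#'
#' Bisection on the net charge (see [chargeAtPh()]) over pH 0-14 until the
#' absolute charge falls below 1e-4 or 100 iterations have run; always
#' converges on that bracket because the charge is monotonically decreasing
#' in pH.
#'
#' @param protein protein sequence.
#' @return The isoelectric point in pH units.
#' @export
isoelectricPoint <- function(protein) {
  protein <- validateSequence(protein, "protein")
  if (!nzchar(protein)) stop("empty protein sequence", call. = FALSE)
  lo <- 0; hi <- 14
  for (i in seq_len(100L)) {
    mid <- (lo + hi) / 2
    q <- chargeAtPh(protein, mid)
    if (abs(q) < 1e-4) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Extinction coefficient at 280 nm
#'
#' Gill-von Hippel prediction: 5500 per tryptophan plus 1490 per tyrosine
#' (reduced form); the cystine value additionally counts 125 per assumed
#' cystine pair (floor(nCys / 2) pairs).
#'
#' @param protein protein sequence.
#' @return Named numeric vector \code{c(reduced, cystine)}, M^-1 cm^-1.
#' @examples
#' extinction280("WYYG")  # reduced 8480, cystine 8480
#' @export
extinction280 <- function(protein) {
  protein <- validateSequence(protein, "protein")
  if (!nzchar(protein)) stop("empty protein sequence", call. = FALSE)
  cnt <- aaCounts(protein)
  reduced <- EPS_TRP * unname(cnt["W"]) + EPS_TYR * unname(cnt["Y"])
  cystine <- reduced + EPS_CYSTINE * (unname(cnt["C"]) %/% 2L)
  c(reduced = reduced, cystine = cystine)
}

#' Full property set for a protein
#'
#' @param protein protein sequence.
#' @return A [PropertySet-class] with MW, pI and both extinction
#'   coefficients.
#' @export
propertySet <- function(protein) {
  eps <- extinction280(protein)
  new("PropertySet", mw = molecularWeight(protein),
      pi = isoelectricPoint(protein),
      eps280Reduced = unname(eps["reduced"]),
      eps280Cystine = unname(eps["cystine"]))
}
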