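#' Monoisotopic mass constants
#'
#' All mass arithmetic in the package runs on a single immutable monoisotopic
#' scale: the standard residue masses of the 20 amino acids, the four
#' monosaccharide residue masses used in the four-digit glycan nomenclature
#' (HexNAc, Hex, Fuc, Neu5Ac), water and the proton. None of the three
#' haptoglobin site peptides contains cysteine, so no fixed modification
#' (e.g. carbamidomethylation) ever applies; variable modifications are not
#' modeled.
#'
#' @return A named list with elements `aa` (named numeric vector of residue
#'   masses, Da), `sugar` (named numeric vector: `hexnac`, `hex`, `fuc`,
#'   `neuac`), `water` and `proton` (Da).
#' @examples
#' mass_constants()$sugar[["hexnac"]]
#' @export
mass_constants <- function() .glyco_masses

.glyco_masses <- list(
  aa = c(
    A = 71.037114, R = 156.101111, N = 114.042927, D = 115.026943,
    C = 103.009185, E = 129.042593, Q = 128.058578, G = 57.021464,
    H = 137.058912, I = 113.084064, L = 113.084064, K = 128.094963,
    M = 131.040485, F = 147.068414, P = 97.052764, S = 87.032028,
    T = 101.047679, W = 186.079313, Y = 163.063329, V = 99.068414
  ),
  sugar = c(
    hexnac = 203.079373,
    hex    = 162.052824,
    fuc    = 146.057909,
    neuac  = 291.095417
  ),
  water  = 18.010565,
  proton = 1.007276
)

# Oxonium marker ions (singly charged, monoisotopic): HexNAc and Neu5Ac
# and their water losses. Diagnostic only, never quantifiers.
.oxonium_ions <- c(
  "HexNAc"       = 204.086649,
  "HexNAc-H2O"   = 186.076084,
  "Neu5Ac"       = 292.102693,
  "Neu5Ac-H2O"   = 274.092128
)

#' Monoisotopic peptide mass
#'
#' Residue-mass sum plus one water, on the scale of [mass_constants()].
#'
#' @param sequence Amino-acid string using one-letter codes.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_mass("NLFLNHSE")
#' @export
peptide_mass <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  res <- strsplit(sequence, "")[[1]]
  bad <- setdiff(res, names(.glyco_masses$aa))
  if (length(bad)) {
    stop("unknown amino-acid code(s): ", paste(unique(bad), collapse = ", "))
  }
  sum(.glyco_masses$aa[res]) + .glyco_masses$water
}
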