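#' Monoisotopic mass constants
#'
#' Fixed physical constants used throughout the pipeline: the proton mass
#' (charge carrier), the 13C-12C isotope spacing that separates members of an
#' isotopic cluster, the mass of water (added once per peptide on hydrolysis),
#' and the methionine-oxidation mass shift.
#'
#' @return Named list with elements `proton`, `isotope_spacing`, `water` and
#'   `oxidation_m`, all in Da.
#' @export
#' @examples
#' mass_constants()$isotope_spacing / 3  # isotope spacing at charge 3, ~0.334 Da
mass_constants <- function() {
  list(
    proton          = 1.0072765,
    isotope_spacing = 1.0033548,
    water           = 18.0105646,
    oxidation_m     = 15.9994
  )
}

# atomic monoisotopic masses (Da)
.ATOM <- c(
  H = 1.00782503207,
  C = 12,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

# residue (= amino acid minus water) elemental compositions, columns C H N O S
.RESIDUE_FORMULA <- matrix(c(
  2,  3, 1, 1, 0, # G
  3,  5, 1, 1, 0, # A
  3,  5, 1, 2, 0, # S
  5,  7, 1, 1, 0, # P
  5,  9, 1, 1, 0, # V
  4,  7, 1, 2, 0, # T
  3,  5, 1, 1, 1, # C
  6, 11, 1, 1, 0, # L
  6, 11, 1, 1, 0, # I
  4,  6, 2, 2, 0, # N
  4,  5, 1, 3, 0, # D
  5,  8, 2, 2, 0, # Q
  6, 12, 2, 1, 0, # K
  5,  7, 1, 3, 0, # E
  5,  9, 1, 1, 1, # M
  6,  7, 3, 1, 0, # H
  9,  9, 1, 1, 0, # F
  6, 12, 4, 1, 0, # R
  9,  9, 1, 2, 0, # Y
  11, 10, 2, 1, 0  # W
), ncol = 5, byrow = TRUE,
  dimnames = list(c("G", "A", "S", "P", "V", "T", "C", "L", "I", "N",
                    "D", "Q", "K", "E", "M", "H", "F", "R", "Y", "W"),
                  c("C", "H", "N", "O", "S")))

# monoisotopic residue masses derived from the elemental compositions
.RESIDUE_MASS <- drop(.RESIDUE_FORMULA %*% .ATOM[colnames(.RESIDUE_FORMULA)])
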