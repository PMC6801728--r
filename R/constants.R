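#' @keywords internal
"_PACKAGE"

## 20-letter amino-acid alphabet (upper case). 'X' is tolerated on input but is
## excluded from identities, frequencies and hydropathy means.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP_CHAR <- "-"

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values in Kyte-Doolittle units (range -4.5 to 4.5).
#' Used by [hydropathy_profile()] to build consensus transmembrane profiles.
#'
#' @return Named numeric vector over the 20 amino acids.
#' @export
#' @examples
#' kyte_doolittle()[["I"]]  # 4.5
kyte_doolittle <- function() {
  c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
    I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
    R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)
}

#' Monoisotopic mass constants for peptide chemistry
#'
#' Residue masses are monoisotopic and refer to the dehydrated residue within a
#' peptide chain; a free peptide adds one water. The hexose delta is the
#' monoisotopic increment of one mannose attached to tryptophan
#' (C-mannosylation); carbamidomethyl is the standard Cys alkylation adduct.
#'
#' @return List with `residues` (named numeric, 20 values), `water`, `proton`,
#'   `hexose` and `carbamidomethyl`, all in Da.
#' @export
mass_constants <- function() {
  list(
    residues = c(
      G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
      T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
      N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
      E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
      R = 156.10111, Y = 163.06333, W = 186.07931),
    water = 18.010565,
    proton = 1.007276,
    hexose = 162.052824,
    carbamidomethyl = 57.021464
  )
}

## internal shorthand
.kd <- kyte_doolittle()
LOG2_20 <- log2(20)
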