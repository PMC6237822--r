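#' Physical constants and reference tables
#'
#' Gas constant in kcal mol^-1 K^-1, used for every free-energy expression
#' in the package so that all energies are in kcal/mol.
#'
#' @format A length-one numeric.
#' @export
R_KCAL <- 1.987e-3

#' Average residue masses (Da) for the 20 standard amino acids
#'
#' Average (not monoisotopic) masses of amino-acid residues, i.e. the free
#' amino acid minus one water. Summing residue masses and adding one water
#' (18.01528 Da) gives the average mass of the peptide chain.
#'
#' @format Named numeric vector, one-letter codes as names.
#' @export
RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

#' @rdname RESIDUE_MASS
#' @export
WATER_MASS <- 18.01528

AA_ALPHABET <- names(RESIDUE_MASS)

#' pKa tables for isoelectric-point calculation
#'
#' Named sets of side-chain and terminal pKa values. `"emboss"` follows the
#' widely used EMBOSS defaults; `"lehninger"` follows standard textbook
#' values. Each table records pKa values for the N-terminal amine
#' (`nterm`), the C-terminal carboxyl (`cterm`) and the ionizable side
#' chains. The table actually used is recorded in every result for
#' provenance.
#'
#' @format A named list of named numeric vectors.
#' @export
PKA_SETS <- list(
  emboss = c(nterm = 8.6, cterm = 3.6,
             K = 10.8, R = 12.5, H = 6.5, D = 3.9, E = 4.1,
             C = 8.5, Y = 10.1),
  lehninger = c(nterm = 9.69, cterm = 2.34,
                K = 10.53, R = 12.48, H = 6.0, D = 3.65, E = 4.25,
                C = 8.18, Y = 10.07)
)

# residues carrying a positive (deprotonated-neutral) vs negative
# (protonated-neutral) ionizable side chain
POSITIVE_SIDE_CHAINS <- c("K", "R", "H")
NEGATIVE_SIDE_CHAINS <- c("D", "E", "C", "Y")
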