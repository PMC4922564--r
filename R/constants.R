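#' Canonical evidence-matrix vocabulary
#'
#' Identifiers for the pairwise similarity matrices the framework knows
#' about, in the canonical order used when rendering integration equations.
#' Sequence-derived matrices (alignment scores), structure-derived matrices
#' (structural alignment size/identity/TM-score, structural-signature
#' distances), genomic-context scores, physicochemical property
#' differences, annotation overlaps, and active-site comparisons.
#'
#' @format Character vector of matrix identifiers.
#' @export
isofam_matrix_names <- c(
  "seqAliG", "seqAliL",
  "strAliSize", "strAliId", "strAliScr",
  "csmDist",
  "neighborhood", "fusion", "cooccurrence", "coexpression",
  "difMolWeight", "difIsoPoint",
  "difAliphRes", "difAromRes", "difPolarRes", "difChargedRes",
  "difBasicRes", "difAcidicRes",
  "aaCompDist",
  "difInstab", "difGRAVY",
  "interpro", "go",
  "ASid", "ASscr"
)

# The 20 standard amino acids, one-letter code, alphabetical.
AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

#' Average residue masses (Da)
#'
#' Average (isotope-abundance weighted) masses of amino-acid residues,
#' i.e. free amino acid minus one water; add one water
#' (\code{isofam_water_mass}) for the mass of an intact chain.
#'
#' @format Named numeric vector over the 20 standard residues.
#' @export
residue_masses <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

#' @rdname residue_masses
#' @export
isofam_water_mass <- 18.01524

#' Kyte-Doolittle hydropathy values
#'
#' Per-residue hydropathy indices; the mean over a sequence is its GRAVY
#' (grand average of hydropathy).
#'
#' @format Named numeric vector over the 20 standard residues.
#' @export
kyte_doolittle <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

#' Dayhoff reference amino-acid composition
#'
#' Reference molar percentages of the 20 amino acids (Dayhoff's survey of
#' protein composition).  The composition array used by
#' [sequence_properties()] divides a sequence's observed molar percentage
#' of each residue by these reference values, so 1 means "as frequent as
#' in an average protein".
#'
#' @format Named numeric vector (molar percent) over the 20 residues.
#' @export
dayhoff_frequencies <- c(
  A = 8.6, R = 4.9, N = 4.3, D = 5.5, C = 2.9,
  Q = 3.9, E = 6.0, G = 8.4, H = 2.0, I = 4.5,
  L = 7.4, K = 6.6, M = 1.7, F = 3.6, P = 5.2,
  S = 7.0, T = 6.1, W = 1.3, Y = 3.4, V = 6.6
)

#' Amino-acid class membership (pepstats convention)
#'
#' Residue classes whose molar percentages are compared between proteins:
#' aliphatic, aromatic, non-polar, polar, charged, basic and acidic.
#'
#' @format Named list of character vectors of one-letter residue codes.
#' @export
amino_acid_classes <- list(
  aliphatic = c("A","I","L","V"),
  aromatic  = c("F","H","W","Y"),
  nonpolar  = c("A","C","F","G","I","L","M","P","V","W","Y"),
  polar     = c("D","E","H","K","N","Q","R","S","T"),
  charged   = c("D","E","H","K","R"),
  basic     = c("H","K","R"),
  acidic    = c("D","E")
)

# BLOSUM62 over the standard alphabet, fetched once from Biostrings.
blosum62_matrix <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
})
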