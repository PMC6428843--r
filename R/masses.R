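# Monoisotopic mass constants shared across the package.
# Residue masses are sums of standard atomic monoisotopic masses
# (CODATA/IUPAC values), e.g. Hex = C6H10O5.

#' Physical mass constants (monoisotopic, Da)
#'
#' Named numeric vector with the monoisotopic masses used throughout the
#' package: `proton` (mass of H+), `water` (H2O), `ammonia` (NH3),
#' `hydrogen` (H atom).
#'
#' @format Named numeric vector.
#' @export
MASS_CONST <- c(
  proton   = 1.007276466,
  water    = 18.010565,
  ammonia  = 17.026549,
  hydrogen = 1.007825032
)

#' Monosaccharide residue mass table
#'
#' Monoisotopic residue masses (Da) of the monosaccharide building blocks
#' recognised by the composition grammar. The table is closed: parsing a
#' composition string never yields a symbol that is absent from it.
#' `Phospho` encodes a phosphate modification (HPO3) and is how
#' mannose-6-phosphate glycans are written, e.g.
#' `"HexNAc(2)Hex(7)Phospho(1)"`.
#'
#' @format Named numeric vector; names are the residue symbols in the
#'   canonical output order.
#' @export
MONOSACCHARIDES <- c(
  HexNAc  = 203.079373,  # C8H13NO5
  Hex     = 162.052824,  # C6H10O5
  Fuc     = 146.057909,  # C6H10O4
  NeuAc   = 291.095417,  # C11H17NO8
  Phospho = 79.966331    # HPO3
)

#' Amino-acid residue mass table
#'
#' Monoisotopic residue masses (Da) of the 20 canonical amino acids
#' (residue = amino acid minus water).
#'
#' @format Named numeric vector keyed by one-letter code.
#' @export
AMINO_ACIDS <- c(
  G =  57.021464, A =  71.037114, S =  87.032028, P =  97.052764,
  V =  99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

#' Default fixed modifications
#'
#' Carbamidomethylation of cysteine (+57.021464 Da), the standard
#' alkylation adduct applied during sample preparation.
#'
#' @format Named numeric vector: residue letter -> mass delta (Da).
#' @export
DEFAULT_FIXED_MODS <- c(C = 57.021464)
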