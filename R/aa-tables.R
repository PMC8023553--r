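# Amino-acid reference tables used across the package.

#' @name aa_tables
#' @title Amino-acid reference tables
#' @description
#' Reference constants shared by the featurization modules: the 20 standard
#' residues, Gly-X-Gly maximum accessible areas (Sander-Rost constants, in
#' square Angstrom), the Kyte-Doolittle hydropathy scale, van der Waals
#' radii, and physicochemical residue subsets.
NULL

# canonical residue order used for PSSM columns and distributions
AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

names(AA1) <- AA3
AA3_BY_ONE <- stats::setNames(AA3, AA1)

#' Convert three-letter residue codes to one-letter codes
#'
#' @param resn character vector of three-letter codes.
#' @return one-letter codes; `NA` for non-standard names.
#' @export
aa_three_to_one <- function(resn) {
  unname(AA1[toupper(resn)])
}

# Gly-X-Gly maximum accessible areas (A^2), Sander-Rost constants
MAX_AREA <- c(
  ALA = 106, ARG = 248, ASN = 157, ASP = 163, CYS = 135,
  GLN = 198, GLU = 194, GLY = 84,  HIS = 184, ILE = 169,
  LEU = 165, LYS = 205, MET = 188, PHE = 197, PRO = 136,
  SER = 130, THR = 142, TRP = 227, TYR = 222, VAL = 142)

#' Gly-X-Gly reference areas
#'
#' Maximum accessible surface areas of residue X in an extended Gly-X-Gly
#' tripeptide, used to normalize ASA into relative solvent accessibility.
#'
#' @return named numeric vector (A^2), one entry per standard residue.
#' @export
max_area_table <- function() MAX_AREA

# Kyte-Doolittle hydropathy index (higher = more hydrophobic)
KYTE_DOOLITTLE <- c(
  ILE =  4.5, VAL =  4.2, LEU =  3.8, PHE =  2.8, CYS =  2.5,
  MET =  1.9, ALA =  1.8, GLY = -0.4, THR = -0.7, SER = -0.8,
  TRP = -0.9, TYR = -1.3, PRO = -1.6, HIS = -3.2, GLU = -3.5,
  GLN = -3.5, ASP = -3.5, ASN = -3.5, LYS = -3.9, ARG = -4.5)

#' Kyte-Doolittle hydropathy scale
#'
#' @return named numeric vector over the 20 standard residues (three-letter
#'   names); higher values are more hydrophobic.
#' @export
kyte_doolittle <- function() KYTE_DOOLITTLE

# van der Waals radii (A); conservative Bondi-like set, `.default` is the
# fallback for elements not listed
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
               P = 1.80, SE = 1.90, .default = 1.80)

#' Default van der Waals radii
#'
#' @return named numeric vector of radii in Angstrom; the `.default` entry is
#'   applied to elements without their own value when `allow_default = TRUE`
#'   in [compute_asa()].
#' @export
vdw_radii <- function() VDW_RADII

#' Physicochemical residue subsets
#'
#' Named subsets used by the summary statistics: charged, positively and
#' negatively charged, polar, non-polar, aromatic, the excluded set
#' (Cys/Gly/Pro) and the small GAS set (Gly/Ala/Ser) relevant to
#' membrane-protein packing.
#'
#' @return named list of three-letter residue code vectors.
#' @export
residue_subsets <- function() {
  list(
    charged   = c("ASP", "GLU", "LYS", "ARG"),
    positive  = c("LYS", "ARG"),
    negative  = c("ASP", "GLU"),
    polar     = c("SER", "THR", "ASN", "GLN", "TYR", "HIS"),
    non_polar = c("ALA", "VAL", "ILE", "LEU", "MET", "PHE", "TRP"),
    aromatic  = c("PHE", "TRP", "TYR"),
    excluded  = c("CYS", "GLY", "PRO"),
    gas       = c("GLY", "ALA", "SER"))
}

# non-standard residue name -> standard parent; MSE/SEC additionally rename
# the selenium atom to the sulfur position of the parent residue
NONSTANDARD_MAP <- c(
  MSE = "MET", SEC = "CYS", CSO = "CYS", CME = "CYS", OCS = "CYS",
  MLY = "LYS", KCX = "LYS", LLP = "LYS",
  SEP = "SER", TPO = "THR", PTR = "TYR",
  HYP = "PRO", PCA = "GLU", CGU = "GLU", FME = "MET")

#' Default non-standard residue mapping
#'
#' @return named character vector mapping modified residue names to their
#'   standard three-letter parent (e.g. selenomethionine `MSE` to `MET`).
#' @export
nonstandard_map <- function() NONSTANDARD_MAP
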