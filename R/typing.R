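# Chemical atom typing for interaction detection: hydrogen-bond donors and
# acceptors, charged groups, aromatic rings, and apolar carbons. Atom names
# follow PDB conventions for the 20 standard residues.

# backbone donors/acceptors apply to every residue (PRO has no N-H donor)
BACKBONE_DONOR <- "N"
BACKBONE_ACCEPTOR <- c("O", "OXT")

SIDECHAIN_DONORS <- list(
  ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
  HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
  TRP = "NE1", TYR = "OH", CYS = "SG")

SIDECHAIN_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  HIS = c("ND1", "NE2"), SER = "OG", THR = "OG1", TYR = "OH", MET = "SD")

CATIONIC_GROUPS <- list(
  LYS = list(nz = "NZ"),
  ARG = list(guanidinium = c("NE", "NH1", "NH2", "CZ")),
  HIS = list(imidazolium = c("ND1", "NE2")))   # only when HIS charged

ANIONIC_GROUPS <- list(
  ASP = list(carboxylate = c("OD1", "OD2", "CG")),
  GLU = list(carboxylate = c("OE1", "OE2", "CD")))

AROMATIC_RINGS <- list(
  PHE = list(ring6 = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(ring6 = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TRP = list(ring5 = c("CG", "CD1", "CD2", "NE1", "CE2"),
             ring6 = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")),
  HIS = list(ring5 = c("CG", "ND1", "CD2", "CE1", "NE2")))

# side-chain carbons bonded only to carbon/hydrogen
APOLAR_CARBONS <- list(
  ALA = "CB", VAL = c("CB", "CG1", "CG2"),
  LEU = c("CB", "CG", "CD1", "CD2"), ILE = c("CB", "CG1", "CG2", "CD1"),
  MET = "CB", PRO = c("CB", "CG"), PHE = c("CB", "CG", "CD1", "CD2",
                                           "CE1", "CE2", "CZ"),
  TRP = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2"),
  LYS = c("CB", "CG", "CD"), ARG = c("CB", "CG"),
  GLU = c("CB", "CG"), GLN = c("CB", "CG"),
  ASP = "CB", ASN = "CB", THR = "CG2", HIS = "CB")

#' Interaction atom-typing tables
#'
#' The donor/acceptor, charged-group, aromatic-ring and apolar-carbon
#' definitions used by the interaction detectors, covering all 20 standard
#' residues (backbone N is a donor except in proline; backbone O/OXT are
#' acceptors everywhere).
#'
#' @return named list of the typing tables.
#' @export
atom_typing <- function() {
  list(backbone_donor = BACKBONE_DONOR, backbone_acceptor = BACKBONE_ACCEPTOR,
       sidechain_donors = SIDECHAIN_DONORS,
       sidechain_acceptors = SIDECHAIN_ACCEPTORS,
       cationic_groups = CATIONIC_GROUPS, anionic_groups = ANIONIC_GROUPS,
       aromatic_rings = AROMATIC_RINGS, apolar_carbons = APOLAR_CARBONS)
}

# logical mask over an atom table
is_donor_atom <- function(atoms) {
  bb <- atoms$name == BACKBONE_DONOR & atoms$resn != "PRO"
  sc <- mapply(function(r, n) n %in% (SIDECHAIN_DONORS[[r]] %||% character()),
               atoms$resn, atoms$name)
  bb | sc
}

is_acceptor_atom <- function(atoms) {
  bb <- atoms$name %in% BACKBONE_ACCEPTOR
  sc <- mapply(function(r, n)
    n %in% (SIDECHAIN_ACCEPTORS[[r]] %||% character()),
    atoms$resn, atoms$name)
  bb | sc
}

is_apolar_carbon <- function(atoms) {
  mapply(function(r, n) n %in% (APOLAR_CARBONS[[r]] %||% character()),
         atoms$resn, atoms$name)
}
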