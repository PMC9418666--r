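# Element and residue lookup tables used by atom-role assignment and the
# contact typer. Radii in Angstrom (Bondi vdW set, Cordero covalent set).

.ELEMENT_VDW <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  NA_ = 2.27, K = 2.75, MG = 1.73, CA = 2.31, ZN = 1.39, FE = 1.60,
  MN = 1.60, CU = 1.40, CO = 1.60, NI = 1.60
)

.ELEMENT_COV <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
  F = 0.57, CL = 1.02, BR = 1.20, I = 1.39,
  NA_ = 1.66, K = 2.03, MG = 1.41, CA = 1.76, ZN = 1.22, FE = 1.32,
  MN = 1.39, CU = 1.32, CO = 1.26, NI = 1.24
)

.METALS <- c("NA", "K", "MG", "CA", "ZN", "FE", "MN", "CU", "CO", "NI")
.HALOGENS <- c("CL", "BR", "I")  # F is a poor halogen-bond donor; excluded

.KNOWN_ELEMENTS <- c("H", "C", "N", "O", "S", "P", "F", .HALOGENS, .METALS)

element_vdw <- function(element) {
  key <- ifelse(toupper(element) == "NA", "NA_", toupper(element))
  r <- unname(.ELEMENT_VDW[key])
  r[is.na(r)] <- 1.70
  r
}

element_cov <- function(element) {
  key <- ifelse(toupper(element) == "NA", "NA_", toupper(element))
  r <- unname(.ELEMENT_COV[key])
  r[is.na(r)] <- 0.76
  r
}

.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

# Per-residue side-chain role templates: which chemical roles each named atom
# carries. Backbone roles (N donor, O acceptor/carbonyl oxygen, C carbonyl
# carbon) are shared by all residues and added separately.
.SIDECHAIN_ROLES <- list(
  ALA = list(CB = c("hydrophobe")),
  ARG = list(CB = "hydrophobe", CG = "hydrophobe",
             NE = c("cation", "donor"), NH1 = c("cation", "donor"),
             NH2 = c("cation", "donor")),
  ASN = list(CB = "hydrophobe", CG = "carbonyl_carbon",
             OD1 = c("acceptor", "carbonyl_oxygen"), ND2 = "donor"),
  ASP = list(CB = "hydrophobe", CG = "carbonyl_carbon",
             OD1 = c("anion", "acceptor"), OD2 = c("anion", "acceptor")),
  CYS = list(CB = "hydrophobe", SG = c("donor", "acceptor")),
  GLN = list(CB = "hydrophobe", CG = "hydrophobe", CD = "carbonyl_carbon",
             OE1 = c("acceptor", "carbonyl_oxygen"), NE2 = "donor"),
  GLU = list(CB = "hydrophobe", CG = "hydrophobe", CD = "carbonyl_carbon",
             OE1 = c("anion", "acceptor"), OE2 = c("anion", "acceptor")),
  GLY = list(),
  HIS = list(CB = "hydrophobe",
             CG = "aromatic", ND1 = c("aromatic", "donor", "acceptor"),
             CD2 = c("aromatic", "hydrophobe"), CE1 = c("aromatic", "hydrophobe"),
             NE2 = c("aromatic", "donor", "acceptor")),
  ILE = list(CB = "hydrophobe", CG1 = "hydrophobe", CG2 = "hydrophobe",
             CD1 = "hydrophobe"),
  LEU = list(CB = "hydrophobe", CG = "hydrophobe", CD1 = "hydrophobe",
             CD2 = "hydrophobe"),
  LYS = list(CB = "hydrophobe", CG = "hydrophobe", CD = "hydrophobe",
             NZ = c("cation", "donor")),
  MET = list(CB = "hydrophobe", CG = "hydrophobe", SD = "acceptor"),
  PHE = list(CB = "hydrophobe",
             CG = c("aromatic", "hydrophobe"), CD1 = c("aromatic", "hydrophobe"),
             CD2 = c("aromatic", "hydrophobe"), CE1 = c("aromatic", "hydrophobe"),
             CE2 = c("aromatic", "hydrophobe"), CZ = c("aromatic", "hydrophobe")),
  PRO = list(CB = "hydrophobe", CG = "hydrophobe"),
  SER = list(OG = c("donor", "acceptor")),
  THR = list(OG1 = c("donor", "acceptor"), CG2 = "hydrophobe"),
  TRP = list(CB = "hydrophobe",
             CG = c("aromatic", "hydrophobe"), CD1 = c("aromatic", "hydrophobe"),
             NE1 = c("aromatic", "donor"),
             CD2 = c("aromatic", "hydrophobe"), CE2 = c("aromatic", "hydrophobe"),
             CE3 = c("aromatic", "hydrophobe"), CZ2 = c("aromatic", "hydrophobe"),
             CZ3 = c("aromatic", "hydrophobe"), CH2 = c("aromatic", "hydrophobe")),
  TYR = list(CB = "hydrophobe",
             CG = c("aromatic", "hydrophobe"), CD1 = c("aromatic", "hydrophobe"),
             CD2 = c("aromatic", "hydrophobe"), CE1 = c("aromatic", "hydrophobe"),
             CE2 = c("aromatic", "hydrophobe"), CZ = c("aromatic", "hydrophobe"),
             OH = c("donor", "acceptor")),
  VAL = list(CB = "hydrophobe", CG1 = "hydrophobe", CG2 = "hydrophobe")
)

# Aromatic ring atom-name sets per residue (TRP uses the fused system).
.RESIDUE_RINGS <- list(
  PHE = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(c("CG", "CD1", "NE1", "CD2", "CE2"),
             c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))
)

# Covalently bonded heavy-atom parent of each named side-chain atom, used as
# the heavy-atom surrogate when no explicit hydrogens are present and for
# donor/halogen angle checks.
.ATOM_PARENT <- c(
  N = "CA", O = "C", C = "CA", CA = "N", CB = "CA", OXT = "C",
  CG = "CB", CG1 = "CB", CG2 = "CB", OG = "CB", OG1 = "CB", SG = "CB",
  CD = "CG", CD1 = "CG", CD2 = "CG", OD1 = "CG", OD2 = "CG", ND1 = "CG",
  ND2 = "CG", SD = "CG",
  CE = "CD", CE1 = "CD1", CE2 = "CD2", CE3 = "CD2", NE = "CD", NE1 = "CD1",
  NE2 = "CD2", OE1 = "CD", OE2 = "CD",
  CZ = "CE1", CZ2 = "CE2", CZ3 = "CE3", NZ = "CE", OH = "CZ", CH2 = "CZ2",
  NH1 = "CZ", NH2 = "CZ"
)

backbone_roles <- function(residue_name) {
  roles <- list(
    N = if (identical(residue_name, "PRO")) character(0) else "donor",
    O = c("acceptor", "carbonyl_oxygen"),
    C = "carbonyl_carbon",
    OXT = c("anion", "acceptor")
  )
  roles
}

#' All recognised interaction roles an atom may carry
#'
#' @return character vector of role names.
#' @export
atom_roles_universe <- function() {
  c("donor", "acceptor", "cation", "anion", "aromatic", "hydrophobe",
    "halogen", "carbonyl_carbon", "carbonyl_oxygen")
}
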