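# Residue chemistry tables: heavy-atom composition and covalent bonds for
# the 20 standard amino acids, internal-coordinate side-chain templates for
# the residue types the peptide builder supports, rotamer states, polar
# hydrogen placement rules, donor/acceptor definitions, van der Waals radii
# and knowledge-based atom typing.

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
         "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
         "TYR", "VAL")

AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V")

aa_three_to_one <- function(res) {
  out <- AA1[res]
  out[is.na(out)] <- "X"
  unname(out)
}

# Side-chain heavy-atom bonds per residue type (backbone bonds are implicit:
# N-CA, CA-C, C-O, CA-CB for non-GLY, C-OXT at the C-terminus).
SIDECHAIN_BONDS <- list(
  ALA = NULL,
  ARG = rbind(c("CB","CG"), c("CG","CD"), c("CD","NE"), c("NE","CZ"),
              c("CZ","NH1"), c("CZ","NH2")),
  ASN = rbind(c("CB","CG"), c("CG","OD1"), c("CG","ND2")),
  ASP = rbind(c("CB","CG"), c("CG","OD1"), c("CG","OD2")),
  CYS = rbind(c("CB","SG")),
  GLN = rbind(c("CB","CG"), c("CG","CD"), c("CD","OE1"), c("CD","NE2")),
  GLU = rbind(c("CB","CG"), c("CG","CD"), c("CD","OE1"), c("CD","OE2")),
  GLY = NULL,
  HIS = rbind(c("CB","CG"), c("CG","ND1"), c("CG","CD2"), c("ND1","CE1"),
              c("CD2","NE2"), c("CE1","NE2")),
  ILE = rbind(c("CB","CG1"), c("CB","CG2"), c("CG1","CD1")),
  LEU = rbind(c("CB","CG"), c("CG","CD1"), c("CG","CD2")),
  LYS = rbind(c("CB","CG"), c("CG","CD"), c("CD","CE"), c("CE","NZ")),
  MET = rbind(c("CB","CG"), c("CG","SD"), c("SD","CE")),
  PHE = rbind(c("CB","CG"), c("CG","CD1"), c("CG","CD2"), c("CD1","CE1"),
              c("CD2","CE2"), c("CE1","CZ"), c("CE2","CZ")),
  PRO = rbind(c("CB","CG"), c("CG","CD"), c("CD","N")),
  SER = rbind(c("CB","OG")),
  THR = rbind(c("CB","OG1"), c("CB","CG2")),
  TRP = rbind(c("CB","CG"), c("CG","CD1"), c("CG","CD2"), c("CD1","NE1"),
              c("NE1","CE2"), c("CD2","CE2"), c("CD2","CE3"), c("CE2","CZ2"),
              c("CE3","CZ3"), c("CZ2","CH2"), c("CZ3","CH2")),
  TYR = rbind(c("CB","CG"), c("CG","CD1"), c("CG","CD2"), c("CD1","CE1"),
              c("CD2","CE2"), c("CE1","CZ"), c("CE2","CZ"), c("CZ","OH")),
  VAL = rbind(c("CB","CG1"), c("CB","CG2"))
)

# Backbone geometry shared by the builder and the bonded-term parameter
# table, Engh-Huber style ideal values.  Lengths in Angstrom, angles deg.
BACKBONE_GEOM <- list(
  b_N_CA  = 1.458, b_CA_C  = 1.525, b_C_N   = 1.329, b_C_O  = 1.231,
  b_CA_CB = 1.530, b_C_OXT = 1.249,
  a_N_CA_C  = 111.0, a_CA_C_N  = 116.2, a_C_N_CA  = 121.7,
  a_CA_C_O  = 120.8, a_N_CA_CB = 110.5, a_C_CA_CB = 110.1,
  a_O_C_OXT = 122.0,
  d_improper_CB = 122.7   # dihedral C-N-CA-CB for L-amino acids
)

# Internal-coordinate templates for side chains beyond CB.  Each row places
# one atom: refs are three previously placed atom names of the same residue
# (a, b, c with the new atom bonded to c), bond (A), angle b-c-new (deg) and
# a dihedral expression "chiK" or "chiK+offset" (deg).  The builder supports
# this residue subset; unknown types fall back to ALA side-chain truncation.
SIDECHAIN_ZMAT <- list(
  SER = list(list("OG",  c("N","CA","CB"),  1.417, 110.8, "chi1")),
  CYS = list(list("SG",  c("N","CA","CB"),  1.808, 114.4, "chi1")),
  THR = list(list("OG1", c("N","CA","CB"),  1.433, 109.6, "chi1"),
             list("CG2", c("N","CA","CB"),  1.521, 110.5, "chi1-120")),
  VAL = list(list("CG1", c("N","CA","CB"),  1.521, 110.5, "chi1"),
             list("CG2", c("N","CA","CB"),  1.521, 110.5, "chi1+122")),
  LEU = list(list("CG",  c("N","CA","CB"),  1.530, 116.3, "chi1"),
             list("CD1", c("CA","CB","CG"), 1.521, 110.7, "chi2"),
             list("CD2", c("CA","CB","CG"), 1.521, 110.7, "chi2+122")),
  ASP = list(list("CG",  c("N","CA","CB"),  1.516, 112.6, "chi1"),
             list("OD1", c("CA","CB","CG"), 1.249, 118.4, "chi2"),
             list("OD2", c("CA","CB","CG"), 1.249, 118.4, "chi2+180")),
  ASN = list(list("CG",  c("N","CA","CB"),  1.516, 112.6, "chi1"),
             list("OD1", c("CA","CB","CG"), 1.231, 120.8, "chi2"),
             list("ND2", c("CA","CB","CG"), 1.328, 116.4, "chi2+180")),
  GLU = list(list("CG",  c("N","CA","CB"),  1.520, 114.1, "chi1"),
             list("CD",  c("CA","CB","CG"), 1.516, 112.6, "chi2"),
             list("OE1", c("CB","CG","CD"), 1.249, 118.4, "chi3"),
             list("OE2", c("CB","CG","CD"), 1.249, 118.4, "chi3+180")),
  GLN = list(list("CG",  c("N","CA","CB"),  1.520, 114.1, "chi1"),
             list("CD",  c("CA","CB","CG"), 1.516, 112.6, "chi2"),
             list("OE1", c("CB","CG","CD"), 1.231, 120.8, "chi3"),
             list("NE2", c("CB","CG","CD"), 1.328, 116.4, "chi3+180")),
  LYS = list(list("CG",  c("N","CA","CB"),  1.520, 114.1, "chi1"),
             list("CD",  c("CA","CB","CG"), 1.520, 111.3, "chi2"),
             list("CE",  c("CB","CG","CD"), 1.520, 111.3, "chi3"),
             list("NZ",  c("CG","CD","CE"), 1.489, 111.9, "chi4")),
  HIS = list(list("CG",  c("N","CA","CB"),  1.497, 113.8, "chi1"),
             list("ND1", c("CA","CB","CG"), 1.378, 122.7, "chi2"),
             list("CD2", c("CA","CB","CG"), 1.354, 131.7, "chi2+180"),
             list("CE1", c("CB","CG","ND1"), 1.320, 107.1, "180"),
             list("NE2", c("CG","ND1","CE1"), 1.318, 111.2, "0"))
)

BUILDER_RESIDUES <- c("GLY", "ALA", names(SIDECHAIN_ZMAT))

# Common rotamer chi values (deg) per supported residue type; first entry is
# the default.  Minimal library, sufficient for fixture construction.
ROTAMERS <- list(
  SER = list(c(chi1 = -60), c(chi1 = 60), c(chi1 = 180)),
  CYS = list(c(chi1 = -60), c(chi1 = 180)),
  THR = list(c(chi1 = -60), c(chi1 = 60)),
  VAL = list(c(chi1 = 180), c(chi1 = -60)),
  LEU = list(c(chi1 = -60, chi2 = 180), c(chi1 = 180, chi2 = 60)),
  ASP = list(c(chi1 = -60, chi2 = -20), c(chi1 = 180, chi2 = 0)),
  ASN = list(c(chi1 = -60, chi2 = -30), c(chi1 = 180, chi2 = 30)),
  GLU = list(c(chi1 = -60, chi2 = 180, chi3 = -20),
             c(chi1 = 180, chi2 = 180, chi3 = 0)),
  GLN = list(c(chi1 = -60, chi2 = 180, chi3 = -30),
             c(chi1 = 180, chi2 = 180, chi3 = 30)),
  LYS = list(c(chi1 = -60, chi2 = 180, chi3 = 180, chi4 = 180),
             c(chi1 = 180, chi2 = 180, chi3 = 180, chi4 = 180)),
  HIS = list(c(chi1 = -60, chi2 = -75), c(chi1 = 180, chi2 = 60))
)

# van der Waals radii (A) by element.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20)

#' @keywords internal
element_of <- function(name) {
  # Strip digits/primes; first remaining letter is the element for standard
  # amino-acid atoms (C, N, O, S, H only).
  first <- sub("^[0-9']*", "", name)
  toupper(substr(first, 1, 1))
}

vdw_radius <- function(element) {
  r <- VDW_RADII[element]
  r[is.na(r)] <- 1.7
  unname(r)
}

# Characteristic side-chain atom per residue type for GDC-SC (GLY has none).
CHARACTERISTIC_ATOM <- c(
  ALA = "CB",  ARG = "NH1", ASN = "OD1", ASP = "OD1", CYS = "SG",
  GLN = "OE1", GLU = "OE1", HIS = "NE2", ILE = "CD1", LEU = "CD1",
  LYS = "NZ",  MET = "CE",  PHE = "CZ",  PRO = "CG",  SER = "OG",
  THR = "OG1", TRP = "CH2", TYR = "OH",  VAL = "CG1"
)

# ---- knowledge-based atom typing -------------------------------------------

#' PMF atom type of each heavy atom
#'
#' Coarse typing used by the pairwise potential of mean force: shared
#' backbone types (N, CA, C, O, CB) and residue-specific side-chain classes
#' by element (e.g. "SER:O" for the SER hydroxyl oxygen).
#' @param model an `atomic_model`.
#' @return character vector, one type per atom (`NA` for hydrogens).
#' @export
pmf_atom_types <- function(model) {
  at <- model$atoms
  type <- rep(NA_character_, nrow(at))
  heavy <- !at$is_h
  bb <- at$name %in% c("N", "CA", "C", "O", "OXT", "CB")
  type[heavy & bb] <- ifelse(at$name[heavy & bb] == "OXT", "O",
                             at$name[heavy & bb])
  sc <- heavy & !bb
  type[sc] <- paste0(at$resname[sc], ":", at$element[sc])
  type
}

# ---- hydrogen-bond chemistry ------------------------------------------------

# Heavy-atom acceptors: map residue -> atom names that accept H-bonds.
# Backbone O/OXT always accept.  HIS ring nitrogens accept only when not
# protonated (decided at run time from attached hydrogens).
SIDECHAIN_ACCEPTORS <- list(
  ASN = "OD1", GLN = "OE1",
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  SER = "OG", THR = "OG1", TYR = "OH",
  HIS = c("ND1", "NE2"), MET = "SD", CYS = "SG"
)

# Polar-hydrogen templates: for each residue type, hydrogens attached to
# side-chain donors.  Backbone amide H and terminal NH3+ are handled
# separately.  Entries: H name, parent heavy atom, refs (a, b) completing
# the internal-coordinate frame (a-b-parent-H), bond (A), angle (deg),
# dihedral spec ("rotor" = sampled grid position, number = fixed deg).
POLAR_H_TEMPLATES <- list(
  SER = list(list("HG",  "OG",  c("CA","CB"), 0.96, 108.5, "rotor")),
  THR = list(list("HG1", "OG1", c("CA","CB"), 0.96, 108.5, "rotor")),
  CYS = list(list("HG",  "SG",  c("CA","CB"), 1.34,  96.0, "rotor")),
  TYR = list(list("HH",  "OH",  c("CE1","CZ"), 0.96, 109.0, "rotor")),
  LYS = list(list("HZ1", "NZ",  c("CD","CE"), 1.01, 109.5, "rotor"),
             list("HZ2", "NZ",  c("CD","CE"), 1.01, 109.5, "rotor+120"),
             list("HZ3", "NZ",  c("CD","CE"), 1.01, 109.5, "rotor+240")),
  ASN = list(list("HD21", "ND2", c("OD1","CG"), 1.01, 120.0, "180"),
             list("HD22", "ND2", c("OD1","CG"), 1.01, 120.0, "0")),
  GLN = list(list("HE21", "NE2", c("OE1","CD"), 1.01, 120.0, "180"),
             list("HE22", "NE2", c("OE1","CD"), 1.01, 120.0, "0")),
  ARG = list(list("HE",   "NE",  c("CD","CZ"), 1.01, 118.0, "180"),
             list("HH11", "NH1", c("NE","CZ"), 1.01, 120.0, "0"),
             list("HH12", "NH1", c("NE","CZ"), 1.01, 120.0, "180"),
             list("HH21", "NH2", c("NE","CZ"), 1.01, 120.0, "0"),
             list("HH22", "NH2", c("NE","CZ"), 1.01, 120.0, "180")),
  TRP = list(list("HE1",  "NE1", c("CD1","CE2"), 1.01, 125.0, "180"))
)

# HIS tautomer hydrogens (exactly one present): HD1 on ND1 or HE2 on NE2.
HIS_TAUTOMER_H <- list(
  ND1 = list("HD1", "ND1", c("CB", "CG"), 1.01, 125.5, "180"),
  NE2 = list("HE2", "NE2", c("ND1", "CE1"), 1.01, 125.5, "180")
)
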