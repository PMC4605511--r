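# Residue-level lookup tables shared across the package.

#' @noRd
AA3 <- c("ALA","ARG","ASN","ASP","CYS","GLN","GLU","GLY","HIS","ILE",
         "LEU","LYS","MET","PHE","PRO","SER","THR","TRP","TYR","VAL")

#' @noRd
AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")
names(AA1) <- AA3

#' One-letter code for a three-letter residue name ('X' if nonstandard)
#' @param resname character vector of three-letter residue names
#' @return character vector of one-letter codes
#' @export
aa_three_to_one <- function(resname) {
  out <- AA1[toupper(resname)]
  out[is.na(out)] <- "X"
  unname(out)
}

# Expected heavy atoms per standard residue (chemical component definitions,
# terminal OXT not required). Used for the is_complete flag.
#' @noRd
EXPECTED_HEAVY <- list(
  ALA = c("N","CA","C","O","CB"),
  ARG = c("N","CA","C","O","CB","CG","CD","NE","CZ","NH1","NH2"),
  ASN = c("N","CA","C","O","CB","CG","OD1","ND2"),
  ASP = c("N","CA","C","O","CB","CG","OD1","OD2"),
  CYS = c("N","CA","C","O","CB","SG"),
  GLN = c("N","CA","C","O","CB","CG","CD","OE1","NE2"),
  GLU = c("N","CA","C","O","CB","CG","CD","OE1","OE2"),
  GLY = c("N","CA","C","O"),
  HIS = c("N","CA","C","O","CB","CG","ND1","CD2","CE1","NE2"),
  ILE = c("N","CA","C","O","CB","CG1","CG2","CD1"),
  LEU = c("N","CA","C","O","CB","CG","CD1","CD2"),
  LYS = c("N","CA","C","O","CB","CG","CD","CE","NZ"),
  MET = c("N","CA","C","O","CB","CG","SD","CE"),
  PHE = c("N","CA","C","O","CB","CG","CD1","CD2","CE1","CE2","CZ"),
  PRO = c("N","CA","C","O","CB","CG","CD"),
  SER = c("N","CA","C","O","CB","OG"),
  THR = c("N","CA","C","O","CB","OG1","CG2"),
  TRP = c("N","CA","C","O","CB","CG","CD1","CD2","NE1","CE2","CE3","CZ2","CZ3","CH2"),
  TYR = c("N","CA","C","O","CB","CG","CD1","CD2","CE1","CE2","CZ","OH"),
  VAL = c("N","CA","C","O","CB","CG1","CG2")
)

#' Kyte-Doolittle hydropathy scale
#'
#' The standard 20-value residue hydropathy scale (I = 4.5 ... R = -4.5).
#' A peptide's hydropathy is the unweighted mean over its residues.
#'
#' @return named numeric vector, one value per one-letter residue code
#' @export
kyte_doolittle <- function() {
  c(I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
    G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
    H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5)
}

# Van der Waals radii (Angstrom) for SASA; fallback used for rarer elements.
#' @noRd
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

# Elements treated as metals for het classification and interaction flags.
#' @noRd
METAL_ELEMENTS <- c("LI","NA","K","RB","CS","MG","CA","SR","BA","MN","FE",
                    "CO","NI","CU","ZN","CD","HG","MO","W","V","CR","AL",
                    "GA","PT","AU","AG","PB","SN","Y","LA","CE","GD","YB","U")

#' @noRd
WATER_NAMES <- c("HOH","WAT","DOD","H2O")

# Common modified polymer residues deposited as HETATM; kept in the chain
# (one-letter 'X') rather than treated as het groups.
#' @noRd
MODIFIED_RESIDUES <- c("MSE","SEP","TPO","PTR","CSO","CSD","CME","OCS",
                       "HYP","MLY","PCA","KCX","FME","LLP","M3L","SAC")
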