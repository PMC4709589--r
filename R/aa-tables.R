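# Shared amino-acid lookup tables used across the variant, conservation and
# structure layers. All residue identities are one-letter upper case; "X" is
# the stop symbol in variant notation.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

AA1TO3 <- stats::setNames(names(AA3TO1), AA3TO1)

# Formal side-chain charge at physiological pH; histidine counted positive so
# that D->H substitutions register as charge inversions (the D254H case).
AA_CHARGE <- c(D = -1L, E = -1L, K = 1L, R = 1L, H = 1L)

# Hydrophobic side chains (positive Kyte-Doolittle hydropathy).
AA_HYDROPHOBIC <- c("A", "V", "L", "I", "M", "F", "C")

# Theoretical Gly-X-Gly maximum accessible surface areas (A^2), used as the
# denominator of relative SASA (Tien et al. 2013, theoretical column).
AA_MAX_SASA <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0
)

# Van der Waals radii by element (A). Unlisted elements fall back to carbon.
ELEMENT_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
                   P = 1.80, FE = 1.47, ZN = 1.39, SE = 1.90)

# Side-chain atoms carrying formal charge, for ionic-edge detection.
CHARGED_SIDECHAIN_ATOMS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2")
)

vdw_radius <- function(element) {
  r <- ELEMENT_RADII[toupper(element)]
  r[is.na(r)] <- ELEMENT_RADII[["C"]]
  unname(r)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_stop_symbol <- function(x) identical(x, "X") || identical(x, "*")
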