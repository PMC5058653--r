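# Shared lookup tables: amino-acid codes, Bondi van der Waals radii,
# Kyte-Doolittle hydropathy.

# Bondi vdW radii (heavy atoms only; hydrogens are dropped at parse time).
.BONDI_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
.BONDI_DEFAULT <- 1.70

.BACKBONE_ATOMS <- c("N", "CA", "C", "O")

.AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
.AA_ONE_TO_THREE <- structure(names(.AA_THREE_TO_ONE),
                              names = unname(.AA_THREE_TO_ONE))

# Kyte & Doolittle hydropathy; negative = hydrophilic.
.KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# HIV-1 Tat 47-58 cell-penetrating sequence used upstream of cargo peptides.
.TAT_SEQUENCE <- "YGRKKRRQRRR"

#' Van der Waals radius by element
#'
#' Bondi radii for the heavy elements found in protein structures
#' (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 Angstrom). Unknown elements fall
#' back to the carbon radius with a warning.
#'
#' @param element character vector of element symbols.
#' @return numeric vector of radii in Angstrom.
#' @export
vdw_radius <- function(element) {
  element <- toupper(trimws(element))
  r <- .BONDI_RADII[element]
  unknown <- is.na(r)
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(element[unknown]), collapse = ", "),
            "; using default vdW radius ", .BONDI_DEFAULT, " A", call. = FALSE)
    r[unknown] <- .BONDI_DEFAULT
  }
  unname(r)
}

#' Kyte-Doolittle hydropathy of one-letter residue codes
#'
#' @param aa character vector of one-letter amino-acid codes.
#' @return numeric hydropathy values; hydrophilic residues are negative.
#' @export
hydropathy <- function(aa) {
  h <- .KYTE_DOOLITTLE[toupper(aa)]
  if (anyNA(h)) stop("unknown amino-acid code(s): ",
                     paste(unique(aa[is.na(h)]), collapse = ", "), call. = FALSE)
  unname(h)
}

.validate_peptide <- function(peptide, what = "peptide") {
  if (!is.character(peptide) || length(peptide) != 1L || nchar(peptide) < 1L)
    stop(what, " must be a non-empty string", call. = FALSE)
  aa <- strsplit(peptide, "")[[1]]
  bad <- !(aa %in% names(.KYTE_DOOLITTLE))
  if (any(bad))
    stop(what, " contains invalid residue code(s): ",
         paste(unique(aa[bad]), collapse = ", "), call. = FALSE)
  invisible(aa)
}
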