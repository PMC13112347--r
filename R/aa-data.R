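# Amino-acid reference data: 1<->3 letter codes, side-chain heavy-atom
# templates with bond parents (used by the naive side-chain placer), formal
# charges, and loaders for the shipped parameter / hydropathy tables.

#' @keywords internal
.aa_three <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
               Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
               L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
               S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

#' @keywords internal
.aa_one <- stats::setNames(names(.aa_three), .aa_three)

# Formal (integer) side-chain charges at neutral pH.
.aa_formal_charge <- c(ALA = 0, ARG = 1, ASN = 0, ASP = -1, CYS = 0,
                       GLN = 0, GLU = -1, GLY = 0, HIS = 0, ILE = 0,
                       LEU = 0, LYS = 1, MET = 0, PHE = 0, PRO = 0,
                       SER = 0, THR = 0, TRP = 0, TYR = 0, VAL = 0)

# Backbone atom names (heavy + the two backbone hydrogens kept when inputs
# carry them); everything else belongs to the side chain.
.backbone_atoms <- c("N", "CA", "C", "O", "OXT", "H", "HA", "HN",
                     "HA1", "HA2", "H1", "H2", "H3")

# Side-chain heavy-atom templates: each atom with its bonded parent.
# Parent "CA" roots the tree at the backbone.  Order is a valid build order.
.sidechain_tree <- list(
  ALA = rbind(c("CB", "CA")),
  ARG = rbind(c("CB", "CA"), c("CG", "CB"), c("CD", "CG"), c("NE", "CD"),
              c("CZ", "NE"), c("NH1", "CZ"), c("NH2", "CZ")),
  ASN = rbind(c("CB", "CA"), c("CG", "CB"), c("OD1", "CG"), c("ND2", "CG")),
  ASP = rbind(c("CB", "CA"), c("CG", "CB"), c("OD1", "CG"), c("OD2", "CG")),
  CYS = rbind(c("CB", "CA"), c("SG", "CB")),
  GLN = rbind(c("CB", "CA"), c("CG", "CB"), c("CD", "CG"), c("OE1", "CD"),
              c("NE2", "CD")),
  GLU = rbind(c("CB", "CA"), c("CG", "CB"), c("CD", "CG"), c("OE1", "CD"),
              c("OE2", "CD")),
  GLY = NULL,
  HIS = rbind(c("CB", "CA"), c("CG", "CB"), c("ND1", "CG"), c("CD2", "CG"),
              c("CE1", "ND1"), c("NE2", "CD2")),
  ILE = rbind(c("CB", "CA"), c("CG1", "CB"), c("CG2", "CB"), c("CD1", "CG1")),
  LEU = rbind(c("CB", "CA"), c("CG", "CB"), c("CD1", "CG"), c("CD2", "CG")),
  LYS = rbind(c("CB", "CA"), c("CG", "CB"), c("CD", "CG"), c("CE", "CD"),
              c("NZ", "CE")),
  MET = rbind(c("CB", "CA"), c("CG", "CB"), c("SD", "CG"), c("CE", "SD")),
  PHE = rbind(c("CB", "CA"), c("CG", "CB"), c("CD1", "CG"), c("CD2", "CG"),
              c("CE1", "CD1"), c("CE2", "CD2"), c("CZ", "CE1")),
  PRO = rbind(c("CB", "CA"), c("CG", "CB"), c("CD", "CG")),
  SER = rbind(c("CB", "CA"), c("OG", "CB")),
  THR = rbind(c("CB", "CA"), c("OG1", "CB"), c("CG2", "CB")),
  TRP = rbind(c("CB", "CA"), c("CG", "CB"), c("CD1", "CG"), c("CD2", "CG"),
              c("NE1", "CD1"), c("CE2", "CD2"), c("CE3", "CD2"),
              c("CZ2", "CE2"), c("CZ3", "CE3"), c("CH2", "CZ2")),
  TYR = rbind(c("CB", "CA"), c("CG", "CB"), c("CD1", "CG"), c("CD2", "CG"),
              c("CE1", "CD1"), c("CE2", "CD2"), c("CZ", "CE1"), c("OH", "CZ")),
  VAL = rbind(c("CB", "CA"), c("CG1", "CB"), c("CG2", "CB"))
)

#' Element symbol guessed from a PDB atom name
#' @keywords internal
.atom_element <- function(elety) {
  nm <- sub("^[0-9]+", "", toupper(trimws(elety)))
  el <- substr(nm, 1, 1)
  el[substr(nm, 1, 2) %in% c("CL", "BR", "FE", "ZN", "MG")] <-
    substr(nm, 1, 2)[substr(nm, 1, 2) %in% c("CL", "BR", "FE", "ZN", "MG")]
  el
}

#' @keywords internal
.is_hydrogen <- function(elety) .atom_element(elety) == "H"

# Default van der Waals radii by element, used when no per-atom Rmin/2 is
# assigned (Bondi-style values, Angstrom).
.element_vdw <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.10, P = 1.80)

#' Path to a file shipped in inst/extdata
#' @keywords internal
.extdata <- function(file) {
  p <- system.file("extdata", file, package = "pepmc")
  if (!nzchar(p)) stop("shipped data file not found: ", file)
  p
}

#' Load a per-atom force-field-style parameter table
#'
#' The table is keyed by `(residue, atom)` and carries the Lennard-Jones well
#' depth `epsilon` (kcal/mol), the per-atom `rmin_half` (Rmin/2, Angstrom)
#' and the partial `charge` (e).  The shipped default
#' (`atom_params_synthetic.tsv`) is a deliberately simplified, synthetic
#' CHARMM-style heavy-atom set: element-class LJ parameters and partial
#' charges constructed so that every residue sums exactly to its formal
#' charge.  Substitute a real force-field export via `path` for production
#' work.
#'
#' @param path Path to a tab-separated table with columns
#'   `residue`, `atom`, `epsilon`, `rmin_half`, `charge`.  Default: the
#'   shipped synthetic table.
#' @return A `data.frame` with those five columns.
#' @export
load_parameter_table <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("atom_params_synthetic.tsv")
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("residue", "atom", "epsilon", "rmin_half", "charge")
  if (!all(need %in% names(tab)))
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  tab
}

#' Load a hydropathy scale
#'
#' Two-column plain-text table mapping 3-letter residue codes to a
#' dimensionless hydropathy index.  The shipped default is the
#' Kyte-Doolittle scale; any other published or custom scale (for example a
#' surface-composition-derived scale) can be supplied via `path`.
#'
#' @param path Path to a tab-separated table with columns `residue`, `index`.
#' @return Named numeric vector over the 20 standard residues.
#' @export
load_hydropathy_scale <- function(path = NULL) {
  if (is.null(path)) path <- .extdata("hydropathy_kd.tsv")
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("residue", "index") %in% names(tab)))
    stop("hydropathy scale must have columns: residue, index")
  sc <- stats::setNames(tab$index, toupper(tab$residue))
  missing <- setdiff(unname(.aa_three), names(sc))
  if (length(missing))
    stop("hydropathy scale missing residues: ", paste(missing, collapse = ", "))
  sc
}

#' Convert between 1- and 3-letter amino-acid codes
#' @param x Character vector of codes (either convention).
#' @return Character vector in the other convention.
#' @export
aa_three_letter <- function(x) {
  x <- toupper(x)
  out <- ifelse(nchar(x) == 1, unname(.aa_three[x]), x)
  if (anyNA(out)) stop("unknown amino-acid code: ",
                       paste(x[is.na(out)], collapse = ", "))
  out
}

#' @rdname aa_three_letter
#' @export
aa_one_letter <- function(x) {
  x <- toupper(x)
  out <- ifelse(nchar(x) == 3, unname(.aa_one[x]), x)
  if (anyNA(out)) stop("unknown amino-acid code: ",
                       paste(x[is.na(out)], collapse = ", "))
  out
}
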