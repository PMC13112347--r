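# Structure / trajectory data model and standard-format I/O.
#
# A `chain_structure` wraps a per-atom data.frame (one row per atom, in file
# order) in the bio3d column idiom: eleno, elety, resid, chain, resno,
# insert, x, y, z, plus parameter columns charge, epsilon, rmin_half filled
# by assign_parameters().  PDB reading and writing go through bio3d.

#' @keywords internal
new_chain_structure <- function(atom, model_id = 1L) {
  need <- c("eleno", "elety", "resid", "chain", "resno", "insert",
            "x", "y", "z")
  stopifnot(all(need %in% names(atom)))
  if (!all(is.finite(atom$x) & is.finite(atom$y) & is.finite(atom$z)))
    stop("non-finite atom coordinates")
  for (col in c("charge", "epsilon", "rmin_half"))
    if (is.null(atom[[col]])) atom[[col]] <- NA_real_
  atom$elety <- trimws(atom$elety)
  atom$resid <- trimws(atom$resid)
  atom$insert <- ifelse(is.na(atom$insert) | atom$insert == "", "",
                        trimws(atom$insert))
  rownames(atom) <- NULL
  structure(list(atom = atom, model_id = as.integer(model_id)),
            class = "chain_structure")
}

#' @export
print.chain_structure <- function(x, ...) {
  at <- x$atom
  cat("<chain_structure> model", x$model_id, "-", nrow(at), "atoms,",
      length(unique(residue_keys(x))), "residues, chains:",
      paste(unique(at$chain), collapse = " "), "\n")
  invisible(x)
}

#' Per-atom residue keys ("chain|resno|insert")
#' @keywords internal
residue_keys <- function(structure) {
  at <- structure$atom
  paste(at$chain, at$resno, at$insert, sep = "|")
}

#' Atom coordinate matrix (n x 3)
#' @keywords internal
coords <- function(structure) {
  as.matrix(structure$atom[, c("x", "y", "z")])
}

#' @keywords internal
set_coords <- function(structure, xyz) {
  structure$atom$x <- xyz[, 1]
  structure$atom$y <- xyz[, 2]
  structure$atom$z <- xyz[, 3]
  structure
}

#' Residue summary table of a structure
#'
#' One row per residue in file order: chain, resno, insert, resid, and the
#' row indices of its atoms in `structure$atom` (as a list column).
#'
#' @param structure A `chain_structure`.
#' @return A `data.frame` with list column `atom_rows`.
#' @export
residue_table <- function(structure) {
  at <- structure$atom
  key <- residue_keys(structure)
  first <- !duplicated(key)
  idx <- split(seq_len(nrow(at)), factor(key, levels = unique(key)))
  data.frame(chain = at$chain[first], resno = at$resno[first],
             insert = at$insert[first], resid = at$resid[first],
             atom_rows = I(unname(idx)), stringsAsFactors = FALSE)
}

#' @keywords internal
.validate_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  atom_lines <- which(trimws(rec) %in% c("ATOM", "HETATM"))
  for (i in atom_lines) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed ATOM record at line ", i, ": too short")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz))
      stop("malformed ATOM record at line ", i, ": bad coordinates")
  }
  atom_lines
}

#' @keywords internal
.as_pdb_file <- function(pdb) {
  if (length(pdb) == 1 && !grepl("\n", pdb) && file.exists(pdb)) return(pdb)
  txt <- if (length(pdb) == 1) strsplit(pdb, "\n", fixed = TRUE)[[1]] else pdb
  tmp <- tempfile(fileext = ".pdb")
  writeLines(txt, tmp)
  tmp
}

#' Read a single-model protein structure from PDB
#'
#' Parses ATOM records (HETATM records such as waters and ligands are
#' dropped), preserving coordinates, atom and residue names, chain ids,
#' author residue numbering and insertion codes.  Parsing is delegated to
#' bio3d after a light per-line validation that reports malformed ATOM
#' records by line number.
#'
#' @param pdb Path to a PDB file, or PDB content as a single string /
#'   character vector of lines.
#' @return A `chain_structure`.
#' @export
read_structure <- function(pdb) {
  path <- .as_pdb_file(pdb)
  lines <- readLines(path, warn = FALSE)
  .validate_pdb_lines(lines)
  if (!any(substr(lines, 1, 6) == "ATOM  " | substr(lines, 1, 5) == "ATOM "))
    stop("empty input: no ATOM records found")
  p <- bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE, verbose = FALSE)
  at <- p$atom[p$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("empty input: no ATOM records found")
  at$chain[is.na(at$chain)] <- " "
  new_chain_structure(at[, c("eleno", "elety", "resid", "chain", "resno",
                             "insert", "x", "y", "z")])
}

#' Read a multi-model PDB as a trajectory
#'
#' MODEL/ENDMDL blocks become ordered frames.  All models must share an
#' identical topology (same atoms in the same order); a mismatch raises a
#' topology error before any frame is built.
#'
#' @param pdb Path / text as in [read_structure()].
#' @param frame_spacing Time between frames in ns (metadata only).
#' @return A `trajectory`: list of `chain_structure` frames.
#' @export
read_trajectory <- function(pdb, frame_spacing = 1) {
  path <- .as_pdb_file(pdb)
  lines <- readLines(path, warn = FALSE)
  .validate_pdb_lines(lines)
  rec <- trimws(substr(lines, 1, 6))
  model_starts <- which(rec == "MODEL")
  if (length(model_starts) == 0) {
    return(new_trajectory(list(read_structure(path)), frame_spacing))
  }
  model_ends <- which(rec == "ENDMDL")
  if (length(model_ends) != length(model_starts))
    stop("topology error: unbalanced MODEL/ENDMDL records")
  frames <- vector("list", length(model_starts))
  sig0 <- NULL
  for (k in seq_along(model_starts)) {
    block <- lines[(model_starts[k] + 1):(model_ends[k] - 1)]
    fr <- read_structure(block)
    fr$model_id <- k
    sig <- paste(fr$atom$elety, fr$atom$chain, fr$atom$resno, fr$atom$resid)
    if (is.null(sig0)) sig0 <- sig
    else if (length(sig) != length(sig0) || !all(sig == sig0))
      stop("topology error: model ", k,
           " does not match model 1 (atom count or identity differs)")
    frames[[k]] <- fr
  }
  new_trajectory(frames, frame_spacing)
}

#' @keywords internal
new_trajectory <- function(frames, frame_spacing = 1) {
  structure(list(frames = frames, frame_spacing = frame_spacing),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", length(x$frames), "frames, spacing",
      x$frame_spacing, "ns\n")
  invisible(x)
}

#' @export
length.trajectory <- function(x) length(x$frames)

#' Write a structure (or trajectory) as PDB
#'
#' Single structures are written through bio3d with standard 8.3 coordinate
#' fields; trajectories are written as MODEL/ENDMDL blocks.
#'
#' @param x A `chain_structure` or `trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  if (inherits(x, "trajectory")) {
    blocks <- vapply(seq_along(x$frames), function(k) {
      tmp <- tempfile(fileext = ".pdb")
      write_structure(x$frames[[k]], tmp)
      body <- readLines(tmp, warn = FALSE)
      body <- body[!grepl("^END", body)]
      paste(c(sprintf("MODEL     %4d", k), body, "ENDMDL"), collapse = "\n")
    }, character(1))
    writeLines(c(blocks, "END"), path)
    return(invisible(path))
  }
  stopifnot(inherits(x, "chain_structure"))
  at <- x$atom
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(coords(x))),
                   type = rep("ATOM", nrow(at)),
                   eleno = at$eleno, elety = at$elety, resid = at$resid,
                   chain = ifelse(at$chain == " ", "", at$chain),
                   resno = at$resno, insert = at$insert,
                   o = rep(1, nrow(at)), b = rep(0, nrow(at)))
  invisible(path)
}

#' Read per-atom charges and radii from a PQR file
#'
#' Whitespace-delimited ATOM records; the charge and radius are taken from
#' the 9th and 10th fields when a chain id is present (10 fields total), or
#' the two trailing fields otherwise.
#'
#' @param path PQR file path or text.
#' @return data.frame with elety, resid, chain, resno, charge, radius.
#' @export
read_pqr <- function(path) {
  pth <- .as_pdb_file(path)
  lines <- readLines(pth, warn = FALSE)
  lines <- lines[grepl("^ATOM|^HETATM", lines)]
  if (!length(lines)) stop("empty input: no ATOM records in PQR")
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 9)
      stop("malformed PQR ATOM record at line ", i)
    has_chain <- length(f) >= 10 && is.na(suppressWarnings(as.numeric(f[5])))
    chain <- if (has_chain) f[5] else " "
    resno <- as.integer(f[if (has_chain) 6 else 5])
    charge <- as.numeric(f[length(f) - 1])
    radius <- as.numeric(f[length(f)])
    data.frame(elety = f[3], resid = f[4], chain = chain, resno = resno,
               charge = charge, radius = radius, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assign force-field-style parameters to every atom
#'
#' Looks up Lennard-Jones well depth, Rmin/2 and partial charge by
#' `(residue type, atom name)` in a parameter table.  When a PQR record set
#' is supplied its charges take precedence over the table (matched by chain,
#' residue number and atom name).
#'
#' @param structure A `chain_structure`.
#' @param table Parameter table as from [load_parameter_table()].
#' @param pqr Optional data.frame from [read_pqr()] whose charges override
#'   the table.
#' @return The structure with `charge`, `epsilon`, `rmin_half` filled.
#' @export
assign_parameters <- function(structure, table = load_parameter_table(),
                              pqr = NULL) {
  at <- structure$atom
  key <- paste(at$resid, at$elety)
  tkey <- paste(table$residue, table$atom)
  idx <- match(key, tkey)
  if (anyNA(idx)) {
    bad <- unique(key[is.na(idx)])
    stop("no parameter entry for atom(s): ", paste(bad, collapse = ", "))
  }
  at$epsilon <- table$epsilon[idx]
  at$rmin_half <- table$rmin_half[idx]
  at$charge <- table$charge[idx]
  if (!is.null(pqr)) {
    pk <- paste(pqr$chain, pqr$resno, pqr$elety)
    ak <- paste(at$chain, at$resno, at$elety)
    hit <- match(ak, pk)
    at$charge[!is.na(hit)] <- pqr$charge[hit[!is.na(hit)]]
  }
  structure$atom <- at
  structure
}

#' Subset a structure to one or more chains
#' @param structure A `chain_structure`.
#' @param chains Character vector of chain ids.
#' @return A `chain_structure` containing only those chains.
#' @export
subset_chains <- function(structure, chains) {
  keep <- structure$atom$chain %in% chains
  if (!any(keep)) stop("chain id(s) not present: ",
                       paste(chains, collapse = ", "))
  new_chain_structure(structure$atom[keep, , drop = FALSE],
                      structure$model_id)
}
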