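# Two-bead-per-residue coarse graining for the electrostatic term.
#
# Each residue is reduced to a backbone bead and (except glycine) a
# side-chain bead; bead positions are unweighted means of the constituent
# atom positions and bead charges are the sums of their partial charges, so
# total charge is conserved exactly.

#' Two-bead coarse-grained model of a structure
#'
#' Every residue contributes a backbone bead at the mean position of its
#' backbone atoms (N, CA, C, O and variants) and, when side-chain atoms are
#' present, a side-chain bead at their mean position.  Glycine yields the
#' backbone bead only, which then carries the whole residue charge.  Bead
#' charges are sums of the constituent partial charges, so the total bead
#' charge equals the total atomic charge.
#'
#' @param structure A parameterized `chain_structure` (see
#'   [assign_parameters()]); every atom must carry a finite partial charge.
#' @return A `cg_model`: data.frame with columns chain, resno, insert,
#'   resid, role ("backbone"/"sidechain"), x, y, z, charge.
#' @export
coarse_grain <- function(structure) {
  at <- structure$atom
  if (anyNA(at$charge))
    stop("structure not parameterized: run assign_parameters() first")
  res <- residue_table(structure)
  rows <- vector("list", nrow(res))
  for (i in seq_len(nrow(res))) {
    rw <- res$atom_rows[[i]]
    bb <- rw[at$elety[rw] %in% .backbone_atoms]
    sc <- setdiff(rw, bb)
    if (!length(bb))
      stop("malformed residue ", res$chain[i], " ", res$resno[i],
           ": no backbone atoms")
    mk <- function(rws, role) data.frame(
      chain = res$chain[i], resno = res$resno[i], insert = res$insert[i],
      resid = res$resid[i], role = role,
      x = mean(at$x[rws]), y = mean(at$y[rws]), z = mean(at$z[rws]),
      charge = sum(at$charge[rws]), stringsAsFactors = FALSE)
    out <- mk(bb, "backbone")
    if (length(sc)) out <- rbind(out, mk(sc, "sidechain"))
    rows[[i]] <- out
  }
  beads <- do.call(rbind, rows)
  rownames(beads) <- NULL
  structure(list(beads = beads), class = "cg_model")
}

#' @export
print.cg_model <- function(x, ...) {
  cat("<cg_model>", nrow(x$beads), "beads, total charge",
      format(sum(x$beads$charge), digits = 6), "e\n")
  invisible(x)
}
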