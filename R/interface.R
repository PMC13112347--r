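# Trajectory-level interface statistics, peptide-template selection, RMSD,
# extension intervals, and MSA position frequencies.

#' CA coordinates and residue ids of one chain
#' @keywords internal
.chain_ca <- function(frame, chain) {
  at <- frame$atom
  sel <- at$chain == chain & at$elety == "CA"
  if (!any(at$chain == chain)) stop("chain id not present: ", chain)
  res <- residue_table(subset_chains(frame, chain))
  if (sum(sel) != nrow(res))
    stop("malformed residue: chain ", chain, " has residues without a CA atom")
  list(xyz = as.matrix(at[sel, c("x", "y", "z")]),
       resno = at$resno[sel])
}

#' Interface residues of two chains in one frame
#'
#' A residue of chain A is at the interface iff some residue of chain B has
#' its CA strictly within `cutoff` Angstrom of its CA (and symmetrically
#' for B).
#'
#' @param frame A `chain_structure`.
#' @param chain_a,chain_b Chain ids.
#' @param cutoff CA-CA distance cutoff in Angstrom (default 8, strict `<`).
#' @return List with integer vectors `a` and `b` of interface residue
#'   numbers.
#' @export
interface_residues <- function(frame, chain_a, chain_b, cutoff = 8) {
  ca <- .chain_ca(frame, chain_a)
  cb <- .chain_ca(frame, chain_b)
  d2 <- outer(rowSums(ca$xyz^2), rowSums(cb$xyz^2), "+") -
    2 * ca$xyz %*% t(cb$xyz)
  hit <- d2 < cutoff^2 - 1e-12
  list(a = ca$resno[rowSums(hit) > 0], b = cb$resno[colSums(hit) > 0])
}

#' Per-residue contact occurrence along a trajectory
#'
#' occurrence(res) = fraction of frames in which the residue is an interface
#' residue under the CA-CA cutoff rule.
#'
#' @param traj A `trajectory`.
#' @param chain_a Chain whose residues are profiled.
#' @param chain_b Partner chain.
#' @param cutoff CA-CA cutoff, Angstrom.
#' @return A `contact_profile`: data.frame with `resno` and `occurrence`,
#'   plus attribute `n_frames`.
#' @export
contact_occurrence <- function(traj, chain_a, chain_b, cutoff = 8) {
  stopifnot(inherits(traj, "trajectory"))
  if (!length(traj$frames)) stop("empty input: trajectory has no frames")
  resno <- .chain_ca(traj$frames[[1]], chain_a)$resno
  counts <- stats::setNames(numeric(length(resno)), resno)
  for (fr in traj$frames) {
    ir <- interface_residues(fr, chain_a, chain_b, cutoff)
    counts[as.character(ir$a)] <- counts[as.character(ir$a)] + 1
  }
  out <- data.frame(resno = resno,
                    occurrence = unname(counts) / length(traj$frames))
  attr(out, "n_frames") <- length(traj$frames)
  class(out) <- c("contact_profile", "data.frame")
  out
}

#' Select the peptide-template segment from a contact profile
#'
#' Among maximal contiguous runs of residues whose occurrence exceeds
#' `threshold` (strict), returns the longest; ties are broken by higher mean
#' occurrence, then by smaller start residue number.  An optional gap
#' tolerance `max_gap` allows up to that many consecutive below-threshold
#' residues inside a run (default 0: strict rule).
#'
#' @param profile A `contact_profile` (or data.frame with `resno`,
#'   `occurrence`).
#' @param threshold Occurrence threshold (default 0.25).
#' @param max_gap Allowed below-threshold gap length inside a run.
#' @return A `segment_selection`: list with `start`, `end`, `length`,
#'   `resno`, `occurrences`, `mean_occurrence`.
#' @export
select_peptide_segment <- function(profile, threshold = 0.25, max_gap = 0) {
  stopifnot(nrow(profile) > 0)
  above <- profile$occurrence > threshold
  if (!any(above)) stop("no-segment error: no residue above threshold ",
                        threshold)
  # runs of above-threshold residues, merging across gaps <= max_gap
  r <- rle(above)
  if (max_gap > 0) {
    ends <- cumsum(r$lengths)
    for (k in seq_along(r$values)) {
      if (!r$values[k] && r$lengths[k] <= max_gap &&
          k > 1 && k < length(r$values))
        above[(ends[k] - r$lengths[k] + 1):ends[k]] <- TRUE
    }
    r <- rle(above)
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  best <- NULL
  for (k in runs) {
    idx <- starts[k]:ends[k]
    cand <- list(start = profile$resno[starts[k]],
                 end = profile$resno[ends[k]],
                 length = length(idx),
                 resno = profile$resno[idx],
                 occurrences = profile$occurrence[idx],
                 mean_occurrence = mean(profile$occurrence[idx]))
    if (is.null(best) ||
        cand$length > best$length ||
        (cand$length == best$length &&
         cand$mean_occurrence > best$mean_occurrence + 1e-12) ||
        (cand$length == best$length &&
         abs(cand$mean_occurrence - best$mean_occurrence) <= 1e-12 &&
         cand$start < best$start))
      best <- cand
  }
  class(best) <- "segment_selection"
  best
}

#' @export
print.segment_selection <- function(x, ...) {
  cat("<segment_selection> residues", x$start, "-", x$end, "(length",
      x$length, "), mean occurrence",
      format(x$mean_occurrence, digits = 3), "\n")
  invisible(x)
}

#' Fraction of interface vdW energy carried by a segment
#'
#' Ratio of the summed energy-matrix entries in the segment's rows to the
#' summed entries of the whole matrix (signed sums).
#'
#' @param matrix An `energy_matrix` (rows indexed "chain:resno").
#' @param segment A `segment_selection`, or an integer vector of residue
#'   numbers.
#' @return Fraction (can exceed `[0, 1]` when signs mix).
#' @export
segment_vdw_fraction <- function(matrix, segment) {
  resno <- if (inherits(segment, "segment_selection")) segment$resno
  else segment
  rows <- attr(matrix, "rows")
  sel <- rows$resno %in% resno
  if (!any(sel)) stop("segment residues not present in matrix rows")
  total <- sum(matrix)
  if (abs(total) < 1e-12) stop("undefined fraction: zero total energy")
  sum(matrix[sel, , drop = FALSE]) / total
}

#' Per-residue share of the interface vdW energy
#'
#' Row sum of one residue divided by the total (signed sums); shares over
#' all rows partition to 1.
#'
#' @param matrix An `energy_matrix`.
#' @param resno Residue number (row side).
#' @return Fraction.
#' @export
per_residue_vdw_share <- function(matrix, resno) {
  rows <- attr(matrix, "rows")
  sel <- rows$resno == resno
  if (!any(sel)) stop("residue ", resno, " not present in matrix rows")
  total <- sum(matrix)
  if (abs(total) < 1e-12) stop("undefined fraction: zero total energy")
  sum(matrix[sel, , drop = FALSE]) / total
}

#' @keywords internal
.match_atoms <- function(frame, reference, selection) {
  key <- function(s) paste(s$atom$chain, s$atom$resno, s$atom$insert,
                           s$atom$elety)
  kf <- key(frame); kr <- key(reference)
  sel_mask <- function(s) switch(selection,
    all = rep(TRUE, nrow(s$atom)),
    ca = s$atom$elety == "CA",
    backbone = s$atom$elety %in% c("N", "CA", "C", "O"),
    heavy = !.is_hydrogen(s$atom$elety),
    stop("unknown selection: ", selection))
  kf <- kf[sel_mask(frame)]; kr <- kr[sel_mask(reference)]
  if (length(kf) != length(kr) || !all(kf == kr))
    stop("correspondence error: selected atoms do not match between ",
         "frame and reference")
  list(f = which(sel_mask(frame)), r = which(sel_mask(reference)))
}

#' Root-mean-square deviation between two structures
#'
#' RMSD = sqrt(1/N sum_i |r_i - r_i0|^2) over the selected atoms, matched by
#' atom identity (chain, residue, name).  With `superpose = TRUE` a
#' least-squares rigid fit (Kabsch) is applied first; the default is the
#' literal, unfitted deviation.
#'
#' @param frame,reference `chain_structure`s with identical selected atoms.
#' @param selection "all", "ca", "backbone" or "heavy".
#' @param superpose Apply an optimal rigid-body fit before measuring.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(frame, reference, selection = "all", superpose = FALSE) {
  m <- .match_atoms(frame, reference, selection)
  X <- coords(frame)[m$f, , drop = FALSE]
  Y <- coords(reference)[m$r, , drop = FALSE]
  if (superpose) {
    xc <- colMeans(X); yc <- colMeans(Y)
    X0 <- sweep(X, 2, xc); Y0 <- sweep(Y, 2, yc)
    s <- svd(crossprod(Y0, X0))
    d <- sign(det(s$u %*% t(s$v)))
    R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
    X <- sweep(X0 %*% t(R), 2, yc, "+")
    Y <- sweep(Y0, 2, yc, "+")
  }
  sqrt(mean(rowSums((X - Y)^2)))
}

#' Edge-to-edge extension of a segment
#'
#' Euclidean CA-CA distance between the first and last residues of the
#' segment in the given frame.
#'
#' @param frame A `chain_structure`.
#' @param segment A `segment_selection` or integer vector of residue numbers.
#' @param chain Chain id holding the segment.
#' @return Distance in Angstrom.
#' @export
edge_to_edge <- function(frame, segment, chain) {
  resno <- if (inherits(segment, "segment_selection")) segment$resno
  else segment
  ca <- .chain_ca(frame, chain)
  i <- match(min(resno), ca$resno)
  j <- match(max(resno), ca$resno)
  if (is.na(i) || is.na(j))
    stop("malformed residue: terminal segment residue has no CA")
  sqrt(sum((ca$xyz[i, ] - ca$xyz[j, ])^2))
}

#' Mean +/- k sigma interval of a per-frame distance series
#'
#' Computes the interval mean +/- `k_sigma` * population standard deviation
#' and the fraction of frames falling inside it; optionally also the
#' occupancy of an externally supplied interval (for cross-trajectory
#' comparisons).
#'
#' @param distances Numeric per-frame series (length >= 2).
#' @param k_sigma Interval half-width in standard deviations (default 2).
#' @param interval Optional numeric `c(low, high)` whose occupancy in this
#'   series is also reported.
#' @return An `extension_interval`: list with `mean`, `sd`, `low`, `high`,
#'   `occupancy`, and `external_occupancy` when `interval` is given.
#' @export
extension_interval <- function(distances, k_sigma = 2, interval = NULL) {
  stopifnot(length(distances) >= 2)
  mu <- mean(distances)
  sdev <- sqrt(mean((distances - mu)^2))
  if (sdev == 0) warning("constant series: degenerate interval (sd = 0)")
  lo <- mu - k_sigma * sdev
  hi <- mu + k_sigma * sdev
  out <- list(mean = mu, sd = sdev, low = lo, high = hi,
              occupancy = mean(distances >= lo & distances <= hi))
  if (!is.null(interval)) {
    stopifnot(length(interval) == 2, interval[1] <= interval[2])
    out$external_occupancy <- mean(distances >= interval[1] &
                                     distances <= interval[2])
  }
  class(out) <- "extension_interval"
  out
}

#' @export
print.extension_interval <- function(x, ...) {
  cat("<extension_interval>", format(x$low, digits = 4), "-",
      format(x$high, digits = 4), "A (mean", format(x$mean, digits = 4),
      ", sd", format(x$sd, digits = 4), "), occupancy",
      format(x$occupancy, digits = 4), "\n")
  invisible(x)
}

#' Residue frequencies at reference positions of an MSA
#'
#' Maps positions of the (ungapped) reference sequence to alignment columns
#' and tabulates, per column, the frequency of each residue among non-gap
#' symbols.
#'
#' @param alignment Path to an aligned FASTA file, or a named character
#'   vector of aligned sequences.
#' @param positions Integer positions in the ungapped reference sequence.
#' @param reference_id Name of the reference sequence in the alignment.
#' @return Named list (one element per position) of frequency tables; each
#'   sums to 1 over the residues observed in that column.
#' @export
msa_position_frequencies <- function(alignment, positions, reference_id) {
  if (is.character(alignment) && length(alignment) == 1 &&
      file.exists(alignment)) {
    ss <- Biostrings::readAAStringSet(alignment)
    seqs <- stats::setNames(as.character(ss), names(ss))
  } else {
    seqs <- alignment
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (!reference_id %in% names(seqs))
    stop("reference sequence not found: ", reference_id)
  if (length(unique(nchar(seqs))) != 1)
    stop("sequences are not aligned (unequal lengths)")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  ref <- mat[which(names(seqs) == reference_id)[1], ]
  ungapped <- cumsum(ref != "-")
  out <- lapply(positions, function(p) {
    col <- match(p, ungapped)
    if (is.na(col) || p < 1)
      stop("index error: position ", p, " outside the ungapped reference")
    column <- mat[, col]
    column <- column[column != "-"]
    tab <- table(column)
    as.numeric(tab) / sum(tab) -> fr
    stats::setNames(fr, names(tab))
  })
  stats::setNames(out, positions)
}

#' Write a contact profile as TSV
#' @param profile A `contact_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
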