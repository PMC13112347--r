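# Deterministic synthetic fixtures: toy two-chain complexes, trajectories
# with prescribed contact occupancy, analytic disk images, and single-atom
# structures.  These are geometric test inputs, not biological models.

#' @keywords internal
.backbone_offsets <- list(N = c(-1.20, 0.60, 0.00),
                          C = c(1.20, 0.60, 0.00),
                          O = c(1.45, 1.80, 0.00),
                          CB = c(0.00, -0.95, 1.20))

#' @keywords internal
.build_polyala_chain <- function(n_res, chain_id, origin, residue = "ALA",
                                 geometry = "extended") {
  rows <- vector("list", n_res)
  eleno <- 0L
  for (i in seq_len(n_res)) {
    if (geometry == "extended") {
      ca <- origin + c(3.8 * (i - 1), 0.4 * ((i %% 2) * 2 - 1), 0)
    } else { # helical: ~100 deg turn, 1.5 A rise per residue
      ang <- (i - 1) * 100 * pi / 180
      ca <- origin + c(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * (i - 1))
    }
    atoms <- c("N", "CA", "C", "O", if (residue != "GLY") "CB")
    xyz <- t(vapply(atoms, function(a)
      if (a == "CA") ca else ca + .backbone_offsets[[a]], numeric(3)))
    rows[[i]] <- data.frame(
      eleno = eleno + seq_along(atoms), elety = atoms, resid = residue,
      chain = chain_id, resno = i, insert = "",
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE)
    eleno <- eleno + length(atoms)
  }
  do.call(rbind, rows)
}

#' Build a toy two-chain complex
#'
#' Two parallel poly-alanine chains with idealized local geometry (N, CA,
#' C, O and a CB stub per residue), chain B offset from chain A by
#' `separation` Angstrom along z.  Deterministic; `seed` only affects the
#' optional coordinate jitter.
#'
#' @param n_res Residues per chain (>= 2).
#' @param separation Inter-chain CA-CA separation in Angstrom (> 2).
#' @param geometry "extended" or "helical".
#' @param residue Residue type for all positions (3-letter).
#' @param jitter Uniform coordinate jitter amplitude, Angstrom (default 0).
#' @param seed RNG seed for the jitter.
#' @return A `chain_structure` with chains "A" and "B".
#' @export
make_toy_dimer <- function(n_res = 8, separation = 6,
                           geometry = c("extended", "helical"),
                           residue = "ALA", jitter = 0, seed = 1) {
  geometry <- match.arg(geometry)
  stopifnot(n_res >= 2)
  if (separation < 2) stop("clash error: separation below 2 Angstrom")
  a <- .build_polyala_chain(n_res, "A", c(0, 0, 0), residue, geometry)
  b <- .build_polyala_chain(n_res, "B", c(0, 0, separation), residue,
                            geometry)
  at <- rbind(a, b)
  at$eleno <- seq_len(nrow(at))
  if (jitter > 0) {
    set.seed(seed)
    at$x <- at$x + stats::runif(nrow(at), -jitter, jitter)
    at$y <- at$y + stats::runif(nrow(at), -jitter, jitter)
    at$z <- at$z + stats::runif(nrow(at), -jitter, jitter)
  }
  new_chain_structure(at)
}

#' Synthetic trajectory with prescribed per-residue contact occupancy
#'
#' Starting from a dimer pose in which every chain-A residue is in contact,
#' each frame displaces a scheduled subset of chain-A residues far out of
#' contact range (along -z) so that the realized occurrence of residue i
#' equals `round(occupancy[i] * n_frames) / n_frames` exactly; the frames
#' in which a residue stays in contact are a seeded random subset.
#'
#' @param dimer A `chain_structure` from [make_toy_dimer()].
#' @param occupancy Numeric vector in `[0, 1]`, one value per chain-A
#'   residue.
#' @param n_frames Number of frames.
#' @param seed RNG seed for the frame subsets.
#' @param displacement Out-of-contact displacement in Angstrom.
#' @return A `trajectory` of `n_frames` frames.
#' @export
make_synthetic_trajectory <- function(dimer, occupancy, n_frames = 100,
                                      seed = 1, displacement = 40) {
  stopifnot(all(occupancy >= 0), all(occupancy <= 1), n_frames >= 1)
  res_a <- residue_table(subset_chains(dimer, "A"))
  if (length(occupancy) != nrow(res_a))
    stop("occupancy vector length (", length(occupancy),
         ") does not match chain A residues (", nrow(res_a), ")")
  k <- round(occupancy * n_frames)
  if (any(abs(k - occupancy * n_frames) > 1e-9))
    warning("occupancy not exactly representable with ", n_frames,
            " frames; rounded")
  set.seed(seed)
  in_contact <- matrix(FALSE, n_frames, nrow(res_a))
  for (i in seq_len(nrow(res_a)))
    if (k[i] > 0) in_contact[sample.int(n_frames, k[i]), i] <- TRUE
  frames <- vector("list", n_frames)
  a_rows <- which(dimer$atom$chain == "A")
  for (f in seq_len(n_frames)) {
    at <- dimer$atom
    out_res <- res_a$resno[!in_contact[f, ]]
    move <- a_rows[at$resno[a_rows] %in% out_res]
    at$z[move] <- at$z[move] - displacement
    fr <- new_chain_structure(at, model_id = f)
    frames[[f]] <- fr
  }
  new_trajectory(frames)
}

#' Analytic disk image fixtures
#'
#' Exact function values sampled at pixel centers with a full in-disk mask:
#' `"constant"` (value 1), `"zernike_mode"` (Re Z_nm = R_nm(r) cos(m phi)),
#' or `"gaussian_bump"` (exp(-r^2 / 0.18), off-center by `offset`).
#'
#' @param kind One of "constant", "zernike_mode", "gaussian_bump".
#' @param grid_size Pixels per side.
#' @param n,m Mode indices for "zernike_mode".
#' @param offset Length-2 center offset for "gaussian_bump".
#' @return A `disk_image`.
#' @export
make_analytic_disk_image <- function(kind = c("constant", "zernike_mode",
                                              "gaussian_bump"),
                                     grid_size = 64, n = 0, m = 0,
                                     offset = c(0.2, 0.1)) {
  kind <- match.arg(kind)
  g <- as.integer(grid_size)
  h <- 2 / g
  centers <- (seq_len(g) - 0.5) * h - 1
  cx <- matrix(centers, g, g)
  cy <- matrix(centers, g, g, byrow = TRUE)
  r <- sqrt(cx^2 + cy^2)
  phi <- atan2(cy, cx)
  in_disk <- r <= 1
  values <- switch(kind,
    constant = matrix(1, g, g),
    zernike_mode = {
      if (n < 0 || m < 0 || m > n || (n - m) %% 2 != 0)
        stop("domain error: invalid (n, m) Zernike mode")
      matrix(radial_polynomial(n, m, pmin(r, 1)) * cos(m * phi), g, g)
    },
    gaussian_bump = exp(-((cx - offset[1])^2 + (cy - offset[2])^2) / 0.18))
  values[!in_disk] <- NA_real_
  new_disk_image(values, in_disk, matrix(as.integer(in_disk), g, g), g)
}

#' Random smooth band-limited disk image
#'
#' Draws a random function on the unit disk as a band-limited Zernike
#' series with spectrally decaying coefficients (scale (n+1)^-decay) and
#' random phases, sampled at pixel centers -- a smooth random field of the
#' kind produced by projecting real surface patches.  The same draw can be
#' re-sampled rotated by `rotation` radians for invariance testing.
#'
#' @param grid_size Pixels per side.
#' @param order Band limit of the random series.
#' @param seed RNG seed (one seed = one underlying function).
#' @param rotation Rotation angle in radians applied to the function.
#' @param decay Spectral decay exponent.
#' @return A `disk_image`.
#' @export
make_random_disk_image <- function(grid_size = 64, order = 6, seed = 1,
                                   rotation = 0, decay = 1.5) {
  set.seed(seed)
  tab <- zernike_index_table(order)
  amp <- stats::rnorm(nrow(tab)) / (tab$n + 1)^decay
  pha <- stats::runif(nrow(tab), 0, 2 * pi)
  g <- as.integer(grid_size)
  h <- 2 / g
  centers <- (seq_len(g) - 0.5) * h - 1
  cx <- matrix(centers, g, g)
  cy <- matrix(centers, g, g, byrow = TRUE)
  r <- sqrt(cx^2 + cy^2)
  phi <- atan2(cy, cx) - rotation
  v <- matrix(0, g, g)
  for (k in seq_len(nrow(tab)))
    v <- v + amp[k] * radial_polynomial(tab$n[k], tab$m[k], pmin(r, 1)) *
      cos(tab$m[k] * phi + pha[k])
  in_disk <- r <= 1
  v[!in_disk] <- NA_real_
  new_disk_image(v, in_disk, matrix(as.integer(in_disk), g, g), g)
}

#' Single-atom structure for surface tests
#'
#' One CA-like atom with an assigned Rmin/2 radius, placed at `position`.
#'
#' @param rmin_half vdW radius (Rmin/2) in Angstrom.
#' @param position Length-3 numeric position.
#' @param n_atoms Optionally replicate the atom (spaced along x by
#'   `spacing`) to build multi-atom occlusion fixtures.
#' @param spacing Inter-atom spacing for `n_atoms > 1`.
#' @return A `chain_structure`.
#' @export
make_sphere_structure <- function(rmin_half = 1.9, position = c(0, 0, 0),
                                  n_atoms = 1, spacing = 100) {
  at <- data.frame(
    eleno = seq_len(n_atoms), elety = "CA", resid = "ALA", chain = "A",
    resno = seq_len(n_atoms), insert = "",
    x = position[1] + spacing * (seq_len(n_atoms) - 1),
    y = position[2], z = position[3],
    charge = 0, epsilon = 0.08, rmin_half = rmin_half,
    stringsAsFactors = FALSE)
  new_chain_structure(at)
}
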