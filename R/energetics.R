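# Intermolecular non-bonded energetics: 12-6 Lennard-Jones residue-pair
# energies across an interface, coarse-grained Coulomb electrostatics, and
# surface-patch hydropathy.

# Coulomb constant, kcal * Angstrom / (mol * e^2)
.k_coulomb <- 332.0636

#' @keywords internal
.lj_combine <- function(eps_l, eps_m, rmin_half_l, rmin_half_m,
                        combining = c("charmm", "literal")) {
  combining <- match.arg(combining)
  eps <- if (combining == "charmm") sqrt(eps_l * eps_m) else eps_l * eps_m
  list(eps = eps, rmin = rmin_half_l + rmin_half_m)
}

#' 12-6 Lennard-Jones energy of one atom pair
#'
#' E = eps_lm * ((R_lm / r)^12 - 2 (R_lm / r)^6), with the minimum -eps_lm
#' at r = R_lm.  Per-atom parameters are combined as
#' eps_lm = sqrt(eps_l * eps_m) and R_lm = Rmin/2_l + Rmin/2_m (CHARMM
#' convention, the default); `combining = "literal"` uses the plain product
#' eps_l * eps_m instead.
#'
#' @param eps_l,eps_m Well depths, kcal/mol.
#' @param rmin_half_l,rmin_half_m Per-atom Rmin/2, Angstrom.
#' @param r Interatomic distance(s), Angstrom (> 0).
#' @param combining "charmm" or "literal".
#' @return Energy in kcal/mol (vectorized over `r`).
#' @export
lj_pair_energy <- function(eps_l, eps_m, rmin_half_l, rmin_half_m, r,
                           combining = c("charmm", "literal")) {
  if (any(r <= 0)) stop("singularity error: non-positive interatomic distance")
  cmb <- .lj_combine(eps_l, eps_m, rmin_half_l, rmin_half_m, combining)
  s6 <- (cmb$rmin / r)^6
  cmb$eps * (s6^2 - 2 * s6)
}

#' @keywords internal
.check_parameterized <- function(at, what = "structure") {
  if (anyNA(at$epsilon) || anyNA(at$rmin_half))
    stop("unparameterized atoms in ", what,
         ": run assign_parameters() first")
}

#' Lennard-Jones energy between two residues
#'
#' Double sum of [lj_pair_energy()] over all atom pairs of the two residues.
#'
#' @param structure A parameterized `chain_structure`.
#' @param rows_i,rows_j Atom row indices of the two residues (as from
#'   [residue_table()]).
#' @param combining LJ combination rule, see [lj_pair_energy()].
#' @return Energy in kcal/mol.
#' @export
residue_pair_lj <- function(structure, rows_i, rows_j,
                            combining = c("charmm", "literal")) {
  at <- structure$atom
  .check_parameterized(at[c(rows_i, rows_j), ])
  xi <- as.matrix(at[rows_i, c("x", "y", "z")])
  xj <- as.matrix(at[rows_j, c("x", "y", "z")])
  d <- sqrt(outer(rowSums(xi^2), rowSums(xj^2), "+") - 2 * xi %*% t(xj))
  d[d < 1e-12] <- NA
  if (anyNA(d)) stop("singularity error: coincident atoms between residues")
  combining <- match.arg(combining)
  eps <- if (combining == "charmm")
    sqrt(outer(at$epsilon[rows_i], at$epsilon[rows_j]))
  else outer(at$epsilon[rows_i], at$epsilon[rows_j])
  rmin <- outer(at$rmin_half[rows_i], at$rmin_half[rows_j], "+")
  s6 <- (rmin / d)^6
  sum(eps * (s6^2 - 2 * s6))
}

#' Inter-chain residue-pair Lennard-Jones energy matrix
#'
#' Entry (i, j) is the LJ energy between residue i of `chain_a` and residue
#' j of `chain_b`; intra-chain pairs are excluded by construction.
#'
#' @param frame A parameterized `chain_structure` with both chains.
#' @param chain_a,chain_b Chain ids (rows / columns).
#' @param combining LJ combination rule.
#' @return An `energy_matrix`: numeric matrix with dimnames
#'   "chain:resno" and attributes `rows`/`cols` (residue tables).
#' @export
interface_lj_matrix <- function(frame, chain_a, chain_b,
                                combining = c("charmm", "literal")) {
  combining <- match.arg(combining)
  res <- residue_table(frame)
  ra <- res[res$chain == chain_a, , drop = FALSE]
  rb <- res[res$chain == chain_b, , drop = FALSE]
  if (nrow(ra) == 0) stop("chain id not present: ", chain_a)
  if (nrow(rb) == 0) stop("chain id not present: ", chain_b)
  .check_parameterized(frame$atom)
  E <- matrix(0, nrow(ra), nrow(rb),
              dimnames = list(paste0(ra$chain, ":", ra$resno),
                              paste0(rb$chain, ":", rb$resno)))
  for (i in seq_len(nrow(ra)))
    for (j in seq_len(nrow(rb)))
      E[i, j] <- residue_pair_lj(frame, ra$atom_rows[[i]], rb$atom_rows[[j]],
                                 combining = combining)
  structure(E, rows = ra[, 1:4], cols = rb[, 1:4], class = c("energy_matrix",
                                                             "matrix"))
}

#' Coarse-grained Coulomb energy between two bead models
#'
#' E_c = k_e / dielectric * sum_ab q_a q_b / r_ab over all inter-model bead
#' pairs, with k_e = 332.0636 kcal A / (mol e^2).
#'
#' @param cg_a,cg_b `cg_model` objects (see [coarse_grain()]).
#' @param dielectric Relative dielectric constant (> 0, default 1).
#' @return Energy in kcal/mol.
#' @export
coulomb_energy_cg <- function(cg_a, cg_b, dielectric = 1) {
  stopifnot(dielectric > 0)
  a <- cg_a$beads; b <- cg_b$beads
  xa <- as.matrix(a[, c("x", "y", "z")])
  xb <- as.matrix(b[, c("x", "y", "z")])
  d <- sqrt(outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb))
  if (any(d < 1e-9)) {
    k <- which(d < 1e-9, arr.ind = TRUE)[1, ]
    stop("singularity error: coincident beads (", a$chain[k[1]], " ",
         a$resno[k[1]], " ", a$role[k[1]], " / ", b$chain[k[2]], " ",
         b$resno[k[2]], " ", b$role[k[2]], ")")
  }
  .k_coulomb / dielectric * sum(outer(a$charge, b$charge) / d)
}

#' Mean hydropathy of a surface patch
#'
#' Each patch point is assigned to the residue of its nearest heavy atom;
#' the patch value is the point-count-weighted mean of the residues'
#' hydropathy indices (equivalently, the per-point mean of the index of the
#' assigned residue).
#'
#' @param patch A `surface_patch`.
#' @param structure The `chain_structure` the surface was computed from.
#' @param scale Named hydropathy vector (see [load_hydropathy_scale()]).
#' @param max_assign_dist Maximum point-to-atom distance for assignment, A.
#' @return A `patch_hydropathy`: list with `value`, `n_surface_points`, and
#'   per-residue point counts in `residues`.
#' @export
patch_hydropathy <- function(patch, structure,
                             scale = load_hydropathy_scale(),
                             max_assign_dist = 5) {
  at <- structure$atom
  heavy <- which(!.is_hydrogen(at$elety))
  xyz <- as.matrix(at[heavy, c("x", "y", "z")])
  pts <- patch$points
  d2 <- outer(rowSums(pts^2), rowSums(xyz^2), "+") - 2 * pts %*% t(xyz)
  nearest <- max.col(-d2, ties.method = "first")
  mind <- sqrt(pmax(d2[cbind(seq_len(nrow(pts)), nearest)], 0))
  if (any(mind > max_assign_dist))
    stop("assignment error: ", sum(mind > max_assign_dist),
         " patch point(s) farther than ", max_assign_dist,
         " A from any heavy atom")
  rows <- heavy[nearest]
  res3 <- at$resid[rows]
  if (any(!res3 %in% names(scale)))
    stop("hydropathy scale missing residue(s): ",
         paste(unique(res3[!res3 %in% names(scale)]), collapse = ", "))
  key <- paste(at$chain[rows], at$resno[rows], at$resid[rows])
  structure(list(value = mean(scale[res3]),
                 n_surface_points = nrow(pts),
                 residues = table(key)),
            class = "patch_hydropathy")
}

#' Signed hydropathy difference between the fixed and mutated patches
#'
#' H_d = H_fixed - H_mut.
#'
#' @param fixed_side,mut_side `patch_hydropathy` objects (or plain numbers)
#'   computed with the same scale.
#' @return Signed difference.
#' @export
hydropathy_difference <- function(fixed_side, mut_side) {
  v <- function(x) if (inherits(x, "patch_hydropathy")) x$value else x
  v(fixed_side) - v(mut_side)
}

#' Export an energy matrix as TSV with chain/residue labels
#' @param matrix An `energy_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_energy_matrix <- function(matrix, path) {
  utils::write.table(as.data.frame(unclass(matrix)), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}
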