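# Solvent-accessible surface point clouds with outward normals, surface
# patches, and the patch -> oriented-frame -> disk-image projection used by
# the 2D Zernike descriptors.
#
# SAS points are generated by deterministic Fibonacci-lattice sampling of
# each atom's probe-inflated sphere at the requested areal density, keeping
# points not buried inside any neighbouring atom's inflated sphere.  This is
# a DMS-equivalent point/normal cloud; real DMS output can be substituted
# through read_dms_points().

#' @keywords internal
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' @keywords internal
new_surface_cloud <- function(points, normals, atom_index, density,
                              probe_radius) {
  structure(list(points = points, normals = normals,
                 atom_index = atom_index, density = density,
                 probe_radius = probe_radius),
            class = "surface_cloud")
}

#' @export
print.surface_cloud <- function(x, ...) {
  cat("<surface_cloud>", nrow(x$points), "points, density", x$density,
      "pts/A^2, probe", x$probe_radius, "A\n")
  invisible(x)
}

#' Solvent-accessible surface point cloud
#'
#' Samples each atom's sphere of radius (vdW radius + probe) on a
#' deterministic Fibonacci lattice at the requested areal density and keeps
#' the points that are not inside any other atom's probe-inflated sphere.
#' Normals are radial (away from the generating atom center), hence outward.
#'
#' @param structure A `chain_structure`.  Per-atom vdW radii are taken from
#'   the `rmin_half` column when assigned, else from element defaults.
#' @param density Target point density, points per square Angstrom.
#' @param probe_radius Water probe radius in Angstrom.
#' @param heavy_only Drop hydrogens before surfacing (default TRUE).
#' @return A `surface_cloud` with matrices `points` and `normals` (n x 3),
#'   the generating `atom_index` per point, and the requested density/probe.
#' @export
compute_sas_points <- function(structure, density = 5, probe_radius = 1.4,
                               heavy_only = TRUE) {
  stopifnot(density > 0, probe_radius >= 0)
  at <- structure$atom
  if (heavy_only) at <- at[!.is_hydrogen(at$elety), , drop = FALSE]
  if (nrow(at) == 0) stop("empty input: structure has no atoms")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- at$rmin_half
  el <- .atom_element(at$elety)
  fallback <- unname(.element_vdw[el])
  fallback[is.na(fallback)] <- 1.7
  rad[is.na(rad)] <- fallback[is.na(rad)]
  R <- rad + probe_radius
  n_at <- nrow(xyz)
  pts <- vector("list", n_at)
  nrm <- vector("list", n_at)
  src <- vector("list", n_at)
  for (i in seq_len(n_at)) {
    n_i <- max(1L, as.integer(round(density * 4 * pi * R[i]^2)))
    dirs <- .fibonacci_sphere(n_i)
    p <- sweep(dirs * R[i], 2, xyz[i, ], "+")
    keep <- rep(TRUE, n_i)
    # neighbours able to occlude: centre distance < R_i + R_j
    d_cent <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(d_cent < R[i] + R & seq_len(n_at) != i)
    for (j in nb) {
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      keep <- keep & d2 >= (R[j] - 1e-9)^2
      if (!any(keep)) break
    }
    if (any(keep)) {
      pts[[i]] <- p[keep, , drop = FALSE]
      nrm[[i]] <- dirs[keep, , drop = FALSE]
      src[[i]] <- rep(i, sum(keep))
    }
  }
  points <- do.call(rbind, pts)
  if (is.null(points) || nrow(points) == 0)
    stop("empty surface: all sample points buried")
  new_surface_cloud(points, do.call(rbind, nrm), unlist(src),
                    density, probe_radius)
}

#' Read a DMS-style point/normal file
#'
#' Parses lines whose trailing numeric fields contain a surface point and a
#' unit normal (x y z ... nx ny nz), as produced by DMS with the `-n` flag,
#' so externally computed molecular surfaces can replace the built-in
#' sampler bit-for-bit.
#'
#' @param path File path.
#' @param density,probe_radius Metadata recorded on the returned cloud.
#' @return A `surface_cloud`.
#' @export
read_dms_points <- function(path, density = NA_real_, probe_radius = NA_real_) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop("empty input: no point records")
  parse1 <- function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    v <- v[!is.na(v)]
    n <- length(v)
    if (n < 6) return(NULL)
    # DMS with -n: ... x y z type area nx ny nz -> numerics end with
    # (x, y, z, area, nx, ny, nz); bare "x y z nx ny nz" also accepted
    if (n >= 7) c(v[(n - 6):(n - 4)], v[(n - 2):n])
    else c(v[1:3], v[4:6])
  }
  rows <- Filter(Negate(is.null), lapply(lines, parse1))
  if (!length(rows)) stop("no parsable point/normal lines")
  m <- do.call(rbind, rows)
  nrm <- m[, 4:6, drop = FALSE]
  nrm <- nrm / sqrt(rowSums(nrm^2))
  new_surface_cloud(m[, 1:3, drop = FALSE], nrm,
                    rep(NA_integer_, nrow(m)), density, probe_radius)
}

#' Extract a surface patch around a center point
#'
#' Returns the cloud points within `region_radius` (inclusive) of the
#' center.  The center is snapped to the nearest cloud point so that patches
#' are always anchored on the surface.
#'
#' @param cloud A `surface_cloud`.
#' @param center Numeric length-3 center, Angstrom.
#' @param region_radius Patch radius in Angstrom (default 9).
#' @param snap Snap `center` to the nearest cloud point (default TRUE).  With
#'   `snap = FALSE` the center must already lie on a cloud point (within
#'   1e-6 A).
#' @return A `surface_patch`: points, normals, center, region_radius, and
#'   the indices of its points in the parent cloud.
#' @export
extract_patch <- function(cloud, center, region_radius = 9, snap = TRUE) {
  stopifnot(length(center) == 3, region_radius >= 0)
  d2c <- sqrt(colSums((t(cloud$points) - center)^2))
  nearest <- which.min(d2c)
  if (snap) {
    center <- cloud$points[nearest, ]
  } else if (d2c[nearest] > 1e-6) {
    stop("center is not a cloud point (nearest is ",
         format(d2c[nearest], digits = 3), " A away)")
  }
  d <- sqrt(colSums((t(cloud$points) - center)^2))
  keep <- which(d <= region_radius + 1e-12)
  if (!length(keep)) stop("empty patch: no points within region radius")
  structure(list(points = cloud$points[keep, , drop = FALSE],
                 normals = cloud$normals[keep, , drop = FALSE],
                 center = center, region_radius = region_radius,
                 cloud_index = keep),
            class = "surface_patch")
}

#' @export
print.surface_patch <- function(x, ...) {
  cat("<surface_patch>", nrow(x$points), "points, radius",
      x$region_radius, "A\n")
  invisible(x)
}

#' Rotation matrix taking unit vector a onto unit vector b
#' @keywords internal
.rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  s <- sqrt(sum(v^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to a
    axis <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- axis - sum(axis * a) * a
    axis <- axis / sqrt(sum(axis^2))
    K <- matrix(c(0, -axis[3], axis[2],
                  axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    return(diag(3) + 2 * K %*% K)
  }
  K <- matrix(c(0, -v[3], v[2],
                v[3], 0, -v[1],
                -v[2], v[1], 0), 3, 3, byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

#' Reorient a patch so its mean normal lies along the z-axis
#'
#' Applies the rigid rotation taking the patch's mean normal onto +z (or -z
#' with `flip = TRUE`, the convention used for the second patch of a
#' complementarity pair), then recenters points on their centroid.
#'
#' @param patch A `surface_patch`.
#' @param flip Align the mean normal to -z instead of +z.
#' @return An `oriented_patch` with rotated `points`, rotated `normals`, the
#'   3x3 `rotation`, and the applied `flip` flag.
#' @export
reorient_patch <- function(patch, flip = FALSE) {
  mn <- colMeans(patch$normals)
  if (sqrt(sum(mn^2)) < 1e-9)
    stop("degenerate orientation: mean normal is (numerically) zero")
  target <- c(0, 0, if (flip) -1 else 1)
  Rm <- .rotation_between(mn, target)
  pts <- patch$points %*% t(Rm)
  ctr <- colMeans(pts)
  pts <- sweep(pts, 2, ctr)
  structure(list(points = pts, normals = patch$normals %*% t(Rm),
                 rotation = Rm, centroid = ctr, flip = flip,
                 apex_height = NA_real_, theta = NA_real_),
            class = "oriented_patch")
}

#' @export
print.oriented_patch <- function(x, ...) {
  cat("<oriented_patch>", nrow(x$points), "points, apex",
      format(x$apex_height, digits = 4), "A, theta",
      format(x$theta, digits = 4), "deg\n")
  invisible(x)
}

#' @keywords internal
.max_secant_angle <- function(points, h) {
  # largest angle (deg) between the z-axis and secants from C = (0,0,h)
  dz <- h - points[, 3]
  rho <- sqrt(points[, 1]^2 + points[, 2]^2)
  max(atan2(rho, dz)) * 180 / pi
}

#' Place the apex viewpoint so the patch subtends a target cone angle
#'
#' Finds, by bisection, the height of the on-axis point C = (0, 0, h) above
#' a reoriented patch such that the largest angle between the z-axis and any
#' secant from C to a patch point equals `theta_target` (45 degrees by
#' default).  The maximal secant angle is strictly decreasing in h, so the
#' root is unique.
#'
#' @param patch An `oriented_patch`.
#' @param theta_target Target cone half-angle in degrees.
#' @param tol Angular tolerance in degrees.
#' @return The patch with `apex_height` and `theta` filled in.
#' @export
fit_apex_point <- function(patch, theta_target = 45, tol = 1e-6) {
  stopifnot(inherits(patch, "oriented_patch"),
            theta_target > 0, theta_target < 90)
  pts <- patch$points
  rho <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  if (max(rho) < 1e-12)
    stop("solver error: all patch points on the z-axis, no apex height ",
         "achieves the target angle")
  lo <- max(pts[, 3]) + 1e-9
  if (.max_secant_angle(pts, lo) < theta_target)
    stop("solver error: target angle unattainable for this patch geometry")
  hi <- lo + 2 * (max(rho) + diff(range(pts[, 3])) + 1)
  while (.max_secant_angle(pts, hi) > theta_target) hi <- lo + 2 * (hi - lo)
  f <- function(h) .max_secant_angle(pts, h) - theta_target
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  if (abs(f(root)) > max(tol, 1e-4))
    stop("solver error: bisection did not reach the target angle")
  patch$apex_height <- root
  patch$theta <- .max_secant_angle(pts, root)
  patch
}

#' @keywords internal
new_disk_image <- function(values, in_disk, counts, grid_size,
                           theta_max = 45) {
  structure(list(values = values, in_disk = in_disk, counts = counts,
                 grid_size = as.integer(grid_size), theta_max = theta_max),
            class = "disk_image")
}

#' @export
print.disk_image <- function(x, ...) {
  cat("<disk_image>", x$grid_size, "x", x$grid_size, "grid,",
      sum(x$in_disk), "in-disk pixels,",
      sum(x$counts > 0), "observed\n")
  invisible(x)
}

#' Project an oriented patch to a square disk image of secant lengths
#'
#' Each patch point is mapped to unit-disk coordinates
#' (sin a / sin theta_max) * (cos phi, sin phi), where a is the angle of its
#' secant from the apex C = (0, 0, apex_height) to the z-axis and phi its
#' azimuth; with theta_max = 45 degrees the rim of the viewing cone maps to
#' the unit circle.  Points are binned on a `grid_size` x `grid_size`
#' Cartesian grid over [-1, 1]^2 and each pixel stores the mean secant
#' length r = |C - point| of the points it received.  Empty in-disk pixels
#' are filled by one pass of 8-neighbour means, then by the patch mean.
#'
#' @param patch An `oriented_patch` with `apex_height` set (see
#'   [fit_apex_point()]), or a patch plus explicit `apex_height`.
#' @param apex_height Apex height override in Angstrom.
#' @param grid_size Pixels per side (>= 8).
#' @param theta_max Cone half-angle mapped to the unit circle, degrees.
#' @return A `disk_image` with matrices `values` (mean r, NA outside the
#'   disk), `in_disk` (pixel-center radius <= 1) and `counts`.
#' @export
project_to_disk <- function(patch, apex_height = patch$apex_height,
                            grid_size = 64, theta_max = 45) {
  if (grid_size < 8) stop("configuration error: grid_size must be >= 8")
  if (!is.finite(apex_height)) stop("apex height not set; run fit_apex_point()")
  pts <- patch$points
  dz <- apex_height - pts[, 3]
  if (any(dz <= 0))
    stop("apex must lie strictly above all patch points")
  r <- sqrt(pts[, 1]^2 + pts[, 2]^2 + dz^2)
  alpha <- atan2(sqrt(pts[, 1]^2 + pts[, 2]^2), dz)
  phi <- atan2(pts[, 2], pts[, 1])
  u <- sin(alpha) / sin(theta_max * pi / 180)
  x <- u * cos(phi)
  y <- u * sin(phi)
  g <- as.integer(grid_size)
  h <- 2 / g
  ix <- pmin(pmax(floor((x + 1) / h) + 1, 1), g)
  iy <- pmin(pmax(floor((y + 1) / h) + 1, 1), g)
  lin <- (iy - 1) * g + ix
  counts <- matrix(0L, g, g)
  sums <- matrix(0, g, g)
  tab_n <- tapply(rep(1L, length(lin)), lin, sum)
  tab_s <- tapply(r, lin, sum)
  counts[as.integer(names(tab_n))] <- as.integer(tab_n)
  sums[as.integer(names(tab_s))] <- tab_s
  centers <- (seq_len(g) - 0.5) * h - 1
  cx <- matrix(centers, g, g)
  cy <- matrix(centers, g, g, byrow = TRUE)
  in_disk <- cx^2 + cy^2 <= 1
  values <- matrix(NA_real_, g, g)
  obs <- counts > 0
  values[obs] <- sums[obs] / counts[obs]
  # fill policy: one pass of 8-neighbour means over observed pixels, then
  # the patch mean, so the expansion integrand is defined on the whole disk
  hole <- in_disk & !obs
  if (any(hole)) {
    filled <- values
    idx <- which(hole, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1]; j <- idx[k, 2]
      ni <- max(1, i - 1):min(g, i + 1)
      nj <- max(1, j - 1):min(g, j + 1)
      nb <- values[ni, nj]
      nb <- nb[!is.na(nb)]
      filled[i, j] <- if (length(nb)) mean(nb) else mean(r)
    }
    values <- filled
  }
  values[!in_disk & !obs] <- NA_real_
  new_disk_image(values, in_disk, counts, g, theta_max)
}

#' Normalize a disk image for descriptor comparison
#'
#' Shifts the in-disk pixel values to zero mean and scales them to unit
#' maximum absolute value, making descriptor distances comparable across
#' patches of different size and depth.
#'
#' @param image A `disk_image`.
#' @return The normalized `disk_image`.
#' @export
normalize_disk_image <- function(image) {
  v <- image$values[image$in_disk]
  v <- v - mean(v, na.rm = TRUE)
  m <- max(abs(v), na.rm = TRUE)
  if (m > 0) v <- v / m
  image$values[image$in_disk] <- v
  image
}

#' Patch to rotation-invariant Zernike descriptor, end to end
#'
#' Convenience pipeline: reorient (optionally flipped), fit the apex for the
#' target cone angle, project to a disk image, normalize, expand in the 2D
#' Zernike basis and return the invariant vector.
#'
#' @param patch A `surface_patch`.
#' @param order Zernike expansion order N.
#' @param grid_size Disk-image resolution.
#' @param flip Use the "normals down" convention (complementarity partner).
#' @param theta_max Cone half-angle in degrees.
#' @return A `zernike_invariants` vector.
#' @export
patch_invariants <- function(patch, order = 20, grid_size = 64,
                             flip = FALSE, theta_max = 45) {
  op <- fit_apex_point(reorient_patch(patch, flip = flip),
                       theta_target = theta_max)
  img <- normalize_disk_image(
    project_to_disk(op, grid_size = grid_size, theta_max = theta_max))
  zernike_invariants(zernike_expand(img, order = order))
}
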