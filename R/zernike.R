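# 2D Zernike expansion of disk images, rotation-invariant descriptors and
# descriptor distances.
#
# Basis convention: Z_nm(r, phi) = R_nm(r) * exp(i m phi) for 0 <= m <= n,
# (n - m) even; coefficients c_nm = (n+1)/pi * <Z_nm | f> with the conjugate
# inner product over the unit disk.  Only m >= 0 is stored (for real images
# the moduli of +/-m coincide), which gives 121 coefficients at N = 20.
#
# Quadrature: the image is piecewise constant on pixels, so
# <Z|f> = sum_pixels f_p * integral(Z* over pixel-intersect-disk); the
# per-pixel basis integrals are computed once by sub-pixel midpoint
# sampling (subsample^2 nodes per pixel, clipped to the disk) and cached.
# An exact discrete least-squares projection is available as an
# alternative expansion method.

.pepmc_cache <- new.env(parent = emptyenv())

#' Radial Zernike polynomial R_nm(r)
#'
#' Finite-sum form: R_nm(r) = sum_k (-1)^k (n-k)! /
#' (k! ((n+m)/2 - k)! ((n-m)/2 - k)!) r^(n-2k), for 0 <= m <= n with
#' (n - m) even; R_nm(1) = 1.
#'
#' @param n,m Integer indices, 0 <= m <= n, (n - m) even.
#' @param r Numeric vector of radii in `[0, 1]`.
#' @return Numeric vector of `R_nm(r)` values.
#' @export
radial_polynomial <- function(n, m, r) {
  if (n < 0 || m < 0 || m > n) stop("domain error: need 0 <= m <= n")
  if ((n - m) %% 2 != 0) stop("domain error: (n - m) must be even")
  out <- numeric(length(r))
  for (k in 0:((n - m) / 2)) {
    coef <- (-1)^k * exp(lfactorial(n - k) - lfactorial(k) -
                           lfactorial((n + m) / 2 - k) -
                           lfactorial((n - m) / 2 - k))
    out <- out + coef * r^(n - 2 * k)
  }
  out
}

#' Number of Zernike coefficients up to order N
#'
#' Counts the index pairs (n, m) with 0 <= m <= n <= N and (n - m) even;
#' 121 at N = 20.
#'
#' @param order Maximum order N (>= 0).
#' @return Integer count.
#' @export
coefficient_count <- function(order) {
  if (order < 0) stop("domain error: order must be >= 0")
  nrow(zernike_index_table(order))
}

#' Index table of (n, m) pairs up to order N, lexicographic
#' @param order Maximum order N.
#' @return data.frame with integer columns `n`, `m`.
#' @export
zernike_index_table <- function(order) {
  idx <- do.call(rbind, lapply(0:order, function(n) {
    m <- seq(n %% 2, n, by = 2)
    cbind(n = rep(n, length(m)), m = m)
  }))
  as.data.frame(idx)
}

#' Sub-pixel quadrature nodes inside the unit disk
#' @keywords internal
.make_subnodes <- function(grid_size, subsample) {
  g <- as.integer(grid_size); s <- as.integer(subsample)
  h <- 2 / g
  # sub-pixel centers on the fine (g*s) grid, column-major in the coarse grid
  fine <- (seq_len(g * s) - 0.5) * (h / s) - 1
  x <- rep(fine, times = g * s)
  y <- rep(fine, each = g * s)
  keep <- x^2 + y^2 <= 1
  x <- x[keep]; y <- y[keep]
  cell_ix <- pmin(floor((x + 1) / h) + 1, g)
  cell_iy <- pmin(floor((y + 1) / h) + 1, g)
  list(x = x, y = y, cell = (cell_iy - 1L) * g + cell_ix,
       w = (h / s)^2, grid_size = g)
}

#' Area of the unit disk inside the rectangle [x0,x1] x [y0,y1]
#' @keywords internal
.disk_rect_area <- function(x0, x1, y0, y1) {
  Fint <- function(x) (x * sqrt(pmax(0, 1 - x^2)) + asin(pmin(1, pmax(-1, x)))) / 2
  Apos <- function(x, y) {
    # area of {0<=u<=x, 0<=v<=y, u^2+v^2<=1} for x,y >= 0
    x <- pmin(x, 1)
    if (x <= 0 || y <= 0) return(0)
    if (y >= 1) return(Fint(x))
    u0 <- sqrt(1 - y^2)
    y * pmin(x, u0) + if (x > u0) Fint(x) - Fint(u0) else 0
  }
  A <- function(x, y) sign(x) * sign(y) * Apos(abs(x), abs(y))
  A(x1, y1) - A(x0, y1) - A(x1, y0) + A(x0, y0)
}

#' Per-pixel integrated (conjugated) Zernike basis, cached
#'
#' Integrates each basis function over every pixel's in-disk area by
#' sub-pixel midpoint sampling, plus an exact-area rim correction: the
#' difference between the true pixel/disk overlap area and the jagged
#' subsampled one is assigned the basis value on the rim (R_nm(1) = 1).
#' @keywords internal
.cell_basis <- function(grid_size, order, subsample = 8L) {
  key <- paste0("cb_", grid_size, "_", order, "_", subsample)
  if (!is.null(.pepmc_cache[[key]])) return(.pepmc_cache[[key]])
  nd <- .make_subnodes(grid_size, subsample)
  g <- as.integer(grid_size)
  h <- 2 / g
  # every pixel with positive disk overlap: centers within 1 + h covers all
  centers <- (seq_len(g) - 0.5) * h - 1
  cx <- rep(centers, times = g)
  cy <- rep(centers, each = g)
  cand <- which(sqrt(cx^2 + cy^2) <= 1 + h)
  area <- vapply(cand, function(p) {
    x0 <- -1 + ((p - 1L) %% g) * h
    y0 <- -1 + ((p - 1L) %/% g) * h
    .disk_rect_area(x0, x0 + h, y0, y0 + h)
  }, numeric(1))
  cells <- cand[area > 0]
  area <- area[area > 0]
  r <- sqrt(nd$x^2 + nd$y^2)
  phi <- atan2(nd$y, nd$x)
  counts <- rowsum(rep(1L, length(nd$cell)), nd$cell)
  pos <- match(as.integer(rownames(counts)), cells)
  idx <- zernike_index_table(order)
  Bbar <- matrix(0 + 0i, length(cells), nrow(idx))
  for (k in seq_len(nrow(idx))) {
    col <- radial_polynomial(idx$n[k], idx$m[k], r) *
      exp(-1i * idx$m[k] * phi) * nd$w
    rs <- rowsum(cbind(Re(col), Im(col)), nd$cell)
    Bbar[pos, k] <- complex(real = rs[, 1], imaginary = rs[, 2])
  }
  # rim correction: the area missed by jagged subsampling carries the
  # basis value on the rim, where R_nm(1) = 1
  n_sub <- numeric(length(cells))
  n_sub[pos] <- counts[, 1]
  dA <- area - n_sub * nd$w
  partial <- which(abs(dA) > 1e-15)
  for (w in partial) {
    phi_c <- atan2(cy[cells[w]], cx[cells[w]])
    Bbar[w, ] <- Bbar[w, ] + dA[w] * exp(-1i * idx$m * phi_c)
  }
  out <- list(Bbar = Bbar, cells = cells, idx = idx, grid_size = g)
  .pepmc_cache[[key]] <- out
  out
}

#' Fill undefined pixel values by 8-neighbour means, then the global mean
#' @keywords internal
.fill_values <- function(values, cells) {
  f <- values[cells]
  if (!anyNA(f)) return(f)
  g <- nrow(values)
  glob <- mean(values, na.rm = TRUE)
  for (w in which(is.na(f))) {
    p <- cells[w]
    i <- (p - 1L) %% g + 1L
    j <- (p - 1L) %/% g + 1L
    nb <- values[max(1, i - 1):min(g, i + 1), max(1, j - 1):min(g, j + 1)]
    nb <- nb[!is.na(nb)]
    f[w] <- if (length(nb)) mean(nb) else glob
  }
  f
}

#' Expand a disk image in the 2D Zernike basis
#'
#' Computes c_nm = (n+1)/pi * <Z_nm | f> for all (n, m) with
#' 0 <= m <= n <= order, (n - m) even.  With `method = "quadrature"`
#' (default) the image is treated as piecewise constant on its pixels and
#' the basis is integrated over each pixel's in-disk area; with
#' `method = "least_squares"` the coefficients solve the discrete
#' projection exactly, so band-limited images round-trip to machine
#' precision.
#'
#' @param image A `disk_image` (values defined on in-disk pixels).
#' @param order Maximum order N (default 20, i.e. 121 coefficients).
#' @param method "quadrature" (default) or "least_squares".
#' @return A `zernike_expansion`: complex vector `coefficients` with index
#'   table `idx`, plus `order` and `grid_size`.
#' @export
zernike_expand <- function(image, order = 20,
                           method = c("quadrature", "least_squares")) {
  method <- match.arg(method)
  stopifnot(inherits(image, "disk_image"), order >= 0)
  g <- image$grid_size
  vals <- image$values
  if (!any(is.finite(vals[image$in_disk])))
    stop("empty image: no valid in-disk pixels")
  if (method == "least_squares") {
    keep <- which(image$in_disk & is.finite(vals))
    centers <- (seq_len(g) - 0.5) * (2 / g) - 1
    cx <- rep(centers, times = g)[keep]
    cy <- rep(centers, each = g)[keep]
    r <- sqrt(cx^2 + cy^2); phi <- atan2(cy, cx)
    idx <- zernike_index_table(order)
    cols <- vector("list", nrow(idx))
    for (k in seq_len(nrow(idx))) {
      R <- radial_polynomial(idx$n[k], idx$m[k], r)
      cols[[k]] <- if (idx$m[k] == 0) cbind(R)
      else cbind(2 * R * cos(idx$m[k] * phi), -2 * R * sin(idx$m[k] * phi))
    }
    A <- do.call(cbind, cols)
    sol <- qr.solve(qr(A, LAPACK = TRUE), vals[keep])
    co <- complex(length.out = nrow(idx))
    p <- 1
    for (k in seq_len(nrow(idx))) {
      if (idx$m[k] == 0) { co[k] <- sol[p] + 0i; p <- p + 1 }
      else { co[k] <- complex(real = sol[p], imaginary = sol[p + 1]); p <- p + 2 }
    }
    idx_tab <- idx
  } else {
    cb <- .cell_basis(g, order)
    f <- .fill_values(vals, cb$cells)
    co <- as.vector(crossprod(cb$Bbar, f)) * (cb$idx$n + 1) / pi
    idx_tab <- cb$idx
  }
  structure(list(coefficients = co, idx = idx_tab,
                 order = as.integer(order), grid_size = g),
            class = "zernike_expansion")
}

#' @export
print.zernike_expansion <- function(x, ...) {
  cat("<zernike_expansion> order", x$order, "-", length(x$coefficients),
      "coefficients\n")
  invisible(x)
}

#' Reconstruct a disk image from a Zernike expansion
#'
#' Evaluates the truncated series on a `grid_size` grid.  Real images are
#' recovered from the stored m >= 0 coefficients by conjugate-pair
#' completion: f = Re(sum_m0 c Z + 2 sum_{m>0} c Z).
#'
#' @param expansion A `zernike_expansion`.
#' @param grid_size Output resolution (default: the expansion's).
#' @return A `disk_image`.
#' @export
zernike_reconstruct <- function(expansion, grid_size = expansion$grid_size) {
  g <- as.integer(grid_size)
  h <- 2 / g
  centers <- (seq_len(g) - 0.5) * h - 1
  cx <- rep(centers, times = g)
  cy <- rep(centers, each = g)
  in_disk <- cx^2 + cy^2 <= 1
  r <- sqrt(cx^2 + cy^2)[in_disk]
  phi <- atan2(cy, cx)[in_disk]
  idx <- expansion$idx
  acc <- complex(length.out = length(r))
  for (k in seq_len(nrow(idx))) {
    Z <- radial_polynomial(idx$n[k], idx$m[k], r) * exp(1i * idx$m[k] * phi)
    mult <- if (idx$m[k] == 0) 1 else 2
    acc <- acc + mult * expansion$coefficients[k] * Z
  }
  values <- matrix(NA_real_, g, g)
  values[in_disk] <- Re(acc)
  new_disk_image(values, matrix(in_disk, g, g),
                 matrix(as.integer(in_disk), g, g), g)
}

#' Rotation-invariant Zernike descriptor vector
#'
#' Moduli z_nm = |c_nm| in fixed (n, m) lexicographic order; invariant
#' under rotations of the image about the disk center.
#'
#' @param expansion A `zernike_expansion`.
#' @return A `zernike_invariants` numeric vector with attribute `order`.
#' @export
zernike_invariants <- function(expansion) {
  structure(Mod(expansion$coefficients), order = expansion$order,
            class = "zernike_invariants")
}

#' Euclidean distance between two invariant descriptor vectors
#'
#' d = sqrt(sum_k (z_ak - z_bk)^2); the shape-complementarity score when the
#' two patches were projected with opposite orientation conventions.
#'
#' @param a,b `zernike_invariants` (or plain numeric vectors) of equal
#'   order/length.
#' @return Non-negative distance.
#' @export
descriptor_distance <- function(a, b) {
  if (length(a) != length(b))
    stop("shape error: invariant vectors have different lengths")
  oa <- attr(a, "order"); ob <- attr(b, "order")
  if (!is.null(oa) && !is.null(ob) && oa != ob)
    stop("shape error: invariant vectors have different orders")
  sqrt(sum((as.numeric(a) - as.numeric(b))^2))
}

#' Numerical Gram matrix of the Zernike basis
#'
#' Pixel-quadrature inner products <Z_nm | Z_n'm'> on a `grid_size` pixel
#' grid (each pixel integrated by `subsample`^2 midpoint nodes clipped to
#' the disk) for all index pairs up to `order`; the analytic value is
#' pi/(n+1) * delta_nn' * delta_mm'.
#'
#' @param order Maximum order.
#' @param grid_size Pixel grid resolution.
#' @param subsample Sub-pixel sampling factor per axis.
#' @return Complex matrix with row/column names "n,m".
#' @export
zernike_gram <- function(order, grid_size = 256, subsample = 4L) {
  nd <- .make_subnodes(grid_size, subsample)
  idx <- zernike_index_table(order)
  nc <- nrow(idx)
  G <- matrix(0 + 0i, nc, nc)
  chunk <- 200000L
  n_nodes <- length(nd$x)
  for (start in seq(1L, n_nodes, by = chunk)) {
    sel <- start:min(start + chunk - 1L, n_nodes)
    r <- sqrt(nd$x[sel]^2 + nd$y[sel]^2)
    phi <- atan2(nd$y[sel], nd$x[sel])
    B <- matrix(0 + 0i, length(sel), nc)
    for (k in seq_len(nc))
      B[, k] <- radial_polynomial(idx$n[k], idx$m[k], r) *
        exp(1i * idx$m[k] * phi)
    G <- G + crossprod(Conj(B), B) * nd$w
  }
  lab <- paste(idx$n, idx$m, sep = ",")
  dimnames(G) <- list(lab, lab)
  G
}

#' Serialize invariant vectors to CSV
#'
#' One row per patch: id then the descriptor values.
#'
#' @param invariants Named list of `zernike_invariants`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_invariants_csv <- function(invariants, path) {
  rows <- lapply(names(invariants), function(id)
    data.frame(id = id, t(as.numeric(invariants[[id]]))))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
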