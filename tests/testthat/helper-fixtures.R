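# Shared test helpers: hand-built PDB text, brute-force reference
# implementations, and small constructors.

pdb_atom_line <- function(serial, name, res, chain, resno, x, y, z,
                          record = "ATOM", icode = "") {
  namef <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00",
          record, serial, namef, res, chain, resno, icode, x, y, z)
}

# n_res poly-ALA backbone+CB along x, one chain
pdb_poly_ala <- function(n_res = 3, chain = "A", z = 0, serial0 = 0) {
  lines <- character(0)
  serial <- serial0
  for (i in seq_len(n_res)) {
    base <- c(3.8 * (i - 1), 0, z)
    offs <- list(N = c(-1.2, 0.5, 0), CA = c(0, 0, 0), C = c(1.2, 0.5, 0),
                 O = c(1.4, 1.7, 0), CB = c(0, -1, 1.1))
    for (a in names(offs)) {
      serial <- serial + 1
      p <- base + offs[[a]]
      lines <- c(lines, pdb_atom_line(serial, a, "ALA", chain, i,
                                      p[1], p[2], p[3]))
    }
  }
  lines
}

# brute-force residue-pair LJ with CHARMM combination
brute_lj <- function(at, rows_i, rows_j) {
  tot <- 0
  for (l in rows_i) for (m in rows_j) {
    r <- sqrt((at$x[l] - at$x[m])^2 + (at$y[l] - at$y[m])^2 +
                (at$z[l] - at$z[m])^2)
    eps <- sqrt(at$epsilon[l] * at$epsilon[m])
    rmin <- at$rmin_half[l] + at$rmin_half[m]
    tot <- tot + eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
  }
  tot
}

# brute-force per-frame interface recount
brute_occurrence <- function(traj, cutoff = 8) {
  f1 <- traj$frames[[1]]
  resno <- sort(unique(f1$atom$resno[f1$atom$chain == "A"]))
  counts <- stats::setNames(numeric(length(resno)), resno)
  for (fr in traj$frames) {
    at <- fr$atom
    ca_a <- at[at$chain == "A" & at$elety == "CA", ]
    ca_b <- at[at$chain == "B" & at$elety == "CA", ]
    for (i in seq_len(nrow(ca_a))) {
      d <- sqrt((ca_a$x[i] - ca_b$x)^2 + (ca_a$y[i] - ca_b$y)^2 +
                  (ca_a$z[i] - ca_b$z)^2)
      if (any(d < cutoff)) counts[as.character(ca_a$resno[i])] <-
          counts[as.character(ca_a$resno[i])] + 1
    }
  }
  counts / length(traj$frames)
}

# brute-force longest-run segment selection
brute_segment <- function(resno, occ, threshold = 0.25) {
  best <- NULL
  n <- length(resno)
  for (s in 1:n) for (e in s:n) {
    if (all(occ[s:e] > threshold)) {
      len <- e - s + 1
      if (is.null(best) || len > best$len ||
          (len == best$len && mean(occ[s:e]) > best$mn))
        best <- list(s = resno[s], e = resno[e], len = len,
                     mn = mean(occ[s:e]))
    }
  }
  best
}

# minimal surface_patch wrapper around bare points
manual_patch <- function(points, normals = NULL) {
  if (is.null(normals)) {
    normals <- points / sqrt(rowSums(points^2))
  }
  structure(list(points = points, normals = normals,
                 center = colMeans(points),
                 region_radius = max(sqrt(rowSums(points^2)))),
            class = "surface_patch")
}

# minimal oriented_patch wrapper
manual_oriented <- function(points) {
  structure(list(points = points,
                 normals = matrix(rep(c(0, 0, 1), nrow(points)),
                                  ncol = 3, byrow = TRUE),
                 rotation = diag(3), centroid = c(0, 0, 0), flip = FALSE,
                 apex_height = NA_real_, theta = NA_real_),
            class = "oriented_patch")
}

rigid_transform <- function(st, R = diag(3), t = c(0, 0, 0)) {
  xyz <- as.matrix(st$atom[, c("x", "y", "z")]) %*% t(R)
  st$atom$x <- xyz[, 1] + t[1]
  st$atom$y <- xyz[, 2] + t[2]
  st$atom$z <- xyz[, 3] + t[3]
  st
}

rotz <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}
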