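# SAS point clouds, patches, reorientation, apex fitting, disk projection.

test_that("single-sphere SAS matches the analytic shell", {
  st <- make_sphere_structure(rmin_half = 1.9)
  cl <- compute_sas_points(st, density = 5, probe_radius = 1.4)
  r <- sqrt(rowSums(cl$points^2))
  expect_true(all(abs(r - 3.3) < 0.01))
  expect_equal(nrow(cl$points), round(5 * 4 * pi * 3.3^2), tolerance = 0.1)
  # normals are radial
  dots <- rowSums(cl$normals * cl$points / r)
  expect_true(all(dots > 0.999))
})

test_that("distant atoms give disjoint full shells; fused atoms occlude", {
  st2 <- make_sphere_structure(1.9, n_atoms = 2, spacing = 100)
  cl2 <- compute_sas_points(st2, 5, 1.4)
  one <- compute_sas_points(make_sphere_structure(1.9), 5, 1.4)
  expect_equal(nrow(cl2$points), 2 * nrow(one$points))

  fused <- make_sphere_structure(1.9, n_atoms = 2, spacing = 0.5)
  clf <- compute_sas_points(fused, 5, 1.4)
  expect_lt(nrow(clf$points), 2 * nrow(one$points))
  # no surviving point may lie inside the other atom's inflated sphere
  ctr2 <- c(0.5, 0, 0)
  d_other <- sqrt(colSums((t(clf$points) - ctr2)^2))
  d_self <- sqrt(rowSums(clf$points^2))
  expect_true(all(pmin(d_self, d_other) >= 3.3 - 1e-6))
})

test_that("SAS cloud is translation-equivariant and empty input errors", {
  st <- make_sphere_structure(1.7)
  cl0 <- compute_sas_points(st, 3, 1.4)
  cl1 <- compute_sas_points(make_sphere_structure(1.7, position = c(5, 6, 7)),
                            3, 1.4)
  expect_equal(sweep(cl1$points, 2, c(5, 6, 7)), cl0$points,
               tolerance = 1e-12)
  empty <- st
  empty$atom <- empty$atom[0, ]
  expect_error(compute_sas_points(empty), "empty")
})

test_that("patch extraction equals a brute-force distance filter", {
  st <- make_sphere_structure(1.9)
  cl <- compute_sas_points(st, 5, 1.4)
  ctr <- cl$points[17, ]
  p <- extract_patch(cl, ctr, 2.0)
  d <- sqrt(colSums((t(cl$points) - ctr)^2))
  expect_setequal(p$cloud_index, which(d <= 2.0))
  # radius covering the cloud returns the whole cloud
  all_p <- extract_patch(cl, ctr, 100)
  expect_equal(nrow(all_p$points), nrow(cl$points))
  # boundary inclusive: radius 0 keeps the (snapped) centre point
  p0 <- extract_patch(cl, ctr, 0)
  expect_equal(nrow(p0$points), 1)
  expect_error(extract_patch(cl, c(500, 0, 0), 1, snap = FALSE),
               "not a cloud point")
})

test_that("reorientation is rigid and aligns the mean normal with z", {
  st <- make_sphere_structure(1.9)
  cl <- compute_sas_points(st, 5, 1.4)
  side <- cl$points[which.max(cl$points[, 1]), ]
  p <- extract_patch(cl, side, 2.5)
  op <- reorient_patch(p)
  mn <- colMeans(op$normals)
  mn <- mn / sqrt(sum(mn^2))
  expect_lt(acos(min(1, mn[3])), 1e-6)
  # pairwise distances preserved
  d0 <- as.matrix(dist(p$points))
  d1 <- as.matrix(dist(op$points))
  expect_lt(max(abs(d0 - d1)), 1e-9)
  # flipped convention points the mean normal at -z
  opf <- reorient_patch(p, flip = TRUE)
  mnf <- colMeans(opf$normals)
  expect_lt(mnf[3] / sqrt(sum(mnf^2)), -1 + 1e-6)
  # spherical cap is axially symmetric after reorientation
  expect_lt(abs(mean(op$points[, 1])), 0.05)
  expect_lt(abs(mean(op$points[, 2])), 0.05)
})

test_that("already-aligned patches get the identity rotation", {
  pts <- cbind(runif(30, -2, 2), runif(30, -2, 2), runif(30, -0.1, 0.1))
  p <- manual_patch(pts, normals = matrix(rep(c(0, 0, 1), 30),
                                          ncol = 3, byrow = TRUE))
  op <- reorient_patch(p)
  centred <- sweep(pts, 2, colMeans(pts))
  expect_lt(max(abs(op$points - centred)), 1e-9)
})

test_that("apex fitting solves the flat-disk closed forms", {
  ang <- seq(0, 2 * pi, length.out = 181)[-181]
  disk <- rbind(cbind(2 * cos(ang), 2 * sin(ang), 0), c(0, 0, 0))
  op <- fit_apex_point(manual_oriented(disk))
  expect_equal(op$apex_height, 2, tolerance = 1e-6)
  expect_equal(op$theta, 45, tolerance = 1e-4)
  # tan(theta) = rho / h: theta = atan(1/2) gives h = 2 rho
  op2 <- fit_apex_point(manual_oriented(disk),
                        theta_target = atan(0.5) * 180 / pi)
  expect_equal(op2$apex_height, 4, tolerance = 1e-6)
  # similarity: scaling the patch scales the apex height
  op3 <- fit_apex_point(manual_oriented(disk * 2.5))
  expect_equal(op3$apex_height, 2.5 * op$apex_height, tolerance = 1e-6)
})

test_that("max secant angle decreases monotonically in apex height", {
  set.seed(11)
  pts <- cbind(rnorm(40), rnorm(40), rnorm(40, sd = 0.3))
  hs <- seq(max(pts[, 3]) + 0.05, max(pts[, 3]) + 20, length.out = 60)
  angs <- vapply(hs, function(h) pepmc:::.max_secant_angle(pts, h),
                 numeric(1))
  expect_true(all(diff(angs) < 0))
})

test_that("disk projection bins mean secant lengths and conserves points", {
  ang <- seq(0, 2 * pi, length.out = 200)[-200]
  cap <- cbind(0.9 * cos(ang), 0.9 * sin(ang), 0)
  op <- fit_apex_point(manual_oriented(rbind(cap, c(0, 0, 0))))
  img <- project_to_disk(op, grid_size = 16)
  expect_equal(sum(img$counts), nrow(cap) + 1)
  expect_error(project_to_disk(op, grid_size = 4), "grid_size")

  # all points equidistant from C: every observed pixel holds that r
  h <- 2
  shell <- cbind(cos(ang), sin(ang), 0)  # all at distance sqrt(1+h^2) from C
  ops <- manual_oriented(shell)
  ops$apex_height <- h
  img3 <- project_to_disk(ops, grid_size = 16)
  vals <- img3$values[img3$counts > 0]
  expect_true(all(abs(vals - sqrt(1 + h^2)) < 1e-9))
})

test_that("two points in one pixel average their secant lengths", {
  # two near-axis points with secants r = 2 and r ~ 4 share a pixel
  pts <- rbind(c(0.001, 0, 0), c(0.0005, 0, -2))
  op <- manual_oriented(pts)
  op$apex_height <- 2
  img <- project_to_disk(op, grid_size = 16)
  got <- img$values[which(img$counts == 2)]
  expect_length(got, 1)
  expect_equal(got, mean(c(2, 4)), tolerance = 1e-3)
})

test_that("disk image is equivariant under patch rotation about z", {
  set.seed(5)
  ang <- runif(80, 0, 2 * pi)
  rad <- sqrt(runif(80)) * 1.5
  pts <- cbind(rad * cos(ang), rad * sin(ang), 0.2 * sin(3 * ang) * rad)
  op <- fit_apex_point(manual_oriented(pts))
  img0 <- project_to_disk(op, grid_size = 24)
  th <- 37 * pi / 180
  opr <- fit_apex_point(manual_oriented(pts %*% t(rotz(th))))
  imgr <- project_to_disk(opr, grid_size = 24)
  # rotation-invariant summaries agree up to re-binning at pixel scale
  expect_equal(sum(imgr$counts), sum(img0$counts))
  expect_equal(mean(imgr$values[imgr$counts > 0]),
               mean(img0$values[img0$counts > 0]), tolerance = 1e-2)
  i0 <- zernike_invariants(zernike_expand(normalize_disk_image(img0), 8))
  ir <- zernike_invariants(zernike_expand(normalize_disk_image(imgr), 8))
  expect_lt(descriptor_distance(i0, ir),
            0.15 * sqrt(sum(as.numeric(i0)^2)))
})

test_that("normalization centers and scales in-disk values", {
  img <- make_analytic_disk_image("gaussian_bump", 32)
  nm <- normalize_disk_image(img)
  v <- nm$values[nm$in_disk]
  expect_lt(abs(mean(v)), 1e-12)
  expect_equal(max(abs(v)), 1)
})

test_that("DMS-style point files round-trip through the reader", {
  tmp <- withr::local_tempfile()
  writeLines(c("RES 1 A 1.000 2.000 3.000 SR0 0.5 0.000 0.000 1.000",
               "RES 1 A 4.000 5.000 6.000 SR0 0.5 1.000 0.000 0.000"), tmp)
  cl <- read_dms_points(tmp)
  expect_equal(nrow(cl$points), 2)
  expect_equal(cl$points[1, ], c(1, 2, 3))
  expect_equal(cl$normals[2, ], c(1, 0, 0))
})
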