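# Interface residues, contact occurrence, segment selection, vdW shares,
# RMSD, extension intervals, MSA frequencies.

test_that("interface membership uses a strict CA-CA cutoff", {
  two <- function(d) read_structure(c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "ALA", "B", 1, d, 0, 0)))
  ir <- interface_residues(two(7.9), "A", "B", 8)
  expect_equal(ir$a, 1)
  expect_equal(ir$b, 1)
  ir8 <- interface_residues(two(8.0), "A", "B", 8)
  expect_length(ir8$a, 0)

  # brute-force all-pairs scan on a toy dimer
  st <- make_toy_dimer(6, 6)
  ir2 <- interface_residues(st, "A", "B", 8)
  at <- st$atom
  ca_a <- at[at$chain == "A" & at$elety == "CA", ]
  ca_b <- at[at$chain == "B" & at$elety == "CA", ]
  expect_a <- ca_a$resno[vapply(seq_len(nrow(ca_a)), function(i)
    any(sqrt((ca_a$x[i] - ca_b$x)^2 + (ca_a$y[i] - ca_b$y)^2 +
               (ca_a$z[i] - ca_b$z)^2) < 8), logical(1))]
  expect_equal(ir2$a, expect_a)
})

test_that("contact occurrence counts interface frames per residue", {
  dimer <- make_toy_dimer(6, 6)
  occ <- c(0.5, 0, 1, 0.3, 0.8, 0.1)
  traj <- make_synthetic_trajectory(dimer, occ, n_frames = 10, seed = 5)
  prof <- contact_occurrence(traj, "A", "B", 8)
  expect_equal(prof$occurrence, occ)
  # matches the brute-force per-frame recount
  expect_equal(prof$occurrence, unname(brute_occurrence(traj)))
  expect_error(contact_occurrence(pepmc:::new_trajectory(list()), "A", "B"),
               "empty")
})

test_that("segment selection follows the longest-run rule with tie-breaks", {
  prof <- data.frame(resno = 1:5, occurrence = c(0.1, 0.3, 0.4, 0.5, 0.2))
  seg <- select_peptide_segment(prof, 0.25)
  expect_equal(c(seg$start, seg$end, seg$length), c(2, 4, 3))

  all9 <- data.frame(resno = 1:7, occurrence = rep(0.9, 7))
  seg2 <- select_peptide_segment(all9, 0.25)
  expect_equal(seg2$length, 7)

  # equal lengths: the higher-mean run wins
  tie <- data.frame(resno = 1:7,
                    occurrence = c(0.5, 0.5, 0.1, 0.7, 0.7, 0.1, 0.1))
  seg3 <- select_peptide_segment(tie, 0.25)
  expect_equal(seg3$start, 4)

  # equal length and mean: smaller start id
  tie2 <- data.frame(resno = 1:5,
                     occurrence = c(0.5, 0.1, 0.5, 0.1, 0.1))
  expect_equal(select_peptide_segment(tie2, 0.25)$start, 1)

  expect_error(select_peptide_segment(
    data.frame(resno = 1:3, occurrence = rep(0.1, 3)), 0.25), "no-segment")

  # randomized agreement with exhaustive enumeration
  set.seed(13)
  for (k in 1:25) {
    occ <- round(runif(12), 2)
    if (!any(occ > 0.25)) next
    got <- select_peptide_segment(data.frame(resno = 1:12, occurrence = occ),
                                  0.25)
    want <- brute_segment(1:12, occ, 0.25)
    expect_equal(c(got$start, got$end), c(want$s, want$e))
  }
})

test_that("gap tolerance merges short below-threshold interruptions", {
  prof <- data.frame(resno = 1:7,
                     occurrence = c(0.5, 0.5, 0.1, 0.5, 0.5, 0.5, 0.1))
  strict <- select_peptide_segment(prof, 0.25)
  expect_equal(strict$length, 3)
  merged <- select_peptide_segment(prof, 0.25, max_gap = 1)
  expect_equal(c(merged$start, merged$end), c(1, 6))
})

test_that("segment and per-residue vdW fractions are row-sum ratios", {
  st <- assign_parameters(make_toy_dimer(5, 6))
  E <- interface_lj_matrix(st, "A", "B")
  frac <- segment_vdw_fraction(E, 2:3)
  rows <- attr(E, "rows")
  want <- sum(E[rows$resno %in% 2:3, ]) / sum(E)
  expect_equal(frac, want, tolerance = 1e-12)
  expect_equal(segment_vdw_fraction(E, 1:5), 1)
  # complement partition
  expect_equal(frac + segment_vdw_fraction(E, c(1, 4, 5)), 1,
               tolerance = 1e-12)
  # per-residue shares sum to 1
  shares <- vapply(1:5, function(r) per_residue_vdw_share(E, r), numeric(1))
  expect_equal(sum(shares), 1, tolerance = 1e-12)
  # zero-total guard
  E0 <- E; E0[] <- 0
  expect_error(segment_vdw_fraction(E0, 2), "zero total")
})

test_that("RMSD follows its closed forms and superposition never hurts", {
  st <- subset_chains(make_toy_dimer(6, 6), "A")
  expect_equal(rmsd(st, st), 0)
  # uniform translation by d
  d <- c(1.2, -2.3, 0.7)
  tr <- rigid_transform(st, diag(3), d)
  expect_equal(rmsd(tr, st), sqrt(sum(d^2)), tolerance = 1e-9)
  expect_lt(rmsd(tr, st, superpose = TRUE), 1e-9)
  # one displaced atom of N
  one <- st
  one$atom$x[4] <- one$atom$x[4] + 3
  expect_equal(rmsd(one, st), 3 / sqrt(nrow(st$atom)), tolerance = 1e-9)
  # superposed never exceeds unfitted
  set.seed(8)
  jit <- st
  jit$atom$x <- jit$atom$x + rnorm(nrow(st$atom), sd = 0.3)
  jit <- rigid_transform(jit, rotz(0.4), c(2, 0, -1))
  expect_lte(rmsd(jit, st, superpose = TRUE), rmsd(jit, st))
  # atom mismatch errors
  other <- subset_chains(make_toy_dimer(7, 6), "A")
  expect_error(rmsd(other, st), "correspondence")
})

test_that("edge-to-edge distance matches hand geometry", {
  # 16 collinear CAs spaced 3.8 A
  lines <- vapply(1:16, function(i)
    pdb_atom_line(i, "CA", "ALA", "A", i, 3.8 * (i - 1), 0, 0), "")
  st <- read_structure(lines)
  expect_equal(edge_to_edge(st, 1:16, "A"), 15 * 3.8, tolerance = 1e-9)
  # rigid-motion invariance
  rot <- rigid_transform(st, rotz(1.1), c(5, -3, 2))
  expect_equal(edge_to_edge(rot, 1:16, "A"), 15 * 3.8, tolerance = 1e-9)
  # folded-back hairpin: only the terminal CAs matter
  hp <- read_structure(c(pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
                         pdb_atom_line(2, "CA", "ALA", "A", 2, 20, 0, 0),
                         pdb_atom_line(3, "CA", "ALA", "A", 3, 5, 0, 0)))
  expect_equal(edge_to_edge(hp, 1:3, "A"), 5)
})

test_that("extension intervals use the population sd and count occupancy", {
  s <- c(1, 1, 1, 3, 3, 3)
  ei <- extension_interval(s, 1)
  expect_equal(ei$mean, 2)
  expect_equal(ei$sd, 1)
  expect_equal(ei$occupancy, 1)
  # k = 0 degenerates to the fraction exactly at the mean
  ei0 <- extension_interval(c(1, 2, 2, 3), 0)
  expect_equal(ei0$occupancy, 0.5)
  # Gaussian coverage at 2 sigma
  set.seed(99)
  g <- rnorm(1e5, 10, 2)
  expect_equal(extension_interval(g, 2)$occupancy, 0.954, tolerance = 0.01)
  # external interval occupancy
  eix <- extension_interval(s, 1, interval = c(0, 1.5))
  expect_equal(eix$external_occupancy, 0.5)
  expect_warning(extension_interval(c(2, 2, 2), 1), "constant")
})

test_that("MSA frequencies are gap-aware and column-normalized", {
  msa <- c(ref = "AC-DE", s2 = "ACGDE", s3 = "ACGD-")
  fr <- msa_position_frequencies(msa, c(1, 3), "ref")
  expect_equal(fr[["1"]][["A"]], 1)
  expect_equal(fr[["3"]][["D"]], 1)
  # mixed column with a gap: {A, A, T, -} -> A 2/3, T 1/3
  msa2 <- c(r = "GA", a = "GA", b = "GT", c = "G-")
  fr2 <- msa_position_frequencies(msa2, 2, "r")
  expect_equal(fr2[["2"]][["A"]], 2 / 3)
  expect_equal(fr2[["2"]][["T"]], 1 / 3)
  expect_equal(sum(fr2[["2"]]), 1)
  expect_error(msa_position_frequencies(msa, 10, "ref"), "index error")
  expect_error(msa_position_frequencies(msa, 1, "nope"), "not found")
  # aligned FASTA file input through Biostrings
  tmp <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ref", "AC-DE", ">s2", "ACGDE", ">s3", "ACGD-"), tmp)
  fr3 <- msa_position_frequencies(tmp, 1, "ref")
  expect_equal(fr3[["1"]][["A"]], 1)
})
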