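# Mutation proposals, side-chain placement, cost function, Metropolis
# acceptance, chain driver, candidate filtering.

test_that("mutation proposals are uniform and never propose the current residue", {
  seq16 <- rep("A", 16)
  set.seed(1)
  draws <- replicate(2e4, propose_mutation(seq16)$position)
  tab <- tabulate(draws, 16)
  expect_gt(chisq.test(tab)$p.value, 0.01)
  set.seed(2)
  residues <- replicate(500, propose_mutation(seq16)$residue)
  expect_false(any(residues == "A"))
  expect_false(any(residues == "C"))  # default alphabet excludes CYS
  # fixed seed reproduces the proposal stream
  set.seed(42); p1 <- replicate(50, unlist(propose_mutation(seq16)))
  set.seed(42); p2 <- replicate(50, unlist(propose_mutation(seq16)))
  expect_identical(p1, p2)
  expect_error(propose_mutation(c("A"), alphabet = "A"), "no-move")
})

test_that("side-chain placement preserves the backbone and the template", {
  pep <- assign_parameters(subset_chains(make_toy_dimer(6, 6), "A"))
  bb0 <- pep$atom[pep$atom$resno == 3 &
                    pep$atom$elety %in% c("N", "CA", "C", "O"),
                  c("x", "y", "z")]
  # X -> GLY removes the side chain
  pg <- place_side_chain(pep, "A", 3, "G")
  expect_equal(sort(pg$atom$elety[pg$atom$resno == 3 & pg$atom$chain == "A"]),
               sort(c("N", "CA", "C", "O")))
  # ALA -> ALA is idempotent on the heavy-atom set
  pa <- place_side_chain(pep, "A", 3, "A")
  expect_setequal(pa$atom$elety[pa$atom$resno == 3 & pa$atom$chain == "A"],
                  c("N", "CA", "C", "O", "CB"))
  # ALA -> VAL keeps CB and grows CG1/CG2 nearby with ideal bond lengths
  pv <- place_side_chain(pep, "A", 3, "V")
  sel <- pv$atom$resno == 3 & pv$atom$chain == "A"
  expect_setequal(pv$atom$elety[sel],
                  c("N", "CA", "C", "O", "CB", "CG1", "CG2"))
  cb <- unlist(pv$atom[sel & pv$atom$elety == "CB", c("x", "y", "z")])
  for (a in c("CG1", "CG2")) {
    p <- unlist(pv$atom[sel & pv$atom$elety == a, c("x", "y", "z")])
    expect_lt(sqrt(sum((p - cb)^2)), 2.0)
  }
  bb1 <- pv$atom[sel & pv$atom$elety %in% c("N", "CA", "C", "O"),
                 c("x", "y", "z")]
  expect_lt(max(abs(as.matrix(bb0) - as.matrix(bb1))), 1e-6)
  # rebuilt residues are parameterized and carry the new residue's charge
  expect_false(anyNA(pv$atom$charge))
  expect_equal(sum(pg$atom$charge[pg$atom$resno == 3 & pg$atom$chain == "A"]),
               0, tolerance = 1e-9)
})

test_that("cost deltas combine the four weighted terms", {
  w <- cost_weights(10, 0.04, 32.1, 0.5)
  old <- list(Z_d = 1.0, E_c = 10, H_d = 0.10, M = 2)
  new <- list(Z_d = 1.2, E_c = 0, H_d = 0.15, M = 2)
  # mutation term vanishes at equal M
  expect_equal(cost_delta(old, new, w),
               10 * 0.2 + 0.04 * (-10) + 32.1 * 0.05, tolerance = 1e-12)
  expect_equal(cost_delta(old, old, w), 0)
  # improving every physical term lowers the cost
  better <- list(Z_d = 0.9, E_c = 5, H_d = 0.05, M = 2)
  expect_lt(cost_delta(old, better, w), 0)
  # default penalty: D * (M_new - M_old) * M_new^2
  up <- list(Z_d = 1.0, E_c = 10, H_d = 0.10, M = 3)
  expect_equal(cost_delta(old, up, w), 0.5 * 1 * 9)
  expect_equal(cost_delta(up, old, w), 0.5 * (-1) * 4)
  # literal cubic alternative
  expect_equal(cost_delta(old, up, w, penalty = "cubic"), 0.5 * 1)
})

test_that("Metropolis acceptance is certain downhill and Boltzmann uphill", {
  expect_true(metropolis_accept(-1, 1))
  # boundary: exp(0) = 1 accepts with certainty
  set.seed(3)
  expect_true(all(replicate(100, metropolis_accept(0, 1))))
  set.seed(4)
  rate <- mean(replicate(2e4, metropolis_accept(log(2), 1)))
  expect_equal(rate, 0.5, tolerance = 0.02)
})

test_that("the chain driver logs every proposal and is reproducible", {
  pep <- assign_parameters(subset_chains(make_toy_dimer(8, 6), "A"))
  stub <- make_stub_scorer()
  r <- run_chain(pep, "A", stub, n_steps = 100, seed = 11)
  expect_equal(nrow(r$steps), 100)
  expect_equal(r$accepted$sequence[1], paste(rep("A", 8), collapse = ""))
  # state advances only on acceptance
  expect_equal(nrow(r$accepted), sum(r$steps$accepted) + 1)
  # determinism
  r2 <- run_chain(pep, "A", stub, n_steps = 100, seed = 11)
  expect_identical(r$accepted$sequence, r2$accepted$sequence)
  expect_identical(r$steps$dCf, r2$steps$dCf)
  # acceptance bookkeeping satisfies the Metropolis invariant
  up <- r$steps[r$steps$accepted & r$steps$dCf >= 0, ]
  if (nrow(up)) expect_true(all(up$draw <= exp(-up$dCf)))
})

test_that("an always-worsening scorer under large beta accepts nothing", {
  pep <- assign_parameters(subset_chains(make_toy_dimer(6, 6), "A"))
  worse <- local({
    calls <- 0
    list(evaluate = function(structure, sequence) {
      calls <<- calls + 1
      list(Z_d = calls, E_c = 0, H_d = 0)  # +10 cost per proposal at A = 10
    }, needs_structure = FALSE)
  })
  r <- run_chain(pep, "A", worse, cost_weights(beta = 50),
                 n_steps = 200, seed = 2)
  expect_equal(sum(r$steps$accepted), 0)
  expect_equal(r$final_sequence, paste(rep("A", 6), collapse = ""))
})

test_that("mutation counts equal the Hamming distance at every step", {
  pep <- assign_parameters(subset_chains(make_toy_dimer(8, 6), "A"))
  r <- run_chain(pep, "A", make_stub_scorer(), n_steps = 400, seed = 6)
  orig <- strsplit(r$accepted$sequence[1], "")[[1]]
  for (k in seq_len(nrow(r$accepted))) {
    s <- strsplit(r$accepted$sequence[k], "")[[1]]
    expect_identical(sum(s != orig), as.integer(r$accepted$M[k]))
  }
})

test_that("two-state occupancy matches the Boltzmann ratio", {
  # direct Metropolis dynamics on a toy landscape: state B costs dC more
  dC <- 0.8; beta <- 1
  set.seed(17)
  state <- 0L  # 0 = low-cost A, 1 = high-cost B
  visits <- integer(2)
  for (i in 1:2e4) {
    delta <- if (state == 0L) dC else -dC
    if (metropolis_accept(delta, beta)) state <- 1L - state
    visits[state + 1L] <- visits[state + 1L] + 1L
  }
  ratio <- visits[2] / visits[1]
  se <- 3 * sqrt(1 / visits[2] + 1 / visits[1]) * ratio
  expect_lt(abs(ratio - exp(-beta * dC)), max(se, 0.05))
})

test_that("candidate filtering ranks by physicochemical cost with dedup", {
  w <- cost_weights()
  mk <- function(seqs, Z, E, H, M) structure(list(accepted = data.frame(
    sequence = seqs, Z_d = Z, E_c = E, H_d = H, M = M,
    stringsAsFactors = FALSE)), class = "mc_run")
  r1 <- mk(c("AAAA", "AAAV", "AAVV", "AVVV"), c(1, 0.5, 0.8, 0.2),
           c(0, -10, 5, 0), c(0, 0.01, -0.1, 0), c(0, 1, 2, 3))
  # a state beyond the mutation cap is dropped
  r2 <- mk("VVVVVV6", 0, -100, -1, 6)
  cand <- filter_candidates(list(r1, r2), w, max_mutations = 5, top_k = 10)
  expect_false("VVVVVV6" %in% cand$sequence)
  # ranking equals the brute-force sort of A Z + B E + C H
  pool <- r1$accepted
  cost <- w$A * pool$Z_d + w$B * pool$E_c + w$C * pool$H_d
  expect_equal(cand$sequence, pool$sequence[order(cost, pool$sequence)])
  expect_equal(cand$cost, sort(cost))
  # duplicates keep their best-scoring record
  r3 <- mk(c("AAAV", "AAAV"), c(0.5, 0.1), c(-10, -10), c(0.01, 0.01),
           c(1, 1))
  cand3 <- filter_candidates(r3, w, top_k = 5)
  expect_equal(nrow(cand3), 1)
  expect_equal(cand3$Z_d, 0.1)
  expect_warning(out <- filter_candidates(mk("X", 0, 0, 0, 9), w),
                 "no candidate")
  expect_equal(nrow(out), 0)
})

test_that("mutability profiles tally per-position differences", {
  orig <- "AAAA"
  cands <- c("AAAA", "AVAA", "AVAD", "AAAD")
  mp <- mutability_profile(cands, orig)
  expect_equal(mp$mutation_counts, c(0, 2, 0, 2))
  expect_equal(unname(mp$residue_frequencies["V", 2]), 0.5)
  expect_equal(colSums(mp$residue_frequencies), rep(1, 4),
               ignore_attr = TRUE)
  # brute-force tally
  mat <- do.call(rbind, strsplit(cands, ""))
  expect_equal(mp$mutation_counts,
               as.integer(colSums(mat != matrix(strsplit(orig, "")[[1]],
                                                4, 4, byrow = TRUE))))
  expect_error(mutability_profile("AAA", orig), "shape error")
})

test_that("the structure scorer is exactly invariant under translation", {
  d <- assign_parameters(make_toy_dimer(5, 6))
  ev <- function(st) {
    sc <- make_surface_scorer(subset_chains(st, "B"), subset_chains(st, "A"),
                              grid_size = 32, order = 8)
    unlist(sc$evaluate(subset_chains(st, "A"), rep("A", 5)))
  }
  m0 <- ev(d)
  expect_true(all(is.finite(m0)))
  m1 <- ev(rigid_transform(d, diag(3), c(4.2, -1.3, 9.9)))
  expect_lt(max(abs(m1 - m0)), 1e-9)
  # rotation: Coulomb and hydropathy exactly invariant; the shape term is
  # stable only up to surface-lattice resampling
  m2 <- ev(rigid_transform(d, rotz(0.6)))
  expect_lt(max(abs(m2[c("E_c", "H_d")] - m0[c("E_c", "H_d")])), 1e-9)
  expect_lt(abs(m2[["Z_d"]] - m0[["Z_d"]]), 0.2 * max(abs(m0[["Z_d"]]), 0.1))
})
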