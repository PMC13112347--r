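# Metropolis Monte Carlo mutagenesis engine: mutation proposal, side-chain
# placement, composite cost (shape complementarity + coarse-grained Coulomb
# + hydropathy + mutation penalty), acceptance, run management and
# candidate filtering.

# default proposal alphabet: the standard residues minus cysteine
# (disulfide risk); configurable in all entry points
.default_alphabet <- setdiff(names(.aa_three), "C")

#' Cost-function weights and inverse temperature
#'
#' Defaults A = 10, B = 0.04, C = 32.1, D = 0.5 balance the magnitudes of
#' the shape, Coulomb, hydropathy and mutation terms; beta is the inverse
#' temperature of the Metropolis acceptance in cost units.
#'
#' @param A,B,C,D Term weights (shape, Coulomb, hydropathy, mutation).
#' @param beta Inverse temperature (> 0).
#' @return A `cost_weights` list.
#' @export
cost_weights <- function(A = 10, B = 0.04, C = 32.1, D = 0.5, beta = 1) {
  stopifnot(is.finite(c(A, B, C, D, beta)), beta > 0)
  structure(list(A = A, B = B, C = C, D = D, beta = beta),
            class = "cost_weights")
}

#' Propose a single random mutation
#'
#' Draws a position uniformly over the sequence and a replacement residue
#' uniformly over the alphabet minus the current residue, from R's RNG
#' stream (seed with `set.seed()` for reproducibility).
#'
#' @param sequence Character vector of 1-letter residues.
#' @param alphabet Candidate residues (1-letter).
#' @return List with `position` and `residue`.
#' @export
propose_mutation <- function(sequence, alphabet = .default_alphabet) {
  pos <- sample.int(length(sequence), 1)
  choices <- setdiff(alphabet, sequence[pos])
  if (!length(choices))
    stop("no-move error: alphabet offers no residue different from '",
         sequence[pos], "'")
  list(position = pos, residue = choices[sample.int(length(choices), 1)])
}

#' @keywords internal
.unit <- function(v) v / sqrt(sum(v^2))

#' @keywords internal
.naive_sidechain_positions <- function(N, CA, C, res3) {
  tree <- .sidechain_tree[[res3]]
  if (is.null(tree)) return(NULL)
  b1 <- .unit(N - CA); b2 <- .unit(C - CA)
  bis <- .unit(b1 + b2)
  perp <- .unit(c(b1[2] * b2[3] - b1[3] * b2[2],
                  b1[3] * b2[1] - b1[1] * b2[3],
                  b1[1] * b2[2] - b1[2] * b2[1]))
  dir_cb <- .unit(perp * sqrt(2 / 3) - bis * sqrt(1 / 3))
  pos <- list(CA = CA, CB = CA + 1.53 * dir_cb)
  parent_of <- stats::setNames(tree[, 2], tree[, 1])
  parent_of["CB"] <- "CA"
  sibling_rank <- stats::setNames(stats::ave(seq_len(nrow(tree)), tree[, 2],
                                             FUN = seq_along), tree[, 1])
  for (k in seq_len(nrow(tree))) {
    atom <- tree[k, 1]; parent <- tree[k, 2]
    if (atom == "CB") next
    gp <- parent_of[[parent]]
    gp_pos <- if (gp == "CA" && parent == "CB") CA else pos[[gp]]
    dbase <- .unit(pos[[parent]] - gp_pos)
    ref <- if (abs(dbase[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
    w1 <- .unit(c(dbase[2] * ref[3] - dbase[3] * ref[2],
                  dbase[3] * ref[1] - dbase[1] * ref[3],
                  dbase[1] * ref[2] - dbase[2] * ref[1]))
    w2 <- c(dbase[2] * w1[3] - dbase[3] * w1[2],
            dbase[3] * w1[1] - dbase[1] * w1[3],
            dbase[1] * w1[2] - dbase[2] * w1[1])
    g <- 2 * pi * (sibling_rank[[atom]] - 1) / 3 + 0.3
    d <- .unit(cos(70.5 * pi / 180) * dbase +
                 sin(70.5 * pi / 180) * (cos(g) * w1 + sin(g) * w2))
    len <- if (grepl("^S", atom) || grepl("^S", parent)) 1.82 else 1.52
    pos[[atom]] <- pos[[parent]] + len * d
  }
  do.call(rbind, pos[tree[, 1]])
}

#' Replace a residue's side chain for a new residue type
#'
#' Backbone atoms are left untouched; side-chain atoms are removed and
#' rebuilt from the new residue's heavy-atom template by the built-in naive
#' placer (ideal-geometry growth along the CA->CB direction, fixed bond
#' lengths and tetrahedral angles, no rotamer search or relaxation).  An
#' external placer (e.g. a SCWRL adapter) can be substituted via `placer`:
#' a function `(N, CA, C, res3) -> matrix` of side-chain atom positions with
#' the template's row order.
#'
#' @param structure A `chain_structure`.
#' @param chain Chain id of the residue.
#' @param resno Residue number.
#' @param new_residue New residue type (1- or 3-letter code).
#' @param table Parameter table used to parameterize the rebuilt residue.
#' @param placer Side-chain coordinate generator (default: naive internal).
#' @return The mutated `chain_structure`.
#' @export
place_side_chain <- function(structure, chain, resno, new_residue,
                             table = load_parameter_table(),
                             placer = .naive_sidechain_positions) {
  res3 <- aa_three_letter(new_residue)
  at <- structure$atom
  rows <- which(at$chain == chain & at$resno == resno)
  if (!length(rows)) stop("residue ", chain, " ", resno, " not found")
  bb_rows <- rows[at$elety[rows] %in% .backbone_atoms]
  need <- c("N", "CA", "C")
  if (!all(need %in% at$elety[bb_rows]))
    stop("malformed residue: need N, CA, C backbone atoms to place a ",
         "side chain")
  getp <- function(nm) unlist(at[bb_rows[match(nm, at$elety[bb_rows])],
                                 c("x", "y", "z")], use.names = FALSE)
  sc_xyz <- placer(getp("N"), getp("CA"), getp("C"), res3)
  bb <- at[bb_rows, , drop = FALSE]
  bb$resid <- res3
  new_rows <- bb[0, ]
  if (!is.null(sc_xyz)) {
    new_rows <- bb[rep(1, nrow(sc_xyz)), , drop = FALSE]
    new_rows$elety <- rownames(sc_xyz)
    new_rows$x <- sc_xyz[, 1]; new_rows$y <- sc_xyz[, 2]
    new_rows$z <- sc_xyz[, 3]
  }
  res_at <- rbind(bb, new_rows)
  # re-parameterize the rebuilt residue from the table
  tkey <- paste(table$residue, table$atom)
  idx <- match(paste(res_at$resid, res_at$elety), tkey)
  if (anyNA(idx))
    stop("no parameter entry for rebuilt atom(s): ",
         paste(res_at$elety[is.na(idx)], collapse = ", "))
  res_at$epsilon <- table$epsilon[idx]
  res_at$rmin_half <- table$rmin_half[idx]
  res_at$charge <- table$charge[idx]
  before <- at[seq_len(min(rows) - 1), , drop = FALSE]
  after <- if (max(rows) < nrow(at)) at[(max(rows) + 1):nrow(at), , drop = FALSE]
  else at[0, ]
  out <- rbind(before, res_at, after)
  out$eleno <- seq_len(nrow(out))
  new_chain_structure(out, structure$model_id)
}

#' Deterministic stub metric provider for driver testing
#'
#' Maps a sequence to fake but reproducible (Z_d, E_c, H_d) metrics without
#' touching any structure, so the Monte Carlo driver can be exercised at
#' full scale in seconds.
#'
#' @return A scorer: list with `evaluate(structure, sequence)` and
#'   `needs_structure = FALSE`.
#' @export
make_stub_scorer <- function() {
  kd <- load_hydropathy_scale()
  code <- stats::setNames(seq_along(.aa_three), names(.aa_three))
  list(
    evaluate = function(structure, sequence) {
      v <- code[sequence]
      list(Z_d = mean(v) / 20,
           E_c = sum((v - 10.5)^2) / length(v) - 33,
           H_d = mean(kd[aa_three_letter(sequence)]) / 4.5)
    },
    needs_structure = FALSE)
}

#' Structure-based scorer for peptide-target complementarity
#'
#' Precomputes the target-side quantities once (surface patch invariants
#' with normals "up", interface coarse-grained beads, fixed-side
#' hydropathy) and evaluates each peptide pose against them: Z_d is the
#' descriptor distance between the target patch and the peptide patch
#' projected with the opposite ("normals down") orientation convention,
#' E_c the coarse-grained Coulomb energy between the peptide beads and the
#' target interface beads, and H_d = H_fixed - H_mut.
#'
#' @param target Parameterized `chain_structure` of the target protein.
#' @param peptide Parameterized `chain_structure` of the peptide in its
#'   bound pose (shared coordinate frame with `target`).
#' @param patch_radius Patch region radius, Angstrom.
#' @param order,grid_size Zernike expansion order and disk resolution.
#' @param density,probe_radius Surface sampling parameters.
#' @param contact_cutoff CA-CA cutoff defining target interface residues.
#' @param dielectric Relative dielectric for the Coulomb term.
#' @param scale Hydropathy scale.
#' @return A scorer: list with `evaluate(structure, sequence)`,
#'   `needs_structure = TRUE`, and the cached target quantities.
#' @export
make_surface_scorer <- function(target, peptide, patch_radius = 9,
                                order = 20, grid_size = 64, density = 5,
                                probe_radius = 1.4, contact_cutoff = 8,
                                dielectric = 1,
                                scale = load_hydropathy_scale()) {
  pep_ca <- peptide$atom[peptide$atom$elety == "CA", c("x", "y", "z")]
  pep_centroid <- colMeans(as.matrix(pep_ca))
  cloud_t <- compute_sas_points(target, density, probe_radius)
  patch_t <- extract_patch(cloud_t, pep_centroid, patch_radius)
  inv_t <- patch_invariants(patch_t, order = order, grid_size = grid_size,
                            flip = FALSE)
  h_fixed <- patch_hydropathy(patch_t, target, scale)$value
  # target interface residues by CA-CA cutoff against the peptide pose
  tca <- target$atom[target$atom$elety == "CA", , drop = FALSE]
  d2 <- outer(rowSums(as.matrix(tca[, c("x", "y", "z")])^2),
              rowSums(as.matrix(pep_ca)^2), "+") -
    2 * as.matrix(tca[, c("x", "y", "z")]) %*% t(as.matrix(pep_ca))
  near <- rowSums(d2 < contact_cutoff^2) > 0
  if (!any(near)) stop("no target residues within the contact cutoff of ",
                       "the peptide pose")
  keep_key <- paste(tca$chain[near], tca$resno[near])
  sel <- paste(target$atom$chain, target$atom$resno) %in% keep_key
  cg_t <- coarse_grain(new_chain_structure(
    target$atom[sel, , drop = FALSE], target$model_id))
  patch_center <- patch_t$center
  list(
    evaluate = function(structure, sequence) {
      cloud_p <- compute_sas_points(structure, density, probe_radius)
      patch_p <- extract_patch(cloud_p, patch_center, patch_radius)
      inv_p <- patch_invariants(patch_p, order = order,
                                grid_size = grid_size, flip = TRUE)
      cg_p <- coarse_grain(structure)
      list(Z_d = descriptor_distance(inv_t, inv_p),
           E_c = coulomb_energy_cg(cg_p, cg_t, dielectric),
           H_d = h_fixed - patch_hydropathy(patch_p, structure, scale)$value)
    },
    needs_structure = TRUE,
    target_invariants = inv_t, target_cg = cg_t, h_fixed = h_fixed,
    patch_center = patch_center)
}

#' Cost-function difference between two states
#'
#' Delta C_f = A dZ + B dE_c + C dH + mutation term.  The default mutation
#' term is D * (M_new - M_old) * M_new^2 (signed step, quadratically
#' growing with mutational load); `penalty = "cubic"` selects the literal
#' alternative D * (M_new - M_old)^3.
#'
#' @param old,new Lists with `Z_d`, `E_c`, `H_d` and mutation count `M`.
#' @param weights A `cost_weights`.
#' @param penalty "signed_quadratic" (default) or "cubic".
#' @return Scalar Delta C_f.
#' @export
cost_delta <- function(old, new, weights = cost_weights(),
                       penalty = c("signed_quadratic", "cubic")) {
  penalty <- match.arg(penalty)
  dm <- new$M - old$M
  mut <- if (penalty == "signed_quadratic") weights$D * dm * new$M^2
  else weights$D * dm^3
  weights$A * (new$Z_d - old$Z_d) + weights$B * (new$E_c - old$E_c) +
    weights$C * (new$H_d - old$H_d) + mut
}

#' Physicochemical cost of a state (no mutation term)
#' @param metrics List with `Z_d`, `E_c`, `H_d` (or a data.frame).
#' @param weights A `cost_weights`.
#' @return A * Z_d + B * E_c + C * H_d.
#' @export
physicochemical_cost <- function(metrics, weights = cost_weights()) {
  weights$A * metrics$Z_d + weights$B * metrics$E_c + weights$C * metrics$H_d
}

#' Metropolis acceptance rule
#'
#' Accept always when Delta C_f < 0; otherwise accept with probability
#' exp(-beta * Delta C_f), using one uniform draw from R's RNG stream.
#'
#' @param delta Cost difference Delta C_f.
#' @param beta Inverse temperature (> 0).
#' @return Logical: accepted.
#' @export
metropolis_accept <- function(delta, beta = 1) {
  stopifnot(beta > 0)
  if (delta < 0) TRUE else stats::runif(1) <= exp(-beta * delta)
}

#' One Metropolis Monte Carlo mutagenesis chain
#'
#' Runs `n_steps` single-mutation proposals from the initial peptide,
#' scoring each proposal with `scorer`, forming Delta C_f via
#' [cost_delta()] and accepting by the Metropolis rule.  Every proposal is
#' logged with its full cost breakdown; the state advances only on
#' acceptance.  Fully reproducible under (`seed`, configuration).
#'
#' @param peptide Initial peptide `chain_structure` (parameterized when the
#'   scorer needs structures).
#' @param chain Chain id of the peptide within its structure.
#' @param scorer A scorer from [make_surface_scorer()] or
#'   [make_stub_scorer()].
#' @param weights A `cost_weights`.
#' @param n_steps Number of proposals.
#' @param seed RNG seed for this chain.
#' @param alphabet Proposal alphabet (1-letter codes).
#' @param penalty Mutation-term variant, see [cost_delta()].
#' @param table Parameter table for side-chain rebuilding.
#' @return An `mc_run`: list with `seed`, `steps` (one row per proposal:
#'   position, residue, dZ, dEc, dH, dM_term, dCf, accepted, draw),
#'   `accepted` (state log including the initial state: sequence, Z_d, E_c,
#'   H_d, M), `initial`, `final_sequence`, `acceptance_rate`.
#' @export
run_chain <- function(peptide, chain, scorer, weights = cost_weights(),
                      n_steps = 6000, seed = 1,
                      alphabet = .default_alphabet,
                      penalty = c("signed_quadratic", "cubic"),
                      table = load_parameter_table()) {
  penalty <- match.arg(penalty)
  set.seed(seed)
  res <- residue_table(peptide)
  res <- res[res$chain == chain, , drop = FALSE]
  if (!nrow(res)) stop("chain id not present: ", chain)
  seq0 <- aa_one_letter(res$resid)
  L <- length(seq0)
  state <- list(sequence = seq0, structure = peptide, M = 0L)
  state$metrics <- scorer$evaluate(peptide, seq0)
  rec <- list(step = seq_len(n_steps), position = integer(n_steps),
              residue = character(n_steps), dZ = numeric(n_steps),
              dEc = numeric(n_steps), dH = numeric(n_steps),
              dM_term = numeric(n_steps), dCf = numeric(n_steps),
              accepted = logical(n_steps), draw = rep(NA_real_, n_steps))
  acc_seq <- character(n_steps + 1); acc_Z <- acc_E <- acc_H <-
    numeric(n_steps + 1); acc_M <- integer(n_steps + 1)
  acc_seq[1] <- paste(seq0, collapse = "")
  acc_Z[1] <- state$metrics$Z_d; acc_E[1] <- state$metrics$E_c
  acc_H[1] <- state$metrics$H_d; acc_M[1] <- 0L
  n_acc <- 1L
  for (s in seq_len(n_steps)) {
    mv <- propose_mutation(state$sequence, alphabet)
    trial_seq <- state$sequence
    trial_seq[mv$position] <- mv$residue
    trial_struct <- state$structure
    if (isTRUE(scorer$needs_structure))
      trial_struct <- place_side_chain(trial_struct, chain,
                                       res$resno[mv$position], mv$residue,
                                       table = table)
    trial_metrics <- scorer$evaluate(trial_struct, trial_seq)
    M_new <- sum(trial_seq != seq0)
    old <- c(state$metrics, M = state$M)
    new <- c(trial_metrics, M = M_new)
    dM_term <- cost_delta(list(Z_d = 0, E_c = 0, H_d = 0, M = state$M),
                          list(Z_d = 0, E_c = 0, H_d = 0, M = M_new),
                          weights, penalty)
    dCf <- cost_delta(old, new, weights, penalty)
    if (dCf < 0) {
      accepted <- TRUE; draw <- NA_real_
    } else {
      draw <- stats::runif(1)
      accepted <- draw <= exp(-weights$beta * dCf)
    }
    rec$position[s] <- mv$position; rec$residue[s] <- mv$residue
    rec$dZ[s] <- trial_metrics$Z_d - state$metrics$Z_d
    rec$dEc[s] <- trial_metrics$E_c - state$metrics$E_c
    rec$dH[s] <- trial_metrics$H_d - state$metrics$H_d
    rec$dM_term[s] <- dM_term; rec$dCf[s] <- dCf
    rec$accepted[s] <- accepted; rec$draw[s] <- draw
    if (accepted) {
      state <- list(sequence = trial_seq, structure = trial_struct,
                    M = M_new, metrics = trial_metrics)
      n_acc <- n_acc + 1L
      acc_seq[n_acc] <- paste(trial_seq, collapse = "")
      acc_Z[n_acc] <- trial_metrics$Z_d; acc_E[n_acc] <- trial_metrics$E_c
      acc_H[n_acc] <- trial_metrics$H_d; acc_M[n_acc] <- M_new
    }
  }
  keep <- seq_len(n_acc)
  structure(list(
    seed = seed, n_steps = n_steps,
    steps = as.data.frame(rec, stringsAsFactors = FALSE),
    accepted = data.frame(sequence = acc_seq[keep], Z_d = acc_Z[keep],
                          E_c = acc_E[keep], H_d = acc_H[keep],
                          M = acc_M[keep], stringsAsFactors = FALSE),
    initial = list(sequence = paste(seq0, collapse = ""),
                   metrics = c(list(), acc_Z = acc_Z[1], acc_E = acc_E[1],
                               acc_H = acc_H[1])),
    final_sequence = paste(state$sequence, collapse = ""),
    acceptance_rate = mean(rec$accepted)),
    class = "mc_run")
}

#' @export
print.mc_run <- function(x, ...) {
  cat("<mc_run> seed", x$seed, "-", x$n_steps, "steps, acceptance rate",
      format(x$acceptance_rate, digits = 3), "\n")
  invisible(x)
}

#' Filter and rank candidate sequences from Monte Carlo runs
#'
#' Pools the state logs of all runs, drops sequences with more than
#' `max_mutations` differences from the original, deduplicates (keeping the
#' best-scoring record of each sequence), ranks ascending by the
#' physicochemical cost A Z_d + B E_c + C H_d (no mutation term;
#' deterministic tie-break by sequence) and returns the first `top_k`.
#'
#' @param runs List of `mc_run` objects (or a single one).
#' @param weights A `cost_weights`.
#' @param max_mutations Maximum allowed mutations (default 5).
#' @param top_k Number of candidates returned (default 100).
#' @return data.frame: sequence, M, Z_d, E_c, H_d, cost.
#' @export
filter_candidates <- function(runs, weights = cost_weights(),
                              max_mutations = 5, top_k = 100) {
  if (inherits(runs, "mc_run")) runs <- list(runs)
  pool <- do.call(rbind, lapply(runs, `[[`, "accepted"))
  pool <- pool[pool$M <= max_mutations, , drop = FALSE]
  if (!nrow(pool)) {
    warning("no candidate survives the mutation filter")
    return(pool)
  }
  pool$cost <- weights$A * pool$Z_d + weights$B * pool$E_c +
    weights$C * pool$H_d
  pool <- pool[order(pool$cost, pool$sequence), , drop = FALSE]
  pool <- pool[!duplicated(pool$sequence), , drop = FALSE]
  out <- utils::head(pool[, c("sequence", "M", "Z_d", "E_c", "H_d", "cost")],
                     top_k)
  rownames(out) <- NULL
  out
}

#' Per-position mutability of a candidate set
#'
#' For each position: how many candidates differ from the original residue,
#' and the frequency of each residue observed there.
#'
#' @param candidates Character vector of sequences, or a data.frame with a
#'   `sequence` column (as from [filter_candidates()]).
#' @param original Original sequence (string or character vector).
#' @return List with integer vector `mutation_counts` (length L) and a
#'   residue-by-position frequency matrix `residue_frequencies`.
#' @export
mutability_profile <- function(candidates, original) {
  seqs <- if (is.data.frame(candidates)) candidates$sequence else candidates
  orig <- if (length(original) == 1) strsplit(original, "")[[1]] else original
  mat <- do.call(rbind, strsplit(seqs, ""))
  if (ncol(mat) != length(orig))
    stop("shape error: candidate length differs from the original sequence")
  counts <- colSums(mat != matrix(orig, nrow(mat), length(orig), byrow = TRUE))
  freqs <- apply(mat, 2, function(col) {
    tab <- table(factor(col, levels = names(.aa_three)))
    as.numeric(tab) / length(col)
  })
  rownames(freqs) <- names(.aa_three)
  list(mutation_counts = as.integer(counts), residue_frequencies = freqs)
}
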