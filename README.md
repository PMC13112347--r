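# pepmc

Interface-guided peptide design by Metropolis Monte Carlo mutagenesis,
scored with 2D Zernike shape descriptors, coarse-grained electrostatics and
surface hydropathy.

## The problem

A recurring strategy for inhibiting a pathological protein–protein
association — for example the self-association of an amyloidogenic
antibody light chain into a homodimer — is to excise the piece of one
partner that dominates the interface and optimize it into a standalone
peptide that outcompetes the full-length partner. `pepmc` implements that
whole workflow for structural bioinformaticians:

1. **Interface characterization.** From trajectory frames (multi-model
   PDB), residues are called "interface" when their Cα lies within a
   cutoff (default 8 Å, strict) of any partner-chain Cα. Per-residue
   *contact occurrence* is the fraction of frames in contact; residue-pair
   van der Waals energies are 12–6 Lennard-Jones sums
   E = ε_lm[(R_lm/r)¹² − 2(R_lm/r)⁶] over inter-chain atom pairs.
2. **Template extraction.** The peptide template is the longest contiguous
   run of residues whose occurrence exceeds a threshold (default 25%).
3. **Sequence optimization.** Single-residue mutations are proposed
   uniformly at random, rebuilt with a side-chain placer, and accepted by
   the Metropolis rule P = min(1, e^(−βΔC_f)) on the composite cost

   ΔC_f = A·ΔZ + B·ΔE_c + C·ΔH + D·(M_new − M_old)·M_new²

   with Z the Euclidean distance between rotation-invariant 2D Zernike
   descriptors of the two facing surface patches (shape complementarity),
   E_c the Coulomb energy of a 2-bead-per-residue coarse-grained model,
   H the hydropathy mismatch of the facing patches, and M the mutation
   count. Default weights A = 10, B = 0.04, C = 32.1, D = 0.5.
4. **Candidate filtering.** Accepted sequences with at most 5 mutations
   are deduplicated and ranked by the physicochemical cost
   A·Z_d + B·E_c + C·H_d; the top 100 are reported.

The shape descriptors come from projecting a solvent-accessible-surface
patch (point cloud with outward normals, default 5 points/Å², 1.4 Å probe)
onto the unit disk: the patch is reoriented so its mean normal is the
z-axis, viewed from an apex chosen so the widest secant cone is 45°, binned
into a square grid of mean secant lengths, and expanded in the orthogonal
Zernike basis Z_nm = R_nm(r)e^{imϕ} up to order N = 20 (121 coefficients);
the moduli |c_nm| are rotation-invariant. Facing patches are projected with
opposite orientation conventions so that small descriptor distance means
complementarity, not similarity.

Everything runs offline: a synthetic-fixtures module generates toy dimers,
trajectories with prescribed contact occupancy, and analytic disk images,
so every stage is testable without downloads or external binaries
(DMS/SCWRL adapters exist for users who have them).

## Worked example

```r
library(pepmc)

# a toy dimer whose chain-A residues 5..12 touch chain B in 80% of frames
dimer <- make_toy_dimer(n_res = 16, separation = 6)
occ <- rep(0.1, 16); occ[5:12] <- 0.8
traj <- make_synthetic_trajectory(dimer, occ, n_frames = 100, seed = 1)

prof <- contact_occurrence(traj, "A", "B", cutoff = 8)
seg <- select_peptide_segment(prof, threshold = 0.25)
seg
#> <segment_selection> residues 5 - 12 (length 8 ), mean occurrence 0.8

st <- assign_parameters(dimer)
E <- interface_lj_matrix(st, "A", "B")
segment_vdw_fraction(E, seg)
#> [1] 0.52

# optimize a 6-residue peptide against its partner chain
d6 <- assign_parameters(make_toy_dimer(6, 6))
scorer <- make_surface_scorer(subset_chains(d6, "B"), subset_chains(d6, "A"))
w <- cost_weights()                      # A = 10, B = 0.04, C = 32.1, D = 0.5
runs <- lapply(1:2, function(k)
  run_chain(subset_chains(d6, "A"), "A", scorer, w, n_steps = 100, seed = k))
head(filter_candidates(runs, w, max_mutations = 5, top_k = 10), 3)
#>   sequence M   Z_d  E_c   H_d  cost
#> 1   IIIVIA 5 0.477 10.5 -2.54 -76.3
#> 2   AIIVIA 4 0.477 10.4 -2.33 -69.7
#> 3   AIIVVI 5 0.429 10.6 -2.29 -68.8
```

The selected segment reproduces the planted contact block exactly; it
carries 52% of the toy interface's Lennard-Jones energy (its 8 of 16
residues sit at the contact line). In the optimization, the best candidate
drops the physicochemical cost from 4.98 (the unmutated template) to
−76.3, mostly by raising hydropathy complementarity (ΔH term) while
staying within the 5-mutation cap.

A thin command-line wrapper is shipped at `inst/cli/pepmc.R`
(`Rscript pepmc.R extract-peptide --input frames.pdb --out outdir`, also
`surface`, `optimize --stub-scorer`, `msa-freqs`, `fixtures`, ...); each
run writes its artifacts plus a provenance JSON (package version, seed,
config hash).

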