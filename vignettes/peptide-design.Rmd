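---
title: "Interface-guided peptide design: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface-guided peptide design: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepmc)
```

`pepmc` designs peptide inhibitors of a protein–protein association in
three stages: it characterizes the interface from trajectory frames,
excises the contiguous segment that dominates the contact statistics, and
optimizes that segment's sequence by Metropolis Monte Carlo against a
composite physicochemical cost. This vignette is the package's account of
the underlying models, the tunable parameters, and the numerical decisions
taken where the design was genuinely open. It states no empirical result
that the test suite and `scripts/acceptance.R` do not themselves compute.

## Interface statistics

A residue is an *interface residue* in a frame when its Cα lies strictly
within `contact_cutoff` (default 8 Å) of any partner-chain Cα; *contact
occurrence* is the fraction of frames in which this holds
(`contact_occurrence()`). The Cα rule is used for contact statistics; for
energy-context queries the minimum inter-atom distance is the natural
alternative and residue-pair energies are computed from all atom pairs
regardless of any distance rule.

Residue-pair van der Waals energies use the 12–6 Lennard-Jones form

$$E^{LJ}_{lm} = \epsilon_{lm}\left[\left(\frac{R_{lm}}{r_{lm}}\right)^{12}
 - 2\left(\frac{R_{lm}}{r_{lm}}\right)^{6}\right],$$

summed over all inter-chain atom pairs of the two residues
(`residue_pair_lj()`, `interface_lj_matrix()`). Per-atom parameters are
combined as $\epsilon_{lm} = \sqrt{\epsilon_l\epsilon_m}$ and
$R_{lm} = R^{min}_l/2 + R^{min}_m/2$, the convention of the CHARMM family
of force fields from which such parameters are customarily drawn. A
strict-literal mode (`combining = "literal"`, plain product of the well
depths) is available for comparison, since the pair-energy formula is
sometimes printed with the product form; the combination rule matters only
as an overall per-pair scale. No distance cutoff is applied by default —
the double sum is cheap at interface scale and a cutoff would bias the
fraction statistics.

`segment_vdw_fraction()` and `per_residue_vdw_share()` use **signed** sums
(favorable and unfavorable contributions cancel); this is the
interpretation under which the shares over all residues partition to 1.
`extension_interval()` summarizes a per-frame distance series as
mean ± k·sd with the **population** standard deviation: the frames are
treated as the full analyzed population, and at hundreds of frames the
distinction from the sample estimator is negligible anyway.
`rmsd()` is by default the literal unfitted deviation
$\sqrt{N^{-1}\sum_i |r_i - r^0_i|^2}$; `superpose = TRUE` applies a
least-squares Kabsch fit first, and the fitted value can never exceed the
unfitted one.

## Template extraction

`select_peptide_segment()` returns, among maximal contiguous runs of
residues whose occurrence strictly exceeds `occurrence_threshold`
(default 0.25), the longest; ties break by higher mean occurrence, then by
smaller start index. The strict reading (every member above threshold) is
the testable one; a `max_gap` option can forgive short interruptions but
defaults to 0. On trajectories generated with a planted high-occupancy
block this rule recovers the block exactly (50/50 seeded instances in the
acceptance suite).

## Surface patches and the disk projection

`compute_sas_points()` samples each atom's probe-inflated sphere
(vdW radius + `probe_radius`, default 1.4 Å) on a deterministic Fibonacci
lattice at `density` points/Å² (default 5) and discards points buried in
any neighbour's inflated sphere; normals are radial. This is equivalent in
semantics to the classic DMS point/normal output, and `read_dms_points()`
lets a real DMS run substitute bit-for-bit. Only the solvent-accessible
surface is produced — no Connolly re-entrant surface.

A *patch* is the set of cloud points within `patch_radius` (default 9 Å, a
residue-centred binding-site scale) of a surface point
(`extract_patch()`). `reorient_patch()` applies the rigid rotation taking
the patch's mean normal onto +z (or −z with `flip = TRUE`) and recenters
on the centroid. `fit_apex_point()` places the viewpoint C = (0, 0, h) by
bisection so that the largest angle between the z-axis and any secant from
C to a patch point is 45°; the maximal secant angle is strictly decreasing
in h, so the root is unique (for a flat disk of radius ρ the closed form
is h = ρ/tan θ). `project_to_disk()` then bins each point by the unit-disk
coordinates $(\sin\alpha/\sin\theta_{max})(\cos\phi, \sin\phi)$ — α the
secant's angle to the axis, ϕ its azimuth — so the rim of the 45° cone is
the unit circle, and stores per pixel the mean secant length r. Binning by
secant direction (rather than by raw xy coordinates) is what makes the
disk domain exactly the basis domain of the expansion below. Defaults:
`grid_size = 64`, which resolves order-20 polynomials with margin.

Two policies make the pixel function well-defined everywhere: empty
in-disk pixels are filled by one pass of 8-neighbour means (then the patch
mean), and before expansion the image is normalized to zero mean and unit
maximum absolute value within the disk (`normalize_disk_image()`), making
descriptor distances comparable across patches of different depth. For
complementarity scoring the target patch is projected with normals "up"
and the peptide patch with normals "down" (`flip = TRUE`): facing,
complementary shapes then produce *small* descriptor distances.

## 2D Zernike descriptors

The disk image is expanded in the orthogonal basis
$Z_{nm}(r,\phi) = R_{nm}(r)e^{im\phi}$ with coefficients
$c_{nm} = \frac{n+1}{\pi}\langle Z_{nm}|f\rangle$ for
$0 \le m \le n \le N$, $(n-m)$ even. Only $m \ge 0$ is stored — for real
images the moduli of ±m coincide — which gives 121 coefficients at the
default N = 20. The invariant descriptor is the vector of moduli
$z_{nm} = |c_{nm}|$, unchanged by rotations about the disk center, and two
patches are compared by the Euclidean distance of their invariant vectors
(`descriptor_distance()`).

Numerical choices. The image is piecewise constant on pixels, so the inner
product is computed as $\sum_p f_p \int_{\text{pixel}_p \cap D} Z^*_{nm}\,dA$:
the per-pixel basis integrals are evaluated once per (grid, order) by 8×8
sub-pixel midpoint sampling clipped to the disk, plus an exact-area rim
correction (the area difference between the true pixel/disk overlap —
computed from the closed-form circle–rectangle intersection — and its
jagged subsampled version is assigned the basis value on the rim, where
$R_{nm}(1) = 1$). This keeps the numerical Gram matrix within $10^{-3}$
relative of the analytic $\frac{\pi}{n+1}\delta_{nn'}\delta_{mm'}$ on a
256² grid for all $n \le 10$, which the acceptance suite verifies. The
cached per-pixel basis makes repeated expansions (one per Monte Carlo
step) a single small matrix product.

Riemann quadrature of any flavour cannot reproduce a band-limited image to
machine precision, so `zernike_expand()` also offers
`method = "least_squares"`, the exact discrete projection onto the basis
evaluated at pixel centers; band-limited images round-trip through it at
~10⁻¹⁵ RMS, and the test suite uses it wherever an exactness oracle is
wanted while the quadrature route is tested at its own
pixelization-limited accuracy (relative errors of order 10⁻³–10⁻²).
Reconstruction from the stored $m \ge 0$ coefficients uses conjugate-pair
completion, $f = \mathrm{Re}[\sum_{m=0} c\,Z + 2\sum_{m>0} c\,Z]$; the
half-range sum alone cannot represent a real image.

Invariants are *not* additionally normalized (e.g. by $z_{00}$) before
distances: the image normalization above already fixes the scale, and a
second normalization would discard the patch's mean-depth information.

## Electrostatics and hydropathy

For the Coulomb term the structure is reduced to two beads per residue
(`coarse_grain()`): a backbone bead (atoms N, CA, C, O and terminal/H
variants) and a side-chain bead (everything else), each at the unweighted
mean of its atoms' positions and carrying the sum of their partial
charges, so total charge is conserved exactly. Glycine has no side-chain
heavy atoms and yields only the backbone bead, which absorbs the whole
residue charge — the alternative (an empty-set mean) is undefined. The
coarse-graining is deliberate: mutant side chains come from a placer
without relaxation, and bead-averaged positions forgive the resulting
local geometry errors that would dominate an all-atom Coulomb sum.
`coulomb_energy_cg()` is then $k_e/\varepsilon \sum q_aq_b/r_{ab}$ over
inter-model bead pairs, $k_e = 332.0636$ kcal·Å/(mol·e²), vacuum
dielectric $\varepsilon = 1$ by default (the coarse-grained charges are
not pre-screened; users modelling solvated interfaces can raise it). Only
the target's interface residues (by the Cα cutoff against the peptide
pose) enter the cached target-side bead set — the term scores the facing
interfaces, not the whole protein.

Patch hydropathy (`patch_hydropathy()`) assigns every surface point to the
residue of its nearest heavy atom (error beyond 5 Å) and averages the
residues' hydropathy indices with surface-point weights; the cost term is
the signed difference H_fixed − H_mut between the target and peptide
patches. The shipped default scale is Kyte–Doolittle; the scale is a
plain two-column file and fully substitutable, so analyses that depend on
a custom surface-derived scale are scale-relative by construction.

Partial charges and LJ parameters come from a **synthetic** simplified
parameter table shipped with the package
(`inst/extdata/atom_params_synthetic.tsv`): element-class LJ parameters
and partial charges constructed so each residue sums exactly to its formal
charge. It exists so the pipeline is reproducible offline with integer
residue charges; for production work, substitute a real force-field export
via `load_parameter_table(path)` and/or PQR charges
(`assign_parameters(..., pqr = read_pqr(...))`, which take precedence).

## The Monte Carlo engine

Each step proposes one mutation: position uniform over the peptide,
replacement uniform over the alphabet minus the current residue. The
default alphabet is the 19 standard residues excluding cysteine (to avoid
spurious disulfides); proline is allowed. The mutated side chain is built
by the internal naive placer — ideal-geometry template growth along the
CA→CB direction with fixed bond lengths and tetrahedral branching, no
rotamer search, no relaxation — chosen to keep the package self-contained;
an external rotamer-based placer (e.g. a SCWRL wrapper) can be injected
through the `placer` argument of `place_side_chain()`. The coarse-grained
Coulomb term above is the designed mitigation for unrelaxed side chains.

The cost difference is
$\Delta C_f = A\,\Delta Z + B\,\Delta E_c + C\,\Delta H + D\,(M_{new}-M_{old})\,M_{new}^2$
with defaults A = 10, B = 0.04, C = 32.1, D = 0.5 — magnitudes chosen so
the four terms are comparable. The mutation term as printed in the
protocol's compact form leaves the exact algebra open; the implemented
default is direction-signed and grows quadratically with the mutational
load, so drifting far from the original sequence costs progressively more,
which matches the term's stated purpose. A literal cubic alternative
$D(M_{new}-M_{old})^3$ is selectable (`penalty = "cubic"`). Acceptance is
standard Metropolis, always downhill and $e^{-\beta\Delta C_f}$ uphill.
β is not fixed by the protocol; the default is 1 in cost units, and
`mc_run$acceptance_rate` is reported so users can tune toward the usual
20–50% regime. Candidate filtering ranks by the physicochemical cost
alone (no mutation term), keeps sequences with at most `max_mutations`
(default 5) and returns the `top_k` (default 100) after deduplication;
the chain's state log includes the initial (unmutated) state, which is a
legitimate 0-mutation candidate.

Per step only the peptide's surface and bead model are recomputed; the
target-side patch invariants, interface beads and fixed-side hydropathy
are cached at scorer construction. The optimization acts on the peptide
posed in the complex frame — patches are taken where the two surfaces
face each other — matching the template's provenance as an excised
interface segment.

## Synthetic fixtures and what the tests do (and do not) show

The fixture generators are first-class, deterministic code:
`make_toy_dimer()` (two parallel poly-alanine chains with idealized local
geometry; poly-ALA is the smallest residue exercising both beads),
`make_synthetic_trajectory()` (each chain-A residue displaced out of
contact range in a seeded subset of frames sized `round(occ * n_frames)`,
so scheduled occupancies are realized exactly), analytic disk images
(constant, single Zernike modes, Gaussian bumps) and smooth random
band-limited images with spectral decay $(n+1)^{-1.5}$ — the smoothness
class that projected surface patches actually inhabit.

These fixtures validate the machinery (counting rules, quadrature,
acceptance logic, filtering) exactly, but they are geometric, not
biological: no real side-chain packing, no conformational fluctuation
beyond the scheduled displacements, flat idealized interfaces. Passing
tests therefore demonstrate correctness of the implemented statistics and
optimization, not that a designed peptide will bind a real light chain;
applying the pipeline to real systems additionally needs genuine MD
frames, real force-field parameters and a validated hydropathy scale.

One further documented limitation: the surface sampler's Fibonacci
lattice is axis-aligned in the lab frame, so while all energetic and
hydropathy scores are exactly invariant under rigid translation (and
Coulomb/hydropathy under rotation too), the shape-descriptor term is
rotation-stable only up to surface resampling noise (of order a few
percent on toy patches). Descriptor *comparisons* are always made within
one frame, where this cancels.

## Problem sizes used in the shipped checks

The test and acceptance runs use toy scales chosen to exercise every code
path with comfortable margins: 16-residue peptides for driver-scale runs
(10 chains × 6000 stub-scored steps = 60,000 logged proposals), 30-residue
chains × 20–40 frames for the statistics oracles, order 10 on a 256² grid
for the orthogonality audit, and a 6-residue dimer for the end-to-end
optimization with the real scorers (10 chains × 200 steps). The same code
paths run unchanged at production scale; only wall-clock time grows.
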