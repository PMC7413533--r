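---
title: "Methods: conformational-ensemble analysis of an allosteric regulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational-ensemble analysis of an allosteric regulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allodyn)
```

# Scope

`allodyn` implements the analysis stack used to dissect how an allosteric
effector (zinc, in the motivating system — a MarR-family zinc-uptake
repressor that binds operator DNA only when its two recognition helices
close to ~30 Å) redistributes a homodimer's conformational ensemble:

1. the accelerated-MD (aMD) dual-boost mathematics;
2. two-dimensional potential-of-mean-force (PMF) landscapes over a
   domain-RMSD × inter-helix-distance coordinate pair, with basin
   detection and representative-structure extraction;
3. dynamic cross-correlation matrices (DCCM) of Cα fluctuations;
4. dynamical community networks on occupancy-filtered Cα contact graphs;
5. a census of protein–DNA hydrogen bonds, ionic interactions and
   hydrophobic contacts.

Running all-atom solvated MD is out of scope: the package analyses
trajectories, and ships a coarse-grained dimer generator with planted
ground truth so that every stage can be validated end to end without
external data.

# The aMD dual-boost model

When the instantaneous potential `V` falls below a threshold `E_thresh`,
aMD adds a boost

$$\Delta V = \frac{(E_{thresh}-V)^2}{E_{thresh}-V+\alpha},$$

and propagates `V* = V + ΔV`; at or above the threshold the potential is
untouched. `modified_potential()` is strictly increasing in `V` (the
energy ordering of conformations is preserved), bounded by `E_thresh` on
the boosted branch, and approaches `E_thresh − α` as `V → −∞`; raising
`E_thresh` or lowering `α` can only increase the boost. The dual-boost
parameter recipe (`dual_boost_parameters()`) sets, in kcal/mol,
`α_P = 0.16·N_atoms` and `E_threshP = ⟨E_tot⟩ + α_P` for the total
potential, and `α_D = (4/5)·N_residues`,
`E_threshD = ⟨E_dih⟩ + 4·N_residues` for the dihedral term.

Boosted sampling distorts Boltzmann weights; `reweight_frames()` provides
the standard exponential reweighting `w ∝ exp(ΔV/k_BT)` (with a max-shift
overflow guard). Landscapes are computed from raw frames by default — the
procedure the package mirrors histograms aMD frames directly — and
reweighting is a deliberate opt-in via the `weights` argument of
`pmf_2d()`.

# Landscapes

`pmf_2d()` bins the two reaction coordinates on a 30×30 grid of
equal-width bins (the grid resolution of the motivating study; both the
count and the ranges are arguments — explicit ranges let landscapes of
different systems share axes), normalises to a joint probability
`g(x,y)`, and reports `ΔG = −k_B T ln g`, shifted so the lowest occupied
bin is zero, with `k_B = 0.0019872041` kcal·mol⁻¹·K⁻¹ and `T` defaulting
to 300 K. Empty bins are undefined rather than infinite. Because the
estimate is a plain histogram, free-energy differences between bins are
exact functions of the counts — the tests exploit
`ΔG₁−ΔG₂ = −k_BT ln(n₁/n₂)` directly.

A *basin* is an occupied bin strictly lower than all of its occupied
8-neighbours; undefined neighbours count as infinitely high and ties
disqualify. Two consequences are worth knowing. First, the definition is
shift-invariant. Second, on sparsely sampled surfaces isolated occupied
bins at the rim of the populated region are trivially strict minima, so
`find_basins()` can return shallow spurious basins along with the
physical ones; they carry high `ΔG` and rank last. The deepest basin on
each side of a barrier is the meaningful summary, and that is what the
recovery tests assert.

`representative_frame()` reproduces the usual representative-structure
protocol: frames of a basin are clustered by average-linkage hierarchical
clustering on pairwise DNA-binding-domain Cα RMSD, the tree is cut at
half its maximum merge height, and the medoid of the largest cluster is
returned. Basins with thousands of members are thinned deterministically
(every k-th frame, cap 120) before the quadratic-cost clustering.

Reaction coordinates: `domain_rmsd()` superposes the DNA-binding-domain
Cα atoms of both chains, pooled, onto the same atoms of the reference
structure (Kabsch, proper rotation only) and reports the post-fit RMSD
over that identical atom set — fitting and reporting on the same set is
the least ambiguous reading of a "domain RMSD", and pooling the chains
treats the dimer as one rigid unit. `interhelix_distance()` is the plain
Euclidean distance between the probe residue's Cα on the two protein
chains (residue 71 by default, the recognition-helix probe of the
motivating system). Secondary-structure ranges are never hard-coded: they
come from a `region_config()`/YAML file, because author-numbering ranges
are annotation-dependent.

# DCCM and the dynamical network

`dccm()` superposes all frames onto the iteratively recomputed mean
structure (fit–average–refit until the mean moves < 1e-6 Å), then

$$C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j\rangle}
{\sqrt{\langle|\Delta r_i|^2\rangle\,\langle|\Delta r_j|^2\rangle}},$$

with `Δr_i(t) = r_i(t) − ⟨r_i⟩`. The whole dimer is fitted as one body
(per-chain fitting would silently delete the inter-chain anticorrelation
that is the scientific signal; a caller who wants per-chain fitting can
pass a one-chain selection). An atom with zero total fluctuation makes
`C` undefined and is reported by name. `threshold_for_display()`
implements the usual display rule — |C| < 0.3 neglected (zeroed) — and is
never used in network construction.

The dynamical network has one node per residue (its Cα) and an edge
wherever the minimum heavy-atom inter-residue distance is ≤ 4.5 Å in at
least 75% of frames (`contact_edges()`; a Cα–Cα mode is available, and
same-chain sequence neighbours i,i±1 are excluded by default so
trivially persistent backbone contacts do not dominate — both
configurable). Edges are weighted `w = −log|C_ij|`, the standard choice
that makes strongly correlated contacts short; `|C|` is clamped to
[1e-6, 1−1e-12] so weights stay finite and positive. All-pairs optimal
paths come from a Floyd–Warshall pass with strict-improvement updates
and intermediates scanned in ascending index order, which fixes one
canonical optimal path per pair deterministically; edge betweenness is
the number of canonical paths through the edge (co-optimal path
ensembles are deliberately not enumerated — path degeneracy would make
betweenness non-deterministic). Disconnected pairs contribute nothing.

`girvan_newman_communities()` removes the highest-betweenness edge
(lexicographic tie-break), recomputes betweenness, and scores every
intermediate component partition by Newman–Girvan modularity on the
*original, unweighted* contact graph, returning the maximum. Communities
with fewer than 3 residues are marked discarded: they keep their labels
but are excluded from `community_connectivity()`, which scores each pair
of surviving communities by the maximum betweenness over their bridging
edges (the "bond width" statistic of community diagrams).

One documented consequence of path-based betweenness: an extremely weak
(high-weight) edge in a triangle is bypassed even by its own endpoint
pair and carries betweenness 0; a moderately weak edge that is still
cheaper than the detour carries exactly 1.

# The interaction census

The motivating literature names the categories but no geometry, so the
package fixes explicit, configurable defaults
(`interaction_criteria()`): hydrogen bonds as donor/acceptor heavy-atom
pairs across the protein/DNA interface at ≤ 3.5 Å, with a D–H···A angle
≥ 120° enforced only when hydrogens exist (crystal structures usually
lack them, so detection degrades to distance-only); ionic interactions
as Lys/Arg/His side-chain nitrogens within 4.0 Å of phosphate-backbone
oxygens; hydrophobic contacts as apolar side-chain carbons within 4.5 Å
of deoxyribose/base carbons, aggregated to one record per residue pair
at the closest approach. Donor/acceptor classes come from a built-in
table covering the 20 amino acids and DNA. Every report embeds the
criteria used, because the counts are criteria-dependent by
construction. Counts are invariant under rigid motion and monotone under
cutoff tightening — both property-tested.

# The synthetic dimer generator

`build_dimer_model()` emulates the two-chain regulator at one bead per
residue: each chain is a stack of compact bead blocks (3-D grids, 3.0 Å
spacing) — one planted contact community per block — cross-linked by
stiff springs (10 kcal·mol⁻¹·Å⁻²) and connected by single backbone
springs; the final block of each chain is the "recognition helix", and
the distance `d` between the two helix centroids moves on a quartic
double well with analytically known minima `d1 < d2`, barrier height,
and an optional linear tilt `delta_g` that sets the well free-energy
difference exactly (`doublewell_energy()` / `doublewell_reference()`).
Defaults: wells at 24 and 32 Å (closed, binding-competent ~30 Å scale vs
open), barrier 4 kcal/mol — a slow conformational switch.

Three restraints keep the toy model's noise structure honest, and they
were each added for a reason worth recording:

* free-floating chains undergo unbounded rotational diffusion, which
  swamps the planted correlation signs — beads outside the helix blocks
  therefore carry weak (0.5 kcal·mol⁻¹·Å⁻²) 3-D positional tethers,
  mimicking the orientational confinement of a folded dimer;
* helix beads are tethered only transverse to the separation axis, so
  the reaction coordinate itself is unrestrained and its equilibrium
  density is exactly `p(d) ∝ exp(−U(d)/k_BT)` (an effectively 1-D
  coordinate — the reference used by all recovery tests);
* the *symmetric* translation of the two helix groups (their midpoint
  along the axis) is restrained (20 kcal·mol⁻¹·Å⁻²); without it that
  near-free mode correlates the two helices positively and masks the
  planted antiphase motion. The antisymmetric mode — `d` itself — is
  untouched by construction.

`simulate_dimer()` integrates overdamped (position) Langevin dynamics by
Euler–Maruyama: `dx = F/γ·dt + √(2k_BT·dt/γ)·N(0,1)`. There are no
masses; the stationary distribution is Boltzmann for any friction, so
`γ` (default 0.2 ps⁻¹, i.e. D = k_BT/γ ≈ 3 Å²/ps) is chosen purely so
the well-exchange dynamics decorrelate within desk-scale runs. The
default time step 0.002 ps keeps the stiffest spring modes well inside
the Euler stability limit (`k·dt/γ ≪ 2`); single-block models with few
springs tolerate 0.005 ps, which the statistical tests use for speed.
Euler discretisation inflates the variance of a mode with stiffness `k`
by `2/(2−k·dt/γ)`; at the defaults this is ≤ ~15% on the stiffest
intra-block modes and negligible on the reaction coordinate, which is
why contact-occupancy margins were built at 3.0 Å spacing (rest
diagonals 4.24 Å against the 4.5 Å cutoff). Blocks of fewer than 8 beads
placed on a planar grid have a soft out-of-plane flexing mode (distance
springs resist bending only at second order); models used for
quantitative recovery therefore use 8-bead braced-cube blocks. The seed
is mandatory, trajectories are bitwise reproducible, and the caller's
RNG state is restored.

When a boost is supplied, the double-well term is propagated on the aMD
modified potential: its force is scaled by `(α/(E_thresh−U+α))²` below
the threshold (`boost_force_scale()`, the exact derivative of `V*`).
This is the package's working demonstration of the boost mathematics —
the deep 4 kcal/mol barrier (~6.7 k_BT) traps plain dynamics, while a
boost with `E_thresh = 5, α = 1` reduces the effective barrier to
~0.3 kcal/mol.

What the generator does *not* emulate: solvent and hydrodynamics,
side-chain packing, secondary-structure geometry, sequence-specific
energetics, and any real protein force field. Passing tests demonstrate
that the analysis stages recover planted truth from data with realistic
statistical structure (correlated noise, two-state exchange,
occupancy-fluctuating contacts); they are not evidence about any real
protein.

# Problem sizes and statistical checks

The statistical tests run at sizes chosen for adequate sampling:

* *Landscape recovery*: single-block dimer (8 beads/chain), barrier
  1.0 kcal/mol, tilt 0.5 kcal/mol, 2×10⁵ steps of 0.005 ps (1 ns),
  giving ~10–15 well crossings. Asserted: deepest basin on each side
  within one bin of the analytic minima; basin free-energy gap within 3
  block-bootstrap standard errors of the analytic gap; well populations
  within 3 autocorrelation-corrected standard errors of the Boltzmann
  ratio. `bootstrap_basin_gap()` sizes its blocks at five times the
  integrated autocorrelation time of the slower coordinate (capped at a
  tenth of the series) — blocks shorter than the well-exchange
  correlation time understate the error, which early development runs
  made very visible.
* *Correlation signs*: the 80-bead default layout with the barrier
  lowered to 1.2 kcal/mol so the antiphase helix motion has
  well-crossing amplitude; 3×10⁴ steps.
* *Community recovery*: default layout, 4×10³ steps; the planted blocks
  are geometrically separated, so the expected partition is exact
  (adjusted Rand index 1).
* *Boost demonstration*: 20 replicate pairs (boosted vs plain, equal
  seeds) of 6×10⁴ steps on the single-block model; boosted runs must
  show strictly more hysteresis-counted well crossings in ≥95% of
  pairs. `count_well_crossings()` uses a margin of a quarter of the well
  separation so barrier-top jitter never counts.

# Numerical and design choices

* The PMF sign: probability maxima must be free-energy minima with the
  minimum shifted to zero, hence `ΔG = −k_BT ln g`.
* Kabsch superposition is computed from the SVD of the cross-covariance
  with a determinant correction (proper rotations only); degenerate
  (collinear) point sets are rejected.
* `read_structure()` keeps author residue numbering untouched, takes the
  first model only, and resolves altlocs by highest occupancy, ties to
  `A`. Multi-model files are trajectories, not structures. Malformed
  ATOM records are reported with their line number.
* DCD output is single-precision CHARMM dialect (hence ~1e-3 Å
  round-trip tolerance in the tests); hydrogens, if present, are kept
  and used only where they matter (H-bond angles).
* All clustering/bootstrap randomness flows from explicit seeds;
  pipeline outputs are byte-identical across reruns, and the manifest
  records parameters, package version and input checksums but no
  timestamps, precisely so reruns stay identical.

# Known limitations

* Crystal-structure checks (the probe-residue distances of the deposited
  zinc states: 44.2/42.7/32.5 Å) need the PDB entries 5YI1/5YHY/5YHX,
  which are not redistributable with the package; place them under
  `inst/extdata/pdb/` to activate that test. Whether those printed
  distances are exactly the A71–A71′ Cα metric or a helix-centroid
  metric can only be settled against the files themselves;
  `structure_interhelix_distance()` computes the former.
* Betweenness counts one canonical path per pair; studies wanting
  co-optimal path ensembles need a different tool.
* The histogram PMF has no smoothing or kernel option, by design; rim
  bins can be spurious strict minima (see above).
* The interaction census ignores water-mediated bridges, pi-stacking and
  energetic scoring; it is a geometric census.
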