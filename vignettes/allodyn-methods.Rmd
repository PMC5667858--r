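---
title: "AlloDyn: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AlloDyn: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

AlloDyn chains five analyses that together profile how cooperative a
two-lobe protein fold is: coarse-grained discrete molecular dynamics,
elastic-network and principal-component analysis, perturbation–response
scanning, coupling-weighted residue interaction networks, and pebble-game
rigidity analysis. This vignette explains each model, the parameters that
matter, the numerical choices, and what the synthetic test systems do and do
not establish about real proteins.

## The square-well Gō model and event-driven dynamics

Each residue is a unit-mass Cα bead. Pairs interact through infinite square
wells around their native distance r⁰: the separation is confined to
[(1−σ)r⁰, (1+σ)r⁰]. Bonded neighbours use σ = 0.05 (keeping the virtual bond
near its 3.8 Å equilibrium); non-consecutive pairs within r_c = 8 Å in the
native structure are native contacts with σ = 0.1. All other pairs see only
a hard core, d_hc = 4.0 Å — a value we chose as slightly above the closest
non-contact approach in compact Cα traces; tethered pairs whose inner wall
lies below d_hc keep their own inner wall as the core. Because the wells are
infinite, native contacts never break: the model probes fluctuations *about*
the fold, not unfolding.

Between collisions particles move ballistically, so the simulation is a
sorted sequence of wall-crossing events (no forces, no timestep error). The
engine (compiled, `src/dmd_engine.cpp`) keeps a binary-heap event queue with
per-particle collision counters for lazy invalidation; ties in event time
break on the smaller pair index. After each reflection the pair is nudged
1 nÅ (10⁻⁹ Å) inside its wall so the same crossing is not re-detected; this
is three orders of magnitude below the 10⁻⁶ Å tolerance at which we declare
a wall violated. Units are reduced (k_B = 1, mass = 1, lengths in Å); no
energy scale exists because all wells are infinite.

Temperature control is an Andersen-style thermostat: ghost events at rate
ν per particle resample one particle's velocity from Maxwell–Boltzmann at T.
Published precedent for temperature control in square-well DMD is thin;
we picked Andersen because it is exactly canonical, local,
and leaves kinetic energy strictly conserved *between* ghost events — which
the engine verifies (drift below 10⁻⁹ relative is asserted in the tests).
All randomness flows through R's RNG, so `set.seed` gives bit-identical
trajectories. Snapshots are taken every 1000 events by default (event-count
cadence is robust across densities; time cadence is not).

## Elastic network, mobility, hinges, PCA

The Kirchhoff matrix Γ has Γ_ij = −1 for Cα pairs within r_c = 7.0 Å and
degree on the diagonal; the spring constant is uniform (its absolute value
cancels from every normalized profile). Mobility over the m slowest nonzero
modes is ⟨M_i⟩ = Σ_k λ_k⁻¹[u^(k)]_i² / Σ_k λ_k⁻¹; with orthonormal modes it
sums to one over residues. Zero modes (one per connected component, detected
at 10⁻⁸·λ_max) are excluded. Hinges are local minima of the profile within a
±2-residue window that also fall below the 25th percentile — the window and
percentile are our choices (no published criterion exists); both are
arguments of `identifyHinges`.

PCA runs on the Cα coordinates of the ensemble after two rounds of
mean-structure superposition (mean, fit, re-mean, re-fit — cheap and stable;
one round leaves a small residual rigid-body component). The per-residue
displacement profile over the first three components is eigenvalue-weighted,
D_i = Σ_{k≤3} λ_k‖(v_k)_i‖² / Σ_{k≤3} λ_k, normalized to sum to one. Whether
to weight by eigenvalue is genuinely open; we weight because the unweighted
version lets a negligible third component distort the profile.

## Perturbation–response scanning

With the GNM Laplacian as a scalar Hessian, the response to a unit force at
residue i is column i of the pseudo-inverse Γ⁺ (computed over nonzero
modes; a disconnected graph is rejected because the pseudo-inverse is then
ambiguous across components). The PRS map is S_ij = (Γ⁺_ij)², row i =
perturbed site. Effector profiles are row means with the diagonal excluded —
self-response is not propagation. The scalar-network formulation makes the
directional force averaging of Hessian-based PRS implicit.

Two variants exist because the literature splits: the raw (symmetric) map,
and a row-normalized map S̃_ij = S_ij/S_ii. Raw row means track overall
mobility, so chain termini dominate them; the normalized map measures
propagation *relative to self-response* and peaks in well-connected cores,
which is what "mediating hotspot" narratives refer to. The default is the
raw variant (it keeps effector ≡ sensor); the hotspot property test and the
acceptance summary use `normalized = TRUE` for the reason above.

## Conservation, mutual information, generalized correlation

KL conservation per column is Σ_a P(a) ln(P(a)/Q(a)) in nats, gaps excluded,
with an optional additive pseudocount. The background Q defaults to bundled
Swiss-Prot amino-acid frequencies and is configurable; a fully conserved
column against a uniform background scores ln 20 ≈ 3.00 exactly. (Printed
forms of this score sometimes omit the leading P(a); we implement the
standard KL divergence.)

Column MI uses pairwise-complete rows (both columns ungapped), with marginals
recomputed per pair; pairs with fewer than 10 complete rows are NA. The
plug-in MI estimator is biased upward by ≈(R−1)(C−1)/(2n) — about 0.036 nats
for a 20×20 table at n = 5000, which would swamp weak couplings — so the
Miller–Madow correction (subtract the bias, floor at zero) is applied by
default; a perfectly coupled 2-state pair loses only 10⁻⁴ nats to it.
Sequence weighting (1/cluster-size at 62 % identity) is on by default but is
O(n²) in sequences — for the i.i.d. synthetic alignments it is a no-op and
the acceptance script disables it. APC correction is available and off by
default.

Dynamic coupling uses the Gaussian estimator: per-residue fluctuation
vectors (3-D, after superposition) give MI_ij = ½ ln[det C_i det C_j /
det C_ij] from 3×3/6×6 covariance blocks and r_MI = √(1 − e^(−2·MI/3)),
clipped to [0, 1]. For a pair correlated with ρ on each axis this returns ρ
exactly, which the tests exploit. The Gaussian estimator was chosen over
k-NN because it is deterministic and has closed-form oracles; it
underestimates MI for strongly nonlinear couplings. Edge lengths are
w = −ln max(r, 10⁻⁴); the floor keeps fully uncoupled edges finite
(w ≈ 9.21) rather than infinite. How to blend sequence MI with dynamic r_MI
into one weight is not settled; the default uses dynamic r_MI only.

## Residue interaction networks, paths, communities

Default construction is `ca_contact`: an edge exists in a frame when the Cα
distance is ≤ 7.5 Å; edges present in ≥ 50 % of frames are kept, and their
occupancy is reported. An atom-level mode scores interaction strength
I_ij = 100·n_ij/√(N_i N_j) (side-chain heavy-atom pairs within 4.5 Å, with a
bundled residue-type normalization table reconstructed from the
residue-graph literature) against I_min = 3.0 — this table is configurable
and marked as a reconstruction, since no canonical printed version exists.

Shortest paths are Floyd–Warshall distances plus exact path counts g_jk,
with ties in path length resolved at a relative tolerance of 10⁻¹² (random
continuous weights almost never tie; lattice-like weights do). Node and edge
betweenness are computed from the counts, C_b(i) = Σ_{j<k} g_jk(i)/g_jk —
the suite checks them against both an exhaustive path enumeration and an
independent Brandes implementation. Girvan–Newman removes the
highest-betweenness edge (ties: lexicographic edge id), records a partition
at every component split, and returns the partition with maximal Newman
modularity. Path lengths are the −log weights, but modularity needs
affinities, so it is evaluated with exp(−w) = r_MI as edge strengths —
strongly coupled edges count as strong community ties. Clique percolation
links k-cliques sharing k−1 nodes (standard) or k−2 (a looser variant kept
because some community definitions use it); both are exposed, default k−1.

Community stability across frames matches a reference partition — from the
consensus frame, the one with maximal mean partition similarity to all
others — against every frame's partition by Jaccard ≥ 0.6, and keeps
communities matched in *more than* 75 % of frames (a 7-of-10 community is
dropped). The Jaccard threshold is our parameter; matching by strict
identity would make the rule useless under single-node fluctuations.

## Rigidity: constraint networks, pebble game, dilution

Atoms are rigid bodies with 6 degrees of freedom. Locked covalent bonds
(peptide bonds, double bonds, conjugated groups) contribute 6 bars,
rotatable single bonds 5, hydrogen bonds 5, hydrophobic tethers 2 — the
FIRST bar convention, configurable since variants exist. H-bond energies use
the distance–angle form E = V₀[5(d₀/d)¹² − 6(d₀/d)¹⁰]·cos²θ with V₀ = 8
kcal/mol, d₀ = 2.8 Å, θ the donor–H–acceptor angle (zero for θ ≤ 90°),
candidates at donor–acceptor distance ≤ 3.6 Å; only bonds at or below
E_cut = −1.0 kcal/mol enter the network. The full Mayo function has
hybridization-dependent angular terms; we use the cos² core, which is the
part the printed parameters determine. Hydrophobic tethers join C/S atoms
within the sum of van der Waals radii (C 1.7, S 1.8 Å) + 0.25 Å.

The (6,6) body-bar pebble game covers each bar if 7 pebbles can be gathered
on its endpoints; free pebbles count degrees of freedom (internal DOF =
free − 6·components). Two bodies are mutually rigid when the 7-pebble gather
fails, and — because each body carries full 6-DOF frames — mutual rigidity
is transitive, so rigid clusters are equivalence classes and partition the
bodies. The suite verifies the DOF count against a generic rigidity-matrix
rank oracle on hundreds of random networks.

Dilution removes H-bonds weakest-first (least negative energy; ties by atom
index), recomputing the decomposition each step. The unfolding transition is
the step with the largest single-step drop in giant-cluster size (earliest
on ties); weak spots are residues whose Cα leaves the giant cluster at that
step. A residue counts as flexible when its Cα sits in a flexible region or
a rigid cluster of fewer than four atoms. One behaviour of the *ideal* helix
fixture deserves a note: all its i→i+4 H-bonds are geometrically identical,
so removal order is pure tie-breaking and the largest drop is the final
cooperative collapse — weak spots then sit mid-helix, not at the frayed
termini one would see with realistic end-weakened energetics. That is a
property of degenerate energies, not a bug; jittered conformers (as used in
the pipeline and acceptance script) break the degeneracy.

## Synthetic study systems — and what they do not show

* `makeTwoLobeToy(20, 20)`: two helical-hairpin bundles (axes 8 Å apart,
  hairpin turns solved to a valid 3.8 Å virtual bond) joined by a 3-residue
  extended linker; 43 residues, lobe centroids > 15 Å apart, plus 0.05 Å
  seeded jitter. It plants exactly one slow degree of freedom (the hinge).
* `makeAllAtomHelix(12)`: ideal backbone (φ = −57°, ψ = −47°, ω = 180°,
  template bond lengths), giving 8 ideal i→i+4 H-bonds at 3.09 Å / 165°.
* `makeSyntheticMsa`: i.i.d. uniform columns with planted conserved columns
  (KL = ln 20) and perfectly coupled two-state column pairs (MI = ln 2).
* `makeGaussianEnsemble`: exact low-rank planted covariance.

Problem sizes used by the tests and acceptance script — 10⁶ DMD events on
the 43-residue toy, 5000-sequence alignments, 10⁴-frame Gaussian ensembles,
5 jittered helix conformers — were chosen so each estimator sits comfortably
inside its asymptotic regime. Passing these tests shows the machinery is
mathematically correct and internally consistent; it does not show that a
real kinase's client status would be predicted correctly. Real data add
everything the generators omit: anharmonic side-chain packing, correlated
experimental noise, phylogenetic structure in alignments (where the 62 %
weighting matters), and crystal-contact artifacts.

Two consequences of the toy's deliberate uniformity are worth spelling out.
First, GNM per-residue mobility correlates only weakly (r ≈ 0.2–0.7,
always positive, across seeds) with DMD mean-square fluctuations here:
GNM mobility is a pure contact-density signal and the toy's packing is
uniform, while the DMD fluctuations of a hinging body grow with the lever
arm from the rotation axis — geometry GNM does not see. On real proteins,
whose packing density varies, the two notoriously track each other; on this
fixture the meaningful agreement is that both methods put the slow degree
of freedom on anti-correlated rigid-lobe motion, which is what the
cross-module test asserts. Second, the first three PCA components of the
toy's DMD ensemble capture ~67–78 % of the variance, not the ≥80 % typical
of compact single-domain kinase ensembles: the helical hairpins contribute
soft internal scissoring modes that a packed catalytic core lacks.

## Degenerate inputs and numerical conventions

Coordinates are Å; residue identity is (chain, author number, insertion
code); internal indexing is 1-based, written tables carry author numbering.
Superposition excludes reflections (determinant-corrected Kabsch). A frozen
ensemble is rejected by PCA; an all-gap column scores 0 with a warning; a
disconnected contact graph warns in GNM (zero modes per component) and
errors in PRS. Eigen-solvers are dense symmetric decompositions — the
intended regime is N ≲ 500 residues. The event engine fails hard on an
event-time regression instead of silently reordering.

## Known limitations

* Ensemble analyses are Cα-based end to end; no all-atom reconstruction of
  simulation frames is attempted, so rigidity analysis requires genuinely
  all-atom input (crystal conformers or the synthetic fixture).
* GNM only — no anisotropic (3N) network model, so PRS has no directional
  force information.
* Girvan–Newman recomputes exact betweenness per removal: fine to a few
  hundred edges, quadratic beyond.
* The square-well model cannot unfold; dilution, not DMD, probes unfolding.
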