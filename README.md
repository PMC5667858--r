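# AlloDyn

Ensemble dynamics, allosteric networks and rigidity analysis of protein
kinases (and other two-lobe folds), in one tested R package.

Protein kinases that depend on the Hsp90–Cdc37 chaperone system ("client"
kinases) tend to have softer, less cooperatively coupled catalytic domains
than their chaperone-independent relatives. Differentiating clients from
non-clients computationally requires a chain of methods that is usually
scattered across separate tools: coarse-grained simulation to build a
conformational ensemble, elastic-network and principal-component analysis of
collective motions, perturbation–response scanning to locate allosteric
effector residues, residue-interaction networks weighted by dynamic and
coevolutionary couplings, and rigidity (pebble-game) analysis with
hydrogen-bond dilution to find unfolding "weak spots". AlloDyn implements
that whole chain with a common set of S4 containers, plus synthetic-data
generators with planted ground truth so every stage can be validated without
downloading a single structure.

## The methods in brief

* **Event-driven DMD of a square-well Gō model.** Cα beads interact through
  infinite square wells around their native distances, `d_min = (1−σ)·r⁰`
  and `d_max = (1+σ)·r⁰`, with σ = 0.05 for bonded neighbours, σ = 0.1 and a
  cutoff r_c = 8 Å for native contacts, and a 4 Å hard core otherwise.
  Dynamics is a sequence of elastic wall collisions (no forces, no
  integrator); an Andersen-style thermostat resamples single-particle
  velocities. The event loop is compiled (Rcpp).
* **GNM / mobility / hinges.** Kirchhoff (contact Laplacian) matrix at
  r_c = 7 Å; mobility averaged over the m slowest modes,
  `⟨M_i⟩ = Σ_k λ_k⁻¹ [u^(k)]_i² / Σ_k λ_k⁻¹`; hinge residues at profile
  minima. PCA of the ensemble gives eigenvalue spectra and the per-residue
  normalized squared displacement over the first three components.
* **PRS.** `ΔR(i) = H⁻¹ F(i)` over the GNM network: the PRS map is the
  squared pseudo-inverse, effector profiles are diagonal-excluded row means.
* **Sequence coupling.** Kullback–Leibler column conservation
  `Σ_a P(a) ln(P(a)/Q(a))`, column mutual information with sequence
  weighting and APC, and the Gaussian generalized correlation
  `r_MI = sqrt(1 − exp(−2·MI/3))` from ensemble fluctuations.
* **Residue interaction networks.** Contact edges with frame occupancy,
  lengths `w_ij = −log r_MI`; Floyd–Warshall path ensembles with exact path
  counts; node/edge betweenness `C_b(i) = Σ_{j<k} g_jk(i)/g_jk`;
  Girvan–Newman (modularity-selected) and k-clique-percolation communities;
  a >75 % cross-frame stability rule.
* **Rigidity.** FIRST-style constraint networks (6 bars for locked covalent
  bonds, 5 for rotatable bonds and hydrogen bonds, 2 for hydrophobic
  tethers; H-bond energies from the Mayo-type distance–angle function with
  the −1.0 kcal/mol cutoff), a (6,6) body-bar pebble game, hydrogen-bond
  dilution weakest-first, and weak-spot frequency ranking over conformers.

## A worked example

```r
library(AlloDyn)

trace <- makeTwoLobeToy(20, 20, seed = 1)   # 43-residue hinged mimic
model <- buildGoModel(trace)                # square-well Go model
ens   <- runDmd(model, trace, nEvents = 2e5, temperature = 1, nu = 1,
                snapshotEvery = 1000, seed = 7)

checkWallViolations(ens, model)
#> [1] 0
modes <- gnmModes(buildKirchhoff(trace))
which.min(profileValues(mobilityProfile(modes, m = 1)))
#> [1] 22
pca <- pcaEnsemble(ens)
round(pca$cumulativeVariance[3], 3)
#> [1] 0.739
```

Wall violations of exactly 0 confirm that the hard-wall tethers were never
broken over 200,000 collision events. The slowest GNM mode has its mobility
minimum at residue 22 — the centre of the 3-residue linker — identifying the
planted inter-lobe hinge. The first three PCA components capture ~74 % of
the ensemble variance, with the leading component an anti-correlated
rigid-lobe (hinge) motion.

The full pipeline (simulation → dynamics → PRS → conservation → networks →
rigidity) writes a TSV/JSON report bundle and a manifest that reproduces the
run bit-for-bit:

```r
runPipeline(list(seed = 7, out_dir = "run"))
# or from a shell:
#   Rscript inst/scripts/allodyn.R all --synthetic two-lobe --seed 7 --out run
```

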