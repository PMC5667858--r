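#' @import methods
#' @importFrom stats rnorm runif setNames cov sd quantile cor rexp
#' @importFrom utils write.table head combn
#' @useDynLib AlloDyn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Residue identity is (chain, author number, insertion code) throughout.
## Coordinates are in Angstrom; internal indexing is 1-based (R convention),
## written tables carry author numbering.

#' CaTrace: an ordered C-alpha bead model
#'
#' One bead per residue, in author order.  Consecutive beads are expected at
#' virtual-bond distance (~3.8 A); distances outside [2.8, 4.2] A raise a
#' warning and a gap beyond 6 A is treated as a chain break and rejected.
#'
#' @slot ids data.frame with columns chain, resno, icode (unique rows)
#' @slot resnames character, 3-letter residue names
#' @slot coords numeric N x 3 matrix of C-alpha coordinates (Angstrom)
#' @export
setClass("CaTrace", representation(
  ids = "data.frame", resnames = "character", coords = "matrix"))

setValidity("CaTrace", function(object) {
  n <- nrow(object@coords)
  if (n < 2) return("a CaTrace needs at least 2 residues")
  if (ncol(object@coords) != 3) return("coords must be N x 3")
  if (!is.numeric(object@coords) || any(!is.finite(object@coords)))
    return("coords must be finite numeric")
  if (nrow(object@ids) != n) return("ids/coords length mismatch")
  if (length(object@resnames) != n) return("resnames/coords length mismatch")
  key <- paste(object@ids$chain, object@ids$resno, object@ids$icode)
  if (anyDuplicated(key)) return("duplicate residue ids")
  TRUE
})

#' AtomStructure: an all-atom (or heavy-atom) model
#'
#' @slot atoms data.frame: element, name, resname, chain, resno, icode,
#'   x, y, z (Angstrom)
#' @slot bonds data.frame: i, j (atom row indices), rotatable (logical) --
#'   peptide and sp2/conjugated template bonds are locked, other single
#'   bonds rotatable
#' @slot model integer model index (from MODEL records; 1 if absent)
#' @export
setClass("AtomStructure", representation(
  atoms = "data.frame", bonds = "data.frame", model = "integer"))

setValidity("AtomStructure", function(object) {
  a <- object@atoms
  need <- c("element", "name", "resname", "chain", "resno", "icode",
            "x", "y", "z")
  if (!all(need %in% names(a))) return("atoms missing required columns")
  if (nrow(a) < 1) return("empty structure")
  b <- object@bonds
  if (nrow(b) > 0) {
    if (any(b$i < 1 | b$i > nrow(a) | b$j < 1 | b$j > nrow(a)))
      return("bond list references invalid atom indices")
  }
  TRUE
})

#' Ensemble: a conformational ensemble of C-alpha frames
#'
#' @slot coords numeric F x N x 3 array (Angstrom)
#' @slot times numeric frame times, strictly increasing
#' @slot ids residue ids matching a CaTrace
#' @slot resnames 3-letter residue names
#' @slot provenance list: seed, generator/model parameters
#' @export
setClass("Ensemble", representation(
  coords = "array", times = "numeric", ids = "data.frame",
  resnames = "character", provenance = "list"))

setValidity("Ensemble", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3 || d[3] != 3) return("coords must be F x N x 3")
  if (d[1] < 1) return("at least one frame required")
  if (length(object@times) != d[1]) return("times/frames mismatch")
  if (d[1] > 1 && any(diff(object@times) <= 0))
    return("frame times must be strictly increasing")
  if (nrow(object@ids) != d[2]) return("ids/residues mismatch")
  if (any(!is.finite(object@coords))) return("non-finite coordinates")
  TRUE
})

#' ResidueProfile: a per-residue scalar track
#'
#' @slot values numeric, one value per residue, finite
#' @slot name character label (e.g. "bfactor", "mobility")
#' @slot units character units (e.g. "A^2", "")
#' @slot ids residue ids (chain, resno, icode)
#' @export
setClass("ResidueProfile", representation(
  values = "numeric", name = "character", units = "character",
  ids = "data.frame"))

setValidity("ResidueProfile", function(object) {
  if (any(!is.finite(object@values))) return("non-finite profile values")
  if (nrow(object@ids) != length(object@values))
    return("ids/values length mismatch")
  TRUE
})

#' SquareWellModel: hard-wall tether (Go) model
#'
#' Tethers are infinite square wells [d_min, d_max] around native distances:
#' bonded (consecutive) pairs use half-width sigma_bond, native contacts
#' within the cutoff use sigma_native.  Non-tethered pairs interact only
#' through a hard core.
#'
#' @slot tethers data.frame: i, j, dmin, dmax, type ("bond"/"native")
#' @slot masses numeric particle masses (reduced units, default 1)
#' @slot params list: rc, sigma_bond, sigma_native, dhc
#' @export
setClass("SquareWellModel", representation(
  tethers = "data.frame", masses = "numeric", params = "list"))

setValidity("SquareWellModel", function(object) {
  t <- object@tethers
  if (nrow(t) > 0) {
    if (any(t$dmin <= 0) || any(t$dmax <= t$dmin))
      return("tether walls must satisfy 0 < dmin < dmax")
    key <- paste(pmin(t$i, t$j), pmax(t$i, t$j))
    if (anyDuplicated(key)) return("duplicate tether pairs")
  }
  if (any(object@masses <= 0)) return("masses must be positive")
  TRUE
})

#' KirchhoffMatrix: GNM contact Laplacian
#'
#' Off-diagonal entries are -1 for residue pairs within the cutoff, 0
#' otherwise; the diagonal holds the contact degree, so rows sum to zero and
#' the matrix is positive semidefinite.
#'
#' @slot mat numeric N x N symmetric matrix
#' @slot cutoff numeric contact cutoff (Angstrom)
#' @export
setClass("KirchhoffMatrix", representation(mat = "matrix", cutoff = "numeric"))

setValidity("KirchhoffMatrix", function(object) {
  g <- object@mat
  if (nrow(g) != ncol(g)) return("must be square")
  if (max(abs(g - t(g))) > 1e-12) return("must be symmetric")
  if (max(abs(rowSums(g))) > 1e-9) return("rows must sum to zero")
  TRUE
})

#' ModeSet: eigendecomposition of a Kirchhoff matrix
#'
#' @slot values eigenvalues, ascending
#' @slot vectors orthonormal eigenvectors (columns, matching values)
#' @slot nZero number of zero modes (= connected components)
#' @export
setClass("ModeSet", representation(
  values = "numeric", vectors = "matrix", nZero = "integer"))

#' PrsMatrix: perturbation-response scanning map
#'
#' Element (i, j) is the squared displacement response at residue j to a unit
#' perturbation at residue i, computed from the Kirchhoff pseudo-inverse.
#' Row i therefore corresponds to perturbing site i (standard PRS).
#'
#' @slot mat numeric N x N nonnegative matrix
#' @slot normalized logical; TRUE if rows were divided by the diagonal
#' @export
setClass("PrsMatrix", representation(mat = "matrix", normalized = "logical"))

setValidity("PrsMatrix", function(object) {
  if (any(object@mat < 0)) return("PRS entries must be nonnegative")
  if (!object@normalized && max(abs(object@mat - t(object@mat))) > 1e-9)
    return("unnormalized PRS matrix must be symmetric")
  TRUE
})

#' Msa: a multiple sequence alignment over the 20 amino acids plus gap
#'
#' @slot seqs character matrix, sequences x columns, single characters
#' @slot seqnames sequence names
#' @slot ref integer index of the reference sequence
#' @export
setClass("Msa", representation(
  seqs = "matrix", seqnames = "character", ref = "integer"))

setValidity("Msa", function(object) {
  if (nrow(object@seqs) < 2) return("an alignment needs >= 2 sequences")
  if (length(object@seqnames) != nrow(object@seqs))
    return("names/sequences mismatch")
  if (object@ref < 1 || object@ref > nrow(object@seqs))
    return("reference index out of range")
  TRUE
})

#' CouplingMatrix: pairwise residue couplings
#'
#' @slot mat symmetric matrix of couplings
#' @slot kind "sequence_MI" (nats) or "dynamic_rMI" (dimensionless, [0,1])
#' @slot meta estimator metadata (weighting, APC, frame count, ...)
#' @export
setClass("CouplingMatrix", representation(
  mat = "matrix", kind = "character", meta = "list"))

setValidity("CouplingMatrix", function(object) {
  m <- object@mat
  if (nrow(m) != ncol(m)) return("must be square")
  ok <- is.finite(m)
  if (max(abs(m[ok & t(ok)] - t(m)[ok & t(ok)]), 0) > 1e-9)
    return("must be symmetric")
  if (object@kind == "dynamic_rMI" &&
      any(m[ok] < -1e-12 | m[ok] > 1 + 1e-12))
    return("rMI values must lie in [0, 1]")
  TRUE
})

#' ResidueGraph: weighted residue interaction network
#'
#' Edge lengths w_ij = -log r_MI (communication distances); occupancy is the
#' fraction of ensemble frames in which the contact is present.
#'
#' @slot edges data.frame: i, j, w, occupancy
#' @slot n number of nodes (residues)
#' @slot meta construction metadata (mode, cutoffs, I_min, occupancy_min)
#' @export
setClass("ResidueGraph", representation(
  edges = "data.frame", n = "integer", meta = "list"))

setValidity("ResidueGraph", function(object) {
  e <- object@edges
  if (nrow(e) > 0) {
    if (any(e$i == e$j)) return("self-loops are not allowed")
    if (any(e$w < 0)) return("edge lengths must be nonnegative")
    if (any(e$occupancy < 0 | e$occupancy > 1))
      return("occupancy must lie in [0, 1]")
    if (any(e$i < 1 | e$j < 1 | e$i > object@n | e$j > object@n))
      return("edge endpoints out of range")
  }
  TRUE
})

#' PathMatrix: all-pairs shortest-path ensemble
#'
#' @slot dist symmetric distance matrix (Inf for disconnected pairs)
#' @slot counts numbers of distinct shortest paths g_jk per pair
#' @export
setClass("PathMatrix", representation(dist = "matrix", counts = "matrix"))

#' CommunitySet: a network community decomposition
#'
#' @slot communities list of integer node vectors
#' @slot membership integer node -> community map (NA when overlapping)
#' @slot modularity numeric Newman modularity Q (NA for clique percolation)
#' @slot overlapping logical
#' @slot stability per-community stability fraction (NA unless computed)
#' @export
setClass("CommunitySet", representation(
  communities = "list", membership = "integer", modularity = "numeric",
  overlapping = "logical", stability = "numeric"))

#' ConstraintNetwork: typed body-bar network for rigidity analysis
#'
#' Bodies are atoms with 6 degrees of freedom; constraints carry bar counts
#' per FIRST conventions: locked covalent bonds 6 bars, rotatable covalent
#' bonds and hydrogen bonds 5 bars, hydrophobic tethers 2 bars.
#'
#' @slot bars data.frame: i, j, bars, type, energy (kcal/mol, NA unless hbond)
#' @slot nBodies number of bodies (atoms)
#' @slot atoms atom table of the source structure
#' @slot params list: E_cut_hb, D_cut_hp, vdW radii, bar table
#' @export
setClass("ConstraintNetwork", representation(
  bars = "data.frame", nBodies = "integer", atoms = "data.frame",
  params = "list"))

setValidity("ConstraintNetwork", function(object) {
  b <- object@bars
  if (nrow(b) > 0) {
    if (!all(b$bars %in% c(2L, 5L, 6L)))
      return("bar counts must be 2, 5 or 6")
    key <- paste(pmin(b$i, b$j), pmax(b$i, b$j), b$type)
    if (anyDuplicated(key)) return("duplicate constraints")
    hb <- b$type == "hbond"
    ec <- object@params$E_cut_hb
    if (!is.null(ec) && any(hb) && any(b$energy[hb] > ec + 1e-12))
      return("hydrogen bonds above the energy cutoff must not enter the network")
  }
  TRUE
})

#' RigidDecomposition: pebble-game rigid-cluster decomposition
#'
#' @slot labels integer body -> cluster label (clusters partition bodies)
#' @slot sizes cluster sizes, by label
#' @slot giant label of the largest cluster
#' @slot dof internal degrees of freedom (floppy modes)
#' @slot freePebbles total free pebbles (= 6 * components + dof)
#' @slot flexible per-residue flexible flag (C-alpha in a flexible region or
#'   in a rigid cluster of fewer than four atoms)
#' @export
setClass("RigidDecomposition", representation(
  labels = "integer", sizes = "integer", giant = "integer",
  dof = "integer", freePebbles = "integer", flexible = "logical"))

#' DilutionResult: hydrogen-bond dilution trajectory
#'
#' @slot order data.frame of removed H-bonds in removal order (weakest first)
#' @slot giantSize giant-cluster size after each removal step (step 0 = intact)
#' @slot transition step index of the largest single-step drop
#' @slot weakSpots residue indices leaving the giant cluster at the transition
#' @export
setClass("DilutionResult", representation(
  order = "data.frame", giantSize = "integer", transition = "integer",
  weakSpots = "integer"))

setValidity("DilutionResult", function(object) {
  if (length(object@giantSize) > 1 && any(diff(object@giantSize) > 0))
    return("giant-cluster size must be non-increasing along the dilution")
  TRUE
})

#' WeakSpotProfile: weak-spot frequencies over a conformer ensemble
#'
#' @slot frequency per-residue fraction of conformers flagging the residue
#' @slot rank descending-frequency rank (ties by residue order)
#' @slot ids residue ids
#' @export
setClass("WeakSpotProfile", representation(
  frequency = "numeric", rank = "integer", ids = "data.frame"))

setValidity("WeakSpotProfile", function(object) {
  if (any(object@frequency < 0 | object@frequency > 1))
    return("frequencies must lie in [0, 1]")
  if (!setequal(object@rank, seq_along(object@frequency)))
    return("rank must be a permutation")
  TRUE
})
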