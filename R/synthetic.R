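## Synthetic structures, ensembles and alignments with planted ground truth.
## Every generator is a pure function of its arguments and seed: the RNG
## state of the session is saved and restored.

.withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

.helixPoints <- function(n, radius = 2.3, rise = 1.5, twist = 100,
                         phase = 0, origin = c(0, 0, 0), down = FALSE) {
  i <- seq_len(n) - 1
  th <- (phase + i * twist) * pi / 180
  z <- i * rise * if (down) -1 else 1
  cbind(radius * cos(th) + origin[1],
        radius * sin(th) + origin[2],
        z + origin[3])
}

#' Ideal alpha-helical C-alpha trace
#'
#' Rise 1.5 A/residue, 100 degrees/residue twist, helix radius 2.3 A --
#' giving the canonical ~3.8 A C-alpha virtual bond.
#'
#' @param nRes number of residues (>= 2)
#' @return a CaTrace
#' @export
makeHelix <- function(nRes) {
  if (nRes < 2) stop("need at least 2 residues", call. = FALSE)
  .newCaTrace(.helixPoints(nRes))
}

#' Two-lobe hinged toy structure
#'
#' Emulates the two-lobe kinase architecture: two compact helical-hairpin
#' bundles joined by a 3-residue extended linker, so that the slowest
#' collective mode is an inter-lobe hinge motion centred on the linker.
#' Built deterministically from helix geometry; the seed only adds a 0.05 A
#' jitter that breaks exact symmetry.
#'
#' @param n1,n2 residues per lobe (each >= 10)
#' @param seed integer seed
#' @return a CaTrace with n1 + 3 + n2 residues
#' @export
makeTwoLobeToy <- function(n1, n2, seed = 1) {
  if (n1 < 10 || n2 < 10) stop("each lobe needs >= 10 residues", call. = FALSE)
  lobe <- function(n) {
    m <- ceiling(n / 2)
    a <- .helixPoints(m)
    top <- a[m, ]
    ## second helix antiparallel, its axis 8 A away from the first along the
    ## direction of the hairpin end; pick its phase so the turn is a valid
    ## virtual bond (~3.8 A)
    thTop <- atan2(top[2], top[1])
    orig <- c(8 * cos(thTop), 8 * sin(thTop), top[3])
    best <- NULL; bestErr <- Inf
    for (ph in seq(0, 359, by = 1)) {
      b1 <- .helixPoints(1, phase = ph, origin = orig, down = TRUE)
      err <- abs(sqrt(sum((b1[1, ] - top)^2)) - 3.8)
      if (err < bestErr) { bestErr <- err; best <- ph }
    }
    b <- .helixPoints(n - m, phase = best, origin = orig, down = TRUE)
    rbind(a, b)
  }
  l1 <- lobe(n1)
  p1 <- l1[n1, ]
  c1 <- colMeans(l1)
  u <- (p1 - c1) / sqrt(sum((p1 - c1)^2))   # linker leaves lobe 1 outward
  linker <- t(vapply(1:3, function(k) p1 + k * 3.8 * u, numeric(3)))
  l2raw <- lobe(n2)
  ## orient lobe 2 so its body points onward along the linker direction
  v2 <- colMeans(l2raw) - l2raw[1, ]
  v2 <- v2 / sqrt(sum(v2^2))
  axis <- c(v2[2] * u[3] - v2[3] * u[2],
            v2[3] * u[1] - v2[1] * u[3],
            v2[1] * u[2] - v2[2] * u[1])
  s <- sqrt(sum(axis^2)); cth <- sum(v2 * u)
  R <- diag(3)
  if (s > 1e-12) {
    K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3) / s
    R <- diag(3) + sin(acos(min(1, max(-1, cth)))) * K +
         (1 - cth) * (K %*% K)
  } else if (cth < 0) R <- -diag(3)
  l2c <- sweep(l2raw, 2, l2raw[1, ]) %*% t(R)
  q <- p1 + 4 * 3.8 * u
  l2 <- sweep(l2c, 2, q, "+")
  if (min(as.matrix(dist(rbind(l1, l2)))[seq_len(n1), n1 + seq_len(n2)]) < 3.5)
    stop("internal error: lobes clash")
  xyz <- rbind(l1, linker, l2)
  .withSeed(seed, {
    xyz <- xyz + matrix(rnorm(length(xyz), sd = 0.05), ncol = 3)
  })
  tr <- .newCaTrace(xyz)
  .checkTraceGeometry(tr)
  tr
}

## Ideal backbone geometry (lengths in A, angles in degrees)
.bb <- list(
  b_NCA = 1.458, b_CAC = 1.525, b_CN = 1.329, b_CO = 1.231, b_NH = 1.010,
  a_NCAC = 111.2, a_CACN = 116.2, a_CNCA = 121.7, a_CACO = 120.5,
  a_CNH = 119.5, phi = -57, psi = -47, omega = 180)

## NeRF: place D bonded to C, with angle at C to B and dihedral A-B-C-D
.nerf <- function(A, B, C, bond, angle, dihedral) {
  th <- angle * pi / 180; ph <- dihedral * pi / 180
  d2 <- c(-bond * cos(th), bond * cos(ph) * sin(th), bond * sin(ph) * sin(th))
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m2 <- c(n[2] * bc[3] - n[3] * bc[2],
          n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  C + cbind(bc, m2, n) %*% d2
}

#' Ideal all-atom alpha-helix (backbone N, H, CA, C, O)
#'
#' Built by chain extension at ideal alpha-helical torsions
#' (phi = -57, psi = -47, omega = 180) and ideal bond geometry, so that every
#' residue i >= 5 donates an N-H...O=C hydrogen bond to residue i-4 with a
#' donor-acceptor distance in the canonical 2.8-3.1 A window.
#'
#' @param nRes number of residues (>= 6)
#' @return an AtomStructure (glycine backbone; residue 1 has no amide H)
#' @export
makeAllAtomHelix <- function(nRes) {
  if (nRes < 6) stop("need at least 6 residues", call. = FALSE)
  g <- .bb
  rows <- list()
  add <- function(el, nm, resno, xyz)
    rows[[length(rows) + 1]] <<- data.frame(
      element = el, name = nm, resname = "GLY", chain = "A",
      resno = as.integer(resno), icode = "",
      x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE)
  N <- c(0, 0, 0)
  CA <- c(g$b_NCA, 0, 0)
  thC <- (180 - g$a_NCAC) * pi / 180
  C <- CA + g$b_CAC * c(cos(thC), sin(thC), 0)
  add("N", "N", 1, N); add("C", "CA", 1, CA); add("C", "C", 1, C)
  prevN <- N; prevCA <- CA; prevC <- C
  for (i in 2:nRes) {
    Ni <- .nerf(prevN, prevCA, prevC, g$b_CN, g$a_CACN, g$psi)
    Oi <- .nerf(prevN, prevCA, prevC, g$b_CO, g$a_CACO, g$psi + 180)
    add("O", "O", i - 1, Oi)
    CAi <- .nerf(prevCA, prevC, Ni, g$b_NCA, g$a_CNCA, g$omega)
    Hi <- .nerf(prevCA, prevC, Ni, g$b_NH, g$a_CNH, 0)
    Ci <- .nerf(prevC, Ni, CAi, g$b_CAC, g$a_NCAC, g$phi)
    add("N", "N", i, Ni); add("H", "H", i, Hi)
    add("C", "CA", i, CAi); add("C", "C", i, Ci)
    prevN <- Ni; prevCA <- CAi; prevC <- Ci
  }
  Olast <- .nerf(prevN, prevCA, prevC, g$b_CO, g$a_CACO, g$psi + 180)
  add("O", "O", nRes, Olast)
  atoms <- do.call(rbind, rows)
  new("AtomStructure", atoms = atoms, bonds = .inferBonds(atoms),
      model = 1L)
}

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Synthetic alignment with planted conservation and covariation
#'
#' Conserved columns contain a single amino acid ('A' by default wherever not
#' overridden).  Each covarying pair is sampled from a perfectly coupled
#' 2-state model: column i is A or V, column j is L or I, coupled with 50/50
#' marginals, so the pair carries exactly ln 2 nats of mutual information in
#' the population.  All other columns are i.i.d. uniform over the 20 amino
#' acids.  With gapRate > 0, gaps are planted uniformly at random outside the
#' reference sequence (sequence 1).
#'
#' @param nSeq number of sequences (>= 10)
#' @param nCol number of columns
#' @param conservedCols integer column indices to conserve
#' @param covaryingPairs list of length-2 integer vectors (disjoint from
#'   conservedCols)
#' @param gapRate per-cell gap probability (default 0)
#' @param seed integer seed
#' @return an Msa with reference sequence 1
#' @export
makeSyntheticMsa <- function(nSeq, nCol, conservedCols = integer(0),
                             covaryingPairs = list(), gapRate = 0, seed = 1) {
  if (nSeq < 10) stop("need at least 10 sequences", call. = FALSE)
  covCols <- unlist(covaryingPairs)
  if (any(duplicated(c(conservedCols, covCols))))
    stop("overlapping column assignments", call. = FALSE)
  if (length(c(conservedCols, covCols)) &&
      (max(c(conservedCols, covCols)) > nCol ||
       min(c(conservedCols, covCols)) < 1))
    stop("column index out of range", call. = FALSE)
  .withSeed(seed, {
    m <- matrix(sample(.AA20, nSeq * nCol, replace = TRUE), nSeq, nCol)
    for (cc in conservedCols) m[, cc] <- "A"
    for (p in covaryingPairs) {
      state <- runif(nSeq) < 0.5
      m[, p[1]] <- ifelse(state, "A", "V")
      m[, p[2]] <- ifelse(state, "L", "I")
    }
    if (gapRate > 0) {
      gap <- matrix(runif(nSeq * nCol) < gapRate, nSeq, nCol)
      gap[1, ] <- FALSE
      m[gap] <- "-"
    }
    new("Msa", seqs = m,
        seqnames = sprintf("seq%04d", seq_len(nSeq)), ref = 1L)
  })
}

#' Gaussian ensemble with planted covariance modes
#'
#' Frames are trace + sum_k sqrt(var_k) z_k mode_k with z_k standard normal,
#' so the population covariance is exactly the planted low-rank structure.
#' Mode vectors live in 3N space, flattened residue-major (x1, y1, z1, x2...).
#'
#' @param trace a CaTrace
#' @param modeSpec list of list(vector = numeric(3N), var = positive scalar);
#'   vectors must be orthonormal (Gram deviation < 1e-6)
#' @param nFrames number of frames
#' @param seed integer seed
#' @return an Ensemble
#' @export
makeGaussianEnsemble <- function(trace, modeSpec, nFrames, seed = 1) {
  n3 <- 3 * nResidues(trace)
  V <- vapply(modeSpec, function(s) s$vector, numeric(n3))
  vars <- vapply(modeSpec, function(s) s$var, numeric(1))
  if (any(vars <= 0)) stop("mode variances must be positive", call. = FALSE)
  gram <- crossprod(V)
  if (max(abs(gram - diag(ncol(V)))) > 1e-6)
    stop("mode vectors must be orthonormal (Gram deviation > 1e-6)",
         call. = FALSE)
  base <- as.vector(t(trace@coords))
  .withSeed(seed, {
    z <- matrix(rnorm(nFrames * length(vars)), nFrames)
    flat <- z %*% (t(V) * sqrt(vars))
    arr <- array(0, c(nFrames, nResidues(trace), 3))
    for (f in seq_len(nFrames))
      arr[f, , ] <- matrix(base + flat[f, ], ncol = 3, byrow = TRUE)
    .newEnsemble(arr, trace,
                 provenance = list(generator = "gaussian_modes", seed = seed,
                                   vars = vars))
  })
}
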