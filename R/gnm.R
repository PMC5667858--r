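## Gaussian network model: Kirchhoff matrix, mode decomposition, mobility
## profiles and hinge detection; plus PCA (essential dynamics) of ensembles.

#' Build the GNM Kirchhoff (contact Laplacian) matrix
#'
#' Off-diagonal entries are -1 for C-alpha pairs within the cutoff, 0
#' otherwise; the diagonal is the contact degree.  Bonded and nonbonded
#' pairs are treated identically (uniform spring constant).
#'
#' @param trace a CaTrace
#' @param rc contact cutoff in Angstrom (default 7.0)
#' @return a KirchhoffMatrix
#' @export
buildKirchhoff <- function(trace, rc = 7.0) {
  x <- coords(trace)
  n <- nrow(x)
  d <- as.matrix(dist(x))
  g <- -(d <= rc) * 1
  diag(g) <- 0
  diag(g) <- -rowSums(g)
  if (.countComponents(g) > 1)
    warning("contact graph is disconnected")
  new("KirchhoffMatrix", mat = unname(g), cutoff = rc)
}

## connected components of the contact graph via union-find
.countComponents <- function(g) {
  n <- nrow(g)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (g[i, j] != 0) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' GNM mode decomposition
#'
#' Full symmetric eigendecomposition of the Kirchhoff matrix; eigenvalues
#' ascending, zero modes (one per connected component) flagged and excluded
#' from inverse-eigenvalue weighting downstream.
#'
#' @param gamma a KirchhoffMatrix (or a symmetric Laplacian matrix)
#' @return a ModeSet
#' @export
gnmModes <- function(gamma) {
  g <- if (is(gamma, "KirchhoffMatrix")) gamma@mat else as.matrix(gamma)
  if (max(abs(g - t(g))) > 1e-9)
    stop("Kirchhoff matrix must be symmetric", call. = FALSE)
  e <- eigen(g, symmetric = TRUE)
  ord <- order(e$values)
  vals <- e$values[ord]
  vecs <- e$vectors[, ord, drop = FALSE]
  tol <- 1e-8 * max(abs(vals), 1)
  nz <- sum(abs(vals) < tol)
  vals[abs(vals) < tol] <- 0
  new("ModeSet", values = vals, vectors = vecs, nZero = as.integer(nz))
}

#' Mobility profile over the m slowest nonzero modes
#'
#' <M_i> = sum_k lambda_k^-1 [u^(k)_i]^2 / sum_k lambda_k^-1 over the m
#' slowest nonzero modes; sums to 1 over residues by orthonormality.
#'
#' @param modes a ModeSet
#' @param m number of slow modes to average (>= 1)
#' @param ids optional residue ids for the returned profile
#' @return a ResidueProfile named "mobility"
#' @export
mobilityProfile <- function(modes, m = 10, ids = NULL) {
  nAvail <- length(modes@values) - modes@nZero
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  if (m > nAvail)
    stop(sprintf("m = %d exceeds the %d available nonzero modes", m, nAvail),
         call. = FALSE)
  sel <- (modes@nZero + 1):(modes@nZero + m)
  w <- 1 / modes@values[sel]
  u2 <- modes@vectors[, sel, drop = FALSE]^2
  prof <- as.vector(u2 %*% w) / sum(w)
  n <- length(prof)
  if (is.null(ids))
    ids <- data.frame(chain = "A", resno = seq_len(n), icode = "",
                      stringsAsFactors = FALSE)
  new("ResidueProfile", values = prof, name = "mobility", units = "",
      ids = ids)
}

#' Identify global hinge residues
#'
#' Hinges are local minima of the mobility profile (within a +/- window/2
#' neighbourhood) that also fall below the stated percentile of the profile.
#' Minima of the slow-mode mobility mark the centres about which the lobes
#' move collectively.
#'
#' @param profile a ResidueProfile (mobility)
#' @param window neighbourhood width in residues (default 5)
#' @param percentile profile percentile cap (default 25)
#' @return integer vector of hinge residue indices (possibly empty)
#' @export
identifyHinges <- function(profile, window = 5, percentile = 25) {
  v <- profileValues(profile)
  n <- length(v)
  if (n < window) stop("profile shorter than the window", call. = FALSE)
  if (diff(range(v)) < 1e-12) return(integer(0))
  half <- floor(window / 2)
  cap <- quantile(v, percentile / 100)
  hinges <- integer(0)
  for (i in seq_len(n)) {
    nb <- max(1, i - half):min(n, i + half)
    if (v[i] <= min(v[nb]) && v[i] <= cap) hinges <- c(hinges, i)
  }
  hinges
}

#' PCA of a conformational ensemble (essential dynamics)
#'
#' Frames are superposed onto the ensemble mean, then the 3N x 3N coordinate
#' covariance is diagonalized.  The per-residue normalized squared
#' displacement over the first three components is
#' D_i = sum_{k<=3} lambda_k |(v_k)_i|^2 / sum_{k<=3} lambda_k, normalized so
#' sum_i D_i = 1.
#'
#' @param ensemble an Ensemble with >= 10 frames
#' @param nComponents number of leading components to report (default 3)
#' @param fit superpose frames onto the mean first (default TRUE)
#' @return list with eigenvalues (descending), components (3N columns),
#'   varianceFraction, cumulativeVariance, residueDisplacement (ResidueProfile)
#' @export
pcaEnsemble <- function(ensemble, nComponents = 3, fit = TRUE) {
  arr <- coords(ensemble)
  F <- dim(arr)[1]; n <- dim(arr)[2]
  if (F < 10) stop("need at least 10 frames for PCA", call. = FALSE)
  if (fit) {
    ref <- apply(arr, c(2, 3), mean)
    arr <- .superposeFrames(arr, ref)
    ref <- apply(arr, c(2, 3), mean)
    arr <- .superposeFrames(arr, ref)
  }
  X <- t(vapply(seq_len(F), function(f) as.vector(t(arr[f, , ])),
                numeric(3 * n)))
  X <- sweep(X, 2, colMeans(X))
  if (max(abs(X)) < 1e-12) stop("zero covariance: frozen ensemble",
                                call. = FALSE)
  sv <- svd(X, nu = 0)
  lambda <- sv$d^2 / (F - 1)
  V <- sv$v
  total <- sum(lambda)
  k3 <- min(3, length(lambda))
  w <- lambda[seq_len(k3)]
  disp <- rep(0, n)
  for (k in seq_len(k3)) {
    vk <- matrix(V[, k], ncol = 3, byrow = TRUE)
    disp <- disp + w[k] * rowSums(vk^2)
  }
  disp <- disp / sum(w)
  nc <- min(nComponents, length(lambda))
  list(eigenvalues = lambda,
       components = V[, seq_len(nc), drop = FALSE],
       varianceFraction = lambda / total,
       cumulativeVariance = cumsum(lambda / total),
       residueDisplacement = new("ResidueProfile", values = disp,
                                 name = "pca_displacement", units = "",
                                 ids = ensemble@ids))
}
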