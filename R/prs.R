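## Perturbation-response scanning over the GNM network.  A unit perturbation
## at residue i produces the displacement response Gamma^+ column i (Hooke's
## law with the Kirchhoff matrix as the scalar Hessian); squaring the
## pseudo-inverse entries gives the N x N PRS map.

#' Perturbation-response scan
#'
#' Computes the Moore-Penrose pseudo-inverse of the Kirchhoff matrix over its
#' nonzero modes and squares it entry-wise: S_ij = [(Gamma^+)_ij]^2, the
#' squared response at residue j to a unit perturbation at residue i.  The
#' normalized variant divides each row by its diagonal element.
#'
#' @param gamma a KirchhoffMatrix (connected: exactly one zero mode)
#' @param normalized divide row i by S_ii (default FALSE)
#' @return a PrsMatrix
#' @export
prsScan <- function(gamma, normalized = FALSE) {
  modes <- gnmModes(gamma)
  if (modes@nZero != 1)
    stop("PRS requires a connected contact graph (exactly one zero mode)",
         call. = FALSE)
  sel <- (modes@nZero + 1):length(modes@values)
  U <- modes@vectors[, sel, drop = FALSE]
  ginv <- U %*% (t(U) / modes@values[sel])
  S <- ginv^2
  if (normalized) S <- S / diag(S)
  new("PrsMatrix", mat = S, normalized = normalized)
}

#' Effector profile: row means of the PRS matrix
#'
#' The mean over all elements of row i (the perturbed site), diagonal
#' excluded, measures the ability of residue i to propagate perturbations to
#' the rest of the network; profile peaks mark allosteric mediating hotspots.
#'
#' @param S a PrsMatrix
#' @param ids optional residue ids
#' @return a ResidueProfile named "effector"
#' @export
effectorProfile <- function(S, ids = NULL) {
  m <- S@mat
  n <- nrow(m)
  if (n < 2) stop("need at least 2 residues", call. = FALSE)
  vals <- (rowSums(m) - diag(m)) / (n - 1)
  if (is.null(ids))
    ids <- data.frame(chain = "A", resno = seq_len(n), icode = "",
                      stringsAsFactors = FALSE)
  new("ResidueProfile", values = vals, name = "effector", units = "",
      ids = ids)
}

#' Sensor profile: column means of the PRS matrix
#'
#' Column j averages the responses at residue j to perturbations elsewhere
#' (diagonal excluded).  Identical to the effector profile for the symmetric
#' unnormalized variant.
#'
#' @param S a PrsMatrix
#' @param ids optional residue ids
#' @return a ResidueProfile named "sensor"
#' @export
sensorProfile <- function(S, ids = NULL) {
  m <- S@mat
  n <- nrow(m)
  if (n < 2) stop("need at least 2 residues", call. = FALSE)
  vals <- (colSums(m) - diag(m)) / (n - 1)
  if (is.null(ids))
    ids <- data.frame(chain = "A", resno = seq_len(n), icode = "",
                      stringsAsFactors = FALSE)
  new("ResidueProfile", values = vals, name = "sensor", units = "",
      ids = ids)
}
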