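## Square-well Go model construction and the event-driven DMD front end.
## The event loop itself is compiled (src/dmd_engine.cpp); the R functions
## here expose the model arithmetic and single-event kinematics for testing
## and build the Ensemble from engine snapshots.

#' Build a hard-wall square-well (Go) model from a C-alpha trace
#'
#' Consecutive residues get bonded tethers with half-width sigmaBond around
#' their native distance; non-consecutive pairs whose native distance is
#' within rc get native-contact tethers with half-width sigmaNative.  All
#' other pairs interact only through a hard core of diameter dhc (tethered
#' pairs use their own inner wall as the core).
#'
#' @param trace a CaTrace (the native conformation)
#' @param rc native-contact cutoff in Angstrom (default 8)
#' @param sigmaBond well half-width for bonded pairs (default 0.05)
#' @param sigmaNative well half-width for native contacts (default 0.1)
#' @param dhc hard-core diameter for non-tethered pairs (default 4.0 A)
#' @return a SquareWellModel; walls are d_min = (1 - sigma) r0 and
#'   d_max = (1 + sigma) r0
#' @export
buildGoModel <- function(trace, rc = 8, sigmaBond = 0.05,
                         sigmaNative = 0.1, dhc = 4.0) {
  x <- coords(trace)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 residues", call. = FALSE)
  d <- as.matrix(dist(x))
  ii <- jj <- integer(0); r0 <- numeric(0); type <- character(0)
  for (i in seq_len(n - 1)) {
    ii <- c(ii, i); jj <- c(jj, i + 1)
    r0 <- c(r0, d[i, i + 1]); type <- c(type, "bond")
    js <- which(d[i, ] <= rc)
    js <- js[js > i + 1]
    if (length(js)) {
      ii <- c(ii, rep(i, length(js))); jj <- c(jj, js)
      r0 <- c(r0, d[i, js]); type <- c(type, rep("native", length(js)))
    }
  }
  sig <- ifelse(type == "bond", sigmaBond, sigmaNative)
  tethers <- data.frame(i = ii, j = jj,
                        dmin = (1 - sig) * r0, dmax = (1 + sig) * r0,
                        type = type, stringsAsFactors = FALSE)
  new("SquareWellModel", tethers = tethers, masses = rep(1, n),
      params = list(rc = rc, sigma_bond = sigmaBond,
                    sigma_native = sigmaNative, dhc = dhc))
}

#' Time to the next wall crossing of a pair
#'
#' Smallest positive root of |dr + dv t|^2 = d^2 for ballistic relative
#' motion.  For an outer wall the pair starts inside and the crossing always
#' exists when there is relative motion; for an inner wall it requires
#' sufficient approach.
#'
#' @param dr relative position (length-3)
#' @param dv relative velocity (length-3)
#' @param d wall distance (> 0)
#' @param side "outer" or "inner"
#' @return positive time, or NA if the wall is never reached
#' @export
nextEventTime <- function(dr, dv, d, side = c("outer", "inner")) {
  side <- match.arg(side)
  if (d <= 0) stop("wall distance must be positive", call. = FALSE)
  a <- sum(dv^2)
  if (a == 0) return(NA_real_)
  b <- sum(dr * dv)
  cc <- sum(dr^2) - d^2
  disc <- b^2 - a * cc
  if (side == "outer") {
    if (disc < 0) return(NA_real_)
    t <- (-b + sqrt(disc)) / a
    if (t <= 0) NA_real_ else t
  } else {
    if (b >= 0 || disc <= 0) return(NA_real_)
    t <- (-b - sqrt(disc)) / a
    if (t <= 0) NA_real_ else t
  }
}

#' Elastic hard-wall reflection of a particle pair
#'
#' Reverses the radial component of the relative velocity; total momentum and
#' kinetic energy are conserved exactly.
#'
#' @param rhat unit separation vector (from j to i)
#' @param vi,vj velocities
#' @param mi,mj masses (default 1)
#' @return list(vi, vj) of post-collision velocities
#' @export
reflectVelocities <- function(rhat, vi, vj, mi = 1, mj = 1) {
  vr <- sum((vi - vj) * rhat)
  if (abs(vr) < 1e-14) {
    warning("grazing event: zero radial relative velocity, no-op")
    return(list(vi = vi, vj = vj))
  }
  mu <- mi * mj / (mi + mj)
  J <- 2 * mu * vr
  list(vi = vi - (J / mi) * rhat, vj = vj + (J / mj) * rhat)
}

#' Run event-driven DMD
#'
#' Initial positions are the native trace; initial velocities are drawn from
#' Maxwell-Boltzmann at the requested temperature (reduced units, k_B = 1).
#' An Andersen-style thermostat resamples one particle's velocity at ghost
#' events arriving at rate nu per particle; with nu = 0 the dynamics is
#' purely Newtonian and kinetic energy is conserved.
#'
#' @param model a SquareWellModel
#' @param trace the native CaTrace the model was built from
#' @param nEvents number of collision events to simulate
#' @param temperature reduced temperature T (> 0)
#' @param nu thermostat collision rate per particle (>= 0)
#' @param snapshotEvery snapshot cadence in events (default 1000)
#' @param seed integer seed (reproducible: same seed, same trajectory)
#' @param v0 optional N x 3 initial velocity matrix overriding the
#'   Maxwell-Boltzmann draw
#' @return an Ensemble; provenance carries all parameters plus engine
#'   diagnostics (time-averaged kinetic energy, max relative KE drift
#'   between thermostat events)
#' @export
runDmd <- function(model, trace, nEvents, temperature = 1, nu = 0,
                   snapshotEvery = 1000, seed = 1, v0 = NULL) {
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  if (nu < 0) stop("thermostat rate must be nonnegative", call. = FALSE)
  x0 <- coords(trace)
  n <- nrow(x0)
  .withSeed(seed, {
    if (is.null(v0))
      v0 <- matrix(rnorm(3 * n, sd = sqrt(temperature / model@masses)),
                   n, 3)
    res <- .dmdRun(x0, v0,
                   as.integer(model@tethers$i), as.integer(model@tethers$j),
                   model@tethers$dmin, model@tethers$dmax,
                   model@masses, model@params$dhc,
                   as.integer(nEvents), temperature, nu,
                   as.integer(snapshotEvery))
    nsnap <- res$nsnap
    arr <- array(0, c(nsnap, n, 3))
    flat <- res$frames
    for (f in seq_len(nsnap)) {
      block <- flat[((f - 1) * 3 * n + 1):(f * 3 * n)]
      arr[f, , ] <- matrix(block, ncol = 3, byrow = TRUE)
    }
    times <- res$times
    if (nsnap > 1 && any(diff(times) <= 0)) {
      keep <- c(TRUE, diff(times) > 0)
      arr <- arr[keep, , drop = FALSE]; times <- times[keep]
    }
    .newEnsemble(arr, trace, times = times,
                 provenance = list(
                   engine = "dmd", seed = seed, n_events = res$nEvents,
                   temperature = temperature, nu = nu,
                   snapshot_every = snapshotEvery,
                   rc = model@params$rc, dhc = model@params$dhc,
                   sigma_bond = model@params$sigma_bond,
                   sigma_native = model@params$sigma_native,
                   ke_mean = res$keMean,
                   ke_mean_second_half = res$keMeanSecondHalf,
                   max_ke_drift = res$maxKeDrift))
  })
}

#' Maximum wall violation of an ensemble under a square-well model
#'
#' For every snapshot, checks every tether against its walls and every
#' non-tethered pair against the hard core; returns the largest excursion in
#' Angstrom (0 when all constraints hold exactly).
#'
#' @param ensemble an Ensemble
#' @param model the SquareWellModel the trajectory was generated under
#' @return max violation in Angstrom (should be <= 1e-6 for a valid run)
#' @export
checkWallViolations <- function(ensemble, model) {
  arr <- coords(ensemble)
  n <- dim(arr)[2]
  t <- model@tethers
  pairKey <- paste(t$i, t$j)
  worst <- 0
  allPairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  tethered <- paste(allPairs[, 1], allPairs[, 2]) %in% pairKey
  free <- allPairs[!tethered, , drop = FALSE]
  for (f in seq_len(dim(arr)[1])) {
    x <- arr[f, , ]
    dt <- sqrt(rowSums((x[t$i, , drop = FALSE] - x[t$j, , drop = FALSE])^2))
    worst <- max(worst, t$dmin - dt, dt - t$dmax)
    if (nrow(free)) {
      df <- sqrt(rowSums((x[free[, 1], , drop = FALSE] -
                          x[free[, 2], , drop = FALSE])^2))
      worst <- max(worst, model@params$dhc - df)
    }
  }
  max(worst, 0)
}
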