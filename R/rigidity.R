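## FIRST-style rigidity analysis: geometric hydrogen-bond and hydrophobic
## tether detection, typed body-bar constraint networks, the (6,6) pebble
## game for rigid-cluster decomposition, hydrogen-bond dilution (emulated
## thermal unfolding) and weak-spot frequency ranking over conformers.

#' Detect backbone/side-chain hydrogen bonds
#'
#' Donor-hydrogen pairs (N/O with a covalently attached H) are screened
#' against N/O acceptors within 3.6 A (donor-acceptor).  The energy is the
#' distance-angle function E = V0 [5 (d0/d)^12 - 6 (d0/d)^10] cos^2(theta)
#' with V0 = 8 kcal/mol, d0 = 2.8 A, theta the D-H...A angle (F = 0 for
#' theta <= 90 degrees).
#'
#' @param s an AtomStructure with hydrogens and a bond list
#' @param dMax candidate donor-acceptor cutoff (default 3.6 A)
#' @param V0 well depth, kcal/mol (default 8)
#' @param d0 optimal donor-acceptor distance (default 2.8 A)
#' @return data.frame: donor, hydrogen, acceptor (atom indices), dist,
#'   angle (degrees), energy (kcal/mol)
#' @export
detectHbonds <- function(s, dMax = 3.6, V0 = 8, d0 = 2.8) {
  a <- s@atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  b <- s@bonds
  ## hydrogens attached to N/O
  hIdx <- which(a$element == "H")
  dh <- list()
  for (h in hIdx) {
    part <- c(b$i[b$j == h], b$j[b$i == h])
    don <- part[a$element[part] %in% c("N", "O")]
    if (length(don)) dh[[length(dh) + 1]] <- c(don[1], h)
  }
  donors <- which(a$element %in% c("N", "O"))
  if (length(hIdx) && !length(dh))
    warning("no donor found for any hydrogen")
  acceptors <- which(a$element %in% c("N", "O"))
  out <- list()
  reskey <- paste(a$chain, a$resno, a$icode)
  for (p in dh) {
    D <- p[1]; H <- p[2]
    for (A in acceptors) {
      if (A == D || reskey[A] == reskey[D]) next
      d <- sqrt(sum((xyz[D, ] - xyz[A, ])^2))
      if (d > dMax) next
      v1 <- xyz[D, ] - xyz[H, ]
      v2 <- xyz[A, ] - xyz[H, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      theta <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      Fang <- if (theta > 90) cos(theta * pi / 180)^2 else 0
      E <- V0 * (5 * (d0 / d)^12 - 6 * (d0 / d)^10) * Fang
      out[[length(out) + 1]] <-
        data.frame(donor = D, hydrogen = H, acceptor = A,
                   dist = d, angle = theta, energy = E)
    }
  }
  if (!length(out))
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), dist = numeric(0),
                      angle = numeric(0), energy = numeric(0)))
  do.call(rbind, out)
}

#' Detect hydrophobic tethers
#'
#' Carbon/sulfur atom pairs from different residues within the sum of their
#' van der Waals radii (C 1.7 A, S 1.8 A) plus a temperature-independent
#' 0.25 A margin.
#'
#' @param s an AtomStructure
#' @param dCut margin added to the vdW radii sum (default 0.25 A)
#' @param sideChainOnly restrict to side-chain atoms (default TRUE)
#' @return data.frame: i, j (atom indices), dist
#' @export
detectHydrophobic <- function(s, dCut = 0.25, sideChainOnly = TRUE) {
  a <- s@atoms
  vdw <- c(C = 1.7, S = 1.8)
  cand <- which(a$element %in% names(vdw))
  if (sideChainOnly)
    cand <- cand[!(a$name[cand] %in% c("N", "CA", "C", "O"))]
  if (length(cand) < 2)
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  xyz <- as.matrix(a[cand, c("x", "y", "z")])
  d <- as.matrix(dist(xyz))
  lim <- outer(vdw[a$element[cand]], vdw[a$element[cand]], "+") + dCut
  reskey <- paste(a$chain, a$resno, a$icode)[cand]
  hit <- which(d <= lim & upper.tri(d) &
               outer(reskey, reskey, "!="), arr.ind = TRUE)
  data.frame(i = cand[hit[, 1]], j = cand[hit[, 2]],
             dist = d[hit])
}

#' Build a body-bar constraint network
#'
#' Atoms are rigid bodies with 6 degrees of freedom.  Constraints carry bar
#' counts per FIRST conventions: locked covalent bonds 6 bars, rotatable
#' covalent bonds 5 bars, hydrogen bonds 5 bars (only those at or below the
#' energy cutoff enter), hydrophobic tethers 2 bars.
#'
#' @param s an AtomStructure (bond list classified rotatable/locked)
#' @param hbonds data.frame from \code{detectHbonds}
#' @param tethers data.frame from \code{detectHydrophobic}
#' @param eCut hydrogen-bond energy cutoff, kcal/mol (default -1.0)
#' @return a ConstraintNetwork
#' @export
buildConstraintNetwork <- function(s, hbonds = detectHbonds(s),
                                   tethers = detectHydrophobic(s),
                                   eCut = -1.0) {
  b <- s@bonds
  bars <- data.frame(
    i = b$i, j = b$j,
    bars = ifelse(b$rotatable, 5L, 6L),
    type = ifelse(b$rotatable, "covalent_rotatable", "covalent_locked"),
    energy = NA_real_, stringsAsFactors = FALSE)
  hb <- hbonds[hbonds$energy <= eCut, , drop = FALSE]
  if (nrow(hb))
    bars <- rbind(bars, data.frame(
      i = pmin(hb$donor, hb$acceptor), j = pmax(hb$donor, hb$acceptor),
      bars = 5L, type = "hbond", energy = hb$energy,
      stringsAsFactors = FALSE))
  if (nrow(tethers))
    bars <- rbind(bars, data.frame(
      i = pmin(tethers$i, tethers$j), j = pmax(tethers$i, tethers$j),
      bars = 2L, type = "hydrophobic", energy = NA_real_,
      stringsAsFactors = FALSE))
  key <- paste(pmin(bars$i, bars$j), pmax(bars$i, bars$j), bars$type)
  bars <- bars[!duplicated(key), , drop = FALSE]
  covOnly <- bars[grepl("covalent", bars$type), , drop = FALSE]
  comp <- .components(nrow(s@atoms),
                      data.frame(i = covOnly$i, j = covOnly$j))
  if (max(comp) > 1)
    warning("covalent skeleton is disconnected")
  new("ConstraintNetwork", bars = bars, nBodies = nrow(s@atoms),
      atoms = s@atoms,
      params = list(E_cut_hb = eCut, bar_table = c(
        covalent_rotatable = 5, covalent_locked = 6, hbond = 5,
        hydrophobic = 2)))
}

## (6,6) body-bar pebble game.  Mutable state lives in an environment:
## free pebble counts per body and the directed multigraph of covered bars.
.pebbleState <- function(B) {
  st <- new.env(parent = emptyenv())
  st$B <- B
  st$free <- rep(6L, B)
  st$out <- vector("list", B)           # out[[u]]: integer heads (multi)
  st
}

## DFS for a free pebble reachable from start (excluding excl); on success
## the path is reversed and the pebble arrives at start.
.pebbleSearch <- function(st, start, excl) {
  visited <- rep(FALSE, st$B)
  visited[excl] <- TRUE
  dfs <- function(u) {
    visited[u] <<- TRUE
    for (w in unique(st$out[[u]])) {
      if (visited[w]) next
      if (st$free[w] > 0L) {
        ## take a free pebble from w and pull it across u -> w
        st$free[w] <- st$free[w] - 1L
        k <- match(w, st$out[[u]])
        st$out[[u]] <- st$out[[u]][-k]
        st$out[[w]] <- c(st$out[[w]], u)
        return(TRUE)
      }
      if (dfs(w)) {
        ## a pebble already bubbled up to w; reverse the u -> w edge
        k <- match(w, st$out[[u]])
        st$out[[u]] <- st$out[[u]][-k]
        st$out[[w]] <- c(st$out[[w]], u)
        return(TRUE)
      }
    }
    FALSE
  }
  if (dfs(start)) {
    st$free[start] <- st$free[start] + 1L
    TRUE
  } else FALSE
}

## gather up to 7 pebbles on {u, v}; TRUE if reached
.pebbleGather <- function(st, u, v) {
  repeat {
    if (st$free[u] + st$free[v] >= 7L) return(TRUE)
    moved <- FALSE
    if (st$free[u] < 6L && .pebbleSearch(st, u, v)) moved <- TRUE
    if (st$free[u] + st$free[v] >= 7L) return(TRUE)
    if (st$free[v] < 6L && .pebbleSearch(st, v, u)) moved <- TRUE
    if (!moved) return(st$free[u] + st$free[v] >= 7L)
  }
}

#' Rigid-cluster decomposition by the (6,6) body-bar pebble game
#'
#' Each body holds 6 pebbles; a bar is independent when 7 pebbles can be
#' gathered on its endpoints, and covering it consumes one.  After all bars
#' are processed, bodies are mutually rigid when the 7-pebble gather fails;
#' rigid clusters are the transitive closure of locked bar-connected pairs.
#' Internal degrees of freedom = free pebbles - 6 x (connected components).
#'
#' @param net a ConstraintNetwork
#' @return a RigidDecomposition
#' @export
pebbleGame <- function(net) {
  B <- net@nBodies
  st <- .pebbleState(B)
  bars <- net@bars
  for (r in seq_len(nrow(bars))) {
    u <- bars$i[r]; v <- bars$j[r]
    for (rep_ in seq_len(bars$bars[r])) {
      if (.pebbleGather(st, u, v)) {
        if (st$free[u] > 0L) {
          st$free[u] <- st$free[u] - 1L
          st$out[[u]] <- c(st$out[[u]], v)
        } else {
          st$free[v] <- st$free[v] - 1L
          st$out[[v]] <- c(st$out[[v]], u)
        }
      }                                  # else redundant bar
    }
  }
  ncomp <- max(.components(B, bars))
  freeTot <- sum(st$free)
  dof <- freeTot - 6L * ncomp
  ## rigid clusters: union-find over bar pairs failing the 7-pebble gather
  parent <- seq_len(B)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  pairKey <- unique(paste(bars$i, bars$j))
  for (pk in pairKey) {
    uv <- as.integer(strsplit(pk, " ")[[1]])
    if (!.pebbleGather(st, uv[1], uv[2])) {
      ri <- find(uv[1]); rj <- find(uv[2])
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(B), find, integer(1))
  labels <- match(roots, unique(roots))
  sizes <- as.integer(table(factor(labels, levels = seq_len(max(labels)))))
  giant <- which.max(sizes)
  flexible <- .residueFlexibility(net, labels, sizes)
  new("RigidDecomposition", labels = as.integer(labels), sizes = sizes,
      giant = as.integer(giant), dof = as.integer(dof),
      freePebbles = as.integer(freeTot), flexible = flexible)
}

## a residue is flexible when its C-alpha sits in a flexible region or in a
## rigid cluster of fewer than four atoms
.residueFlexibility <- function(net, labels, sizes) {
  a <- net@atoms
  if (!nrow(a) || !"name" %in% names(a)) return(logical(0))
  caIdx <- which(a$name == "CA")
  if (!length(caIdx)) return(logical(0))
  sizes[labels[caIdx]] < 4L
}

#' Hydrogen-bond dilution (emulated thermal unfolding)
#'
#' Hydrogen bonds are removed one at a time from weakest (least negative
#' energy) to strongest (ties broken by donor atom index), keeping all
#' covalent and hydrophobic constraints, and the rigid decomposition is
#' recomputed after each removal.  The unfolding transition is the step with
#' the largest single-step drop in giant-cluster size (earliest on ties);
#' weak spots are residues whose C-alpha is in the giant cluster immediately
#' before the transition and outside it immediately after.
#'
#' @param net a ConstraintNetwork with at least one hydrogen bond
#' @return a DilutionResult; the weak-spot slot holds residue indices into
#'   the structure's residue order
#' @export
hbDilution <- function(net) {
  hbRows <- which(net@bars$type == "hbond")
  if (!length(hbRows)) {
    warning("no hydrogen bonds to dilute")
    return(new("DilutionResult",
               order = net@bars[integer(0), ],
               giantSize = integer(0), transition = NA_integer_,
               weakSpots = integer(0)))
  }
  hb <- net@bars[hbRows, , drop = FALSE]
  ord <- order(-hb$energy, hb$i, hb$j)     # least negative (weakest) first
  removeSeq <- hbRows[ord]
  a <- net@atoms
  reskey <- paste(a$chain, a$resno, a$icode)
  resLevels <- unique(reskey)
  caIdx <- vapply(resLevels, function(rk)
    which(reskey == rk & a$name == "CA")[1], integer(1))
  giantMembers <- function(dec) {
    which(dec@labels == dec@giant)
  }
  dec0 <- pebbleGame(net)
  gs <- dec0@sizes[dec0@giant]
  members <- list(giantMembers(dec0))
  for (k in seq_along(removeSeq)) {
    step <- new("ConstraintNetwork",
                bars = net@bars[-removeSeq[seq_len(k)], , drop = FALSE],
                nBodies = net@nBodies, atoms = net@atoms,
                params = net@params)
    dec <- pebbleGame(step)
    gs <- c(gs, dec@sizes[dec@giant])
    members[[k + 1]] <- giantMembers(dec)
  }
  drops <- -diff(gs)
  transition <- if (all(drops <= 0)) NA_integer_ else which.max(drops)
  weak <- integer(0)
  if (!is.na(transition)) {
    before <- members[[transition]]
    after <- members[[transition + 1]]
    weak <- which(caIdx %in% setdiff(before, after))
  }
  new("DilutionResult",
      order = net@bars[removeSeq, , drop = FALSE],
      giantSize = as.integer(gs), transition = transition,
      weakSpots = as.integer(weak))
}

#' Weak-spot frequencies over a conformer ensemble
#'
#' The frequency of each residue being flagged as a weak spot across the
#' dilution results of multiple conformers, ranked in decreasing order
#' (ties broken by residue order).
#'
#' @param results list of DilutionResult over conformers of one structure
#' @param nRes number of residues
#' @param ids optional residue ids
#' @return a WeakSpotProfile
#' @export
weakSpotFrequency <- function(results, nRes, ids = NULL) {
  if (!length(results)) stop("need at least one dilution result",
                             call. = FALSE)
  bad <- vapply(results, function(r)
    length(r@weakSpots) && max(r@weakSpots) > nRes, logical(1))
  if (any(bad)) stop("inconsistent residue sets across conformers",
                     call. = FALSE)
  freq <- rowMeans(vapply(results, function(r)
    seq_len(nRes) %in% r@weakSpots, logical(nRes)))
  rk <- order(-freq, seq_len(nRes))
  rank <- integer(nRes); rank[rk] <- seq_len(nRes)
  if (is.null(ids))
    ids <- data.frame(chain = "A", resno = seq_len(nRes), icode = "",
                      stringsAsFactors = FALSE)
  new("WeakSpotProfile", frequency = freq, rank = rank, ids = ids)
}
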