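## Ensemble-averaged residue interaction networks: construction, shortest-path
## ensembles (Floyd-Warshall with tie-tolerant path counts), node/edge
## betweenness by path counting, Girvan-Newman and clique-percolation
## communities, and cross-frame community stability.

## residue-type normalization values for the interaction-strength formula
## I_ij = 100 n_ij / sqrt(N_i N_j); bundled, configurable reconstruction
.rinNorm <- c(
  ALA = 55.76, ARG = 93.79, ASN = 73.41, ASP = 75.15, CYS = 54.95,
  GLN = 78.13, GLU = 78.83, GLY = 47.31, HIS = 83.74, ILE = 67.95,
  LEU = 72.25, LYS = 69.61, MET = 69.26, PHE = 93.31, PRO = 51.33,
  SER = 61.39, THR = 63.71, TRP = 106.70, TYR = 100.72, VAL = 62.37)

#' Build a residue interaction network from an ensemble
#'
#' In "ca_contact" mode an edge exists in a frame when the C-alpha distance
#' is within caCutoff; in "atom_interaction" mode when the interaction
#' strength I_ij = 100 n_ij / sqrt(N_i N_j) (n_ij: side-chain heavy-atom
#' pairs within atomCutoff, N_i a residue-type normalization) reaches iMin.
#' Edges present in at least occupancyMin of the frames are kept and receive
#' length w_ij = -log r_MI from the coupling matrix.
#'
#' @param frames an Ensemble (ca_contact) or list of AtomStructure
#'   (atom_interaction)
#' @param coupling a CouplingMatrix covering all residues
#' @param mode "ca_contact" (default) or "atom_interaction"
#' @param caCutoff C-alpha contact cutoff, A (default 7.5)
#' @param atomCutoff heavy-atom contact cutoff, A (default 4.5)
#' @param iMin interaction-strength threshold (default 3.0)
#' @param occupancyMin minimum frame occupancy (default 0.5, inclusive)
#' @param normTable residue-type normalization values (atom mode)
#' @return a ResidueGraph
#' @export
buildRin <- function(frames, coupling,
                     mode = c("ca_contact", "atom_interaction"),
                     caCutoff = 7.5, atomCutoff = 4.5, iMin = 3.0,
                     occupancyMin = 0.5, normTable = .rinNorm) {
  mode <- match.arg(mode)
  cm <- as.matrix(coupling)
  n <- nrow(cm)
  if (mode == "ca_contact") {
    if (!is(frames, "Ensemble")) stop("ca_contact mode needs an Ensemble",
                                      call. = FALSE)
    arr <- coords(frames)
    if (dim(arr)[2] != n)
      stop("residue count mismatch between frames and coupling",
           call. = FALSE)
    F <- dim(arr)[1]
    occ <- matrix(0, n, n)
    for (f in seq_len(F))
      occ <- occ + (as.matrix(dist(arr[f, , ])) <= caCutoff)
    occ <- occ / F
  } else {
    if (!is.list(frames) || !length(frames))
      stop("atom_interaction mode needs a non-empty list of AtomStructure",
           call. = FALSE)
    occ <- matrix(0, n, n)
    for (s in frames) {
      a <- s@atoms
      reskey <- paste(a$chain, a$resno, a$icode)
      resLevels <- unique(reskey)
      if (length(resLevels) != n)
        stop("residue count mismatch between frames and coupling",
             call. = FALSE)
      sc <- a$element != "H" & !(a$name %in% c("N", "CA", "C", "O"))
      strength <- matrix(0, n, n)
      idx <- which(sc)
      if (length(idx) > 1) {
        d <- as.matrix(dist(as.matrix(a[idx, c("x", "y", "z")])))
        ri <- match(reskey[idx], resLevels)
        close <- which(d <= atomCutoff & upper.tri(d), arr.ind = TRUE)
        for (r in seq_len(nrow(close))) {
          u <- ri[close[r, 1]]; v <- ri[close[r, 2]]
          if (u != v) strength[u, v] <- strength[v, u] <- strength[u, v] + 1
        }
      }
      rn <- a$resname[!duplicated(reskey)]
      norm <- normTable[rn]
      norm[is.na(norm)] <- mean(normTable)
      Iij <- 100 * strength / sqrt(outer(norm, norm))
      occ <- occ + (Iij >= iMin)
    }
    occ <- occ / length(frames)
  }
  diag(occ) <- 0
  keep <- which(occ >= occupancyMin & upper.tri(occ), arr.ind = TRUE)
  w <- edgeWeight(ifelse(is.na(cm[keep]), 0, cm[keep]))
  edges <- data.frame(i = keep[, 1], j = keep[, 2], w = w,
                      occupancy = occ[keep])
  new("ResidueGraph", edges = edges, n = as.integer(n),
      meta = list(mode = mode, ca_cutoff = caCutoff,
                  atom_cutoff = atomCutoff, I_min = iMin,
                  occupancy_min = occupancyMin))
}

#' Construct a ResidueGraph directly from an edge list
#'
#' @param n number of nodes
#' @param i,j edge endpoints (1-based)
#' @param w edge lengths (default 1)
#' @param occupancy edge occupancies (default 1)
#' @return a ResidueGraph
#' @export
residueGraph <- function(n, i, j, w = rep(1, length(i)),
                         occupancy = rep(1, length(i))) {
  new("ResidueGraph",
      edges = data.frame(i = pmin(i, j), j = pmax(i, j), w = w,
                         occupancy = occupancy),
      n = as.integer(n), meta = list(mode = "manual"))
}

.adjList <- function(g) {
  adj <- vector("list", g@n)
  e <- g@edges
  for (r in seq_len(nrow(e))) {
    adj[[e$i[r]]] <- rbind(adj[[e$i[r]]], c(e$j[r], e$w[r]))
    adj[[e$j[r]]] <- rbind(adj[[e$j[r]]], c(e$i[r], e$w[r]))
  }
  adj
}

#' All-pairs shortest paths with path counts
#'
#' Floyd-Warshall distances plus, per pair, the number of distinct shortest
#' paths g_jk (ties resolved with relative tolerance 1e-12 on path length).
#' Disconnected pairs have infinite distance and zero count.
#'
#' @param g a ResidueGraph with nonnegative edge lengths
#' @return a PathMatrix
#' @export
shortestPaths <- function(g) {
  n <- g@n
  D <- matrix(Inf, n, n); diag(D) <- 0
  e <- g@edges
  for (r in seq_len(nrow(e))) {
    D[e$i[r], e$j[r]] <- min(D[e$i[r], e$j[r]], e$w[r])
    D[e$j[r], e$i[r]] <- D[e$i[r], e$j[r]]
  }
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  adj <- .adjList(g)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    ds <- D[s, ]
    ord <- order(ds)
    cnt <- numeric(n); cnt[s] <- 1
    for (v in ord) {
      if (v == s || !is.finite(ds[v])) next
      av <- adj[[v]]
      if (is.null(av)) next
      tol <- 1e-12 * max(ds[v], 1e-300) + 1e-300
      pred <- av[abs(ds[av[, 1]] + av[, 2] - ds[v]) <= tol, 1]
      cnt[v] <- sum(cnt[pred])
    }
    sigma[s, ] <- cnt
  }
  new("PathMatrix", dist = D, counts = sigma)
}

.pathTol <- function(d) 1e-12 * pmax(d, 1e-300) + 1e-300

#' Node betweenness centrality by path counting
#'
#' C_b(i) = sum_{j < k, j != i != k} g_jk(i) / g_jk, the summed fractions of
#' shortest paths between all residue pairs passing through residue i
#' (unnormalized, weighted paths).
#'
#' @param g a ResidueGraph
#' @param paths optional precomputed PathMatrix
#' @return numeric vector of betweenness values
#' @export
nodeBetweenness <- function(g, paths = shortestPaths(g)) {
  n <- g@n
  D <- paths@dist; S <- paths@counts
  cb <- numeric(n)
  for (i in seq_len(n)) {
    through <- outer(D[, i], D[i, ], "+")
    ok <- is.finite(D) & abs(through - D) <= .pathTol(D) & S > 0
    ok[i, ] <- FALSE; ok[, i] <- FALSE; diag(ok) <- FALSE
    frac <- matrix(0, n, n)
    frac[ok] <- (outer(S[, i], S[i, ]) / S)[ok]
    cb[i] <- sum(frac[upper.tri(frac)])
  }
  cb
}

#' Edge betweenness by path counting
#'
#' Per edge, the summed fractions of each pair's shortest paths that traverse
#' the edge; the basis of the Girvan-Newman decomposition and of
#' edge-centrality distributions.
#'
#' @param g a ResidueGraph
#' @param paths optional precomputed PathMatrix
#' @return numeric vector, one value per row of g's edge list
#' @export
edgeBetweenness <- function(g, paths = shortestPaths(g)) {
  n <- g@n
  D <- paths@dist; S <- paths@counts
  e <- g@edges
  out <- numeric(nrow(e))
  for (r in seq_len(nrow(e))) {
    u <- e$i[r]; v <- e$j[r]; w <- e$w[r]
    t1 <- outer(D[, u] + w, D[v, ], "+")
    t2 <- outer(D[, v] + w, D[u, ], "+")
    n1 <- outer(S[, u], S[v, ])
    n2 <- outer(S[, v], S[u, ])
    used <- (abs(t1 - D) <= .pathTol(D)) * n1 +
            (abs(t2 - D) <= .pathTol(D)) * n2
    ok <- is.finite(D) & S > 0
    diag(ok) <- FALSE
    frac <- matrix(0, n, n)
    frac[ok] <- used[ok] / S[ok]
    out[r] <- sum(frac[upper.tri(frac)])
  }
  out
}

.components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(edges))) {
    ri <- find(as.integer(edges$i[r])); rj <- find(as.integer(edges$j[r]))
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_len(n), function(i) as.integer(find(i)), integer(1))
  match(roots, unique(roots))
}

.asIgraph <- function(g, affinity = TRUE) {
  e <- g@edges
  igraph::graph_from_data_frame(
    data.frame(from = e$i, to = e$j,
               weight = if (affinity) exp(-e$w) else e$w),
    directed = FALSE,
    vertices = data.frame(name = seq_len(g@n)))
}

#' Girvan-Newman community detection
#'
#' Iteratively removes the edge with the highest betweenness (recomputing
#' betweenness after every removal; ties broken by lexicographic edge id),
#' recording the partition at every component split, and returns the
#' partition maximizing Newman modularity.  Modularity uses the coupling
#' affinities exp(-w) as edge strengths, so strongly coupled edges count as
#' strong community ties while path lengths remain the -log weights.
#'
#' @param g a ResidueGraph
#' @return a CommunitySet (non-overlapping)
#' @export
girvanNewman <- function(g) {
  n <- g@n
  if (nrow(g@edges) == 0) {
    return(new("CommunitySet", communities = as.list(seq_len(n)),
               membership = seq_len(n), modularity = NA_real_,
               overlapping = FALSE, stability = NA_real_))
  }
  full <- .asIgraph(g)
  scoreQ <- function(memb)
    igraph::modularity(full, memb, weights = igraph::E(full)$weight)
  cur <- g
  best <- .components(n, g@edges)
  bestQ <- scoreQ(best)
  lastNc <- max(best)
  while (nrow(cur@edges) > 0) {
    eb <- edgeBetweenness(cur)
    top <- which(eb == max(eb))
    if (length(top) > 1) {
      ord <- order(cur@edges$i[top], cur@edges$j[top])
      top <- top[ord[1]]
    }
    cur@edges <- cur@edges[-top, , drop = FALSE]
    memb <- .components(n, cur@edges)
    if (max(memb) > lastNc) {
      lastNc <- max(memb)
      q <- scoreQ(memb)
      if (q > bestQ + 1e-12) { bestQ <- q; best <- memb }
    }
  }
  comms <- split(seq_len(n), best)
  new("CommunitySet", communities = unname(comms),
      membership = as.integer(best), modularity = bestQ,
      overlapping = FALSE, stability = NA_real_)
}

#' k-clique (clique percolation) communities
#'
#' Enumerates all k-cliques, links cliques sharing at least k-1 (default) or
#' k-2 nodes, and reports the node unions of the connected components of the
#' clique graph.  Communities may overlap.
#'
#' @param g a ResidueGraph
#' @param k clique size (>= 3)
#' @param share adjacency rule: "k-1" (standard clique percolation) or "k-2"
#' @return a CommunitySet (overlapping; empty when no k-clique exists)
#' @export
kCliqueCommunities <- function(g, k = 3, share = c("k-1", "k-2")) {
  share <- match.arg(share)
  if (k < 3) stop("k must be >= 3", call. = FALSE)
  ig <- .asIgraph(g)
  cl <- igraph::cliques(ig, min = k, max = k)
  cl <- lapply(cl, function(x) sort(as.integer(names(x))))
  if (!length(cl))
    return(new("CommunitySet", communities = list(),
               membership = rep(NA_integer_, g@n), modularity = NA_real_,
               overlapping = TRUE, stability = NA_real_))
  minShare <- if (share == "k-1") k - 1 else k - 2
  nc <- length(cl)
  ce <- data.frame(i = integer(0), j = integer(0))
  if (nc > 1) {
    pairs <- combn(nc, 2)
    hit <- apply(pairs, 2, function(p)
      length(intersect(cl[[p[1]]], cl[[p[2]]])) >= minShare)
    ce <- data.frame(i = pairs[1, hit], j = pairs[2, hit])
  }
  memb <- .components(nc, ce)
  comms <- lapply(split(seq_len(nc), memb), function(idx)
    sort(unique(unlist(cl[idx]))))
  new("CommunitySet", communities = unname(comms),
      membership = rep(NA_integer_, g@n), modularity = NA_real_,
      overlapping = TRUE, stability = NA_real_)
}

.jaccard <- function(a, b)
  length(intersect(a, b)) / length(union(a, b))

## similarity of two partitions: symmetrized mean best-match Jaccard
.partitionSim <- function(pa, pb) {
  f <- function(x, y) mean(vapply(x, function(cm)
    max(vapply(y, .jaccard, numeric(1), a = cm)), numeric(1)))
  (f(pa, pb) + f(pb, pa)) / 2
}

#' Cross-frame community stability
#'
#' A reference community (taken from the consensus frame, the frame whose
#' partition is most similar on average to all others) is stable if in more
#' than stabilityMin of the frames some community matches it with Jaccard
#' similarity at least matchJaccard.  Communities at exactly the threshold
#' are dropped (the rule is "more than").
#'
#' @param partitions list of CommunitySet, one per frame, on the same node set
#' @param stabilityMin stability threshold (default 0.75, exclusive)
#' @param matchJaccard community match threshold (default 0.6)
#' @return a CommunitySet of the stable consensus communities with their
#'   frequencies in the stability slot
#' @export
communityStability <- function(partitions, stabilityMin = 0.75,
                               matchJaccard = 0.6) {
  if (length(partitions) < 2)
    stop("need partitions from at least 2 frames", call. = FALSE)
  comms <- lapply(partitions, function(p) p@communities)
  nodeSets <- lapply(comms, function(cc) sort(unique(unlist(cc))))
  if (length(unique(vapply(nodeSets, paste, character(1), collapse = ","))) != 1)
    stop("frames cover different node sets", call. = FALSE)
  nf <- length(comms)
  sim <- vapply(seq_len(nf), function(a)
    mean(vapply(seq_len(nf)[-a], function(b)
      .partitionSim(comms[[a]], comms[[b]]), numeric(1))), numeric(1))
  consensus <- which.max(sim)
  ref <- comms[[consensus]]
  freq <- vapply(ref, function(cm)
    mean(vapply(comms, function(fr)
      any(vapply(fr, .jaccard, numeric(1), a = cm) >= matchJaccard),
      logical(1))), numeric(1))
  keep <- freq > stabilityMin
  new("CommunitySet", communities = ref[keep],
      membership = rep(NA_integer_, length(unlist(nodeSets[[1]]))),
      modularity = NA_real_, overlapping = FALSE,
      stability = freq[keep])
}

#' Write a residue graph as an edge-list TSV
#'
#' @param g a ResidueGraph
#' @param file output path
#' @export
writeGraph <- function(g, file) {
  write.table(g@edges, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(g@edges)
}
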