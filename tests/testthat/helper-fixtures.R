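## Shared fixtures and independent oracles for the test suite.

caTrace <- function(coords, resno = seq_len(nrow(coords))) {
  new("CaTrace",
      ids = data.frame(chain = "A", resno = as.integer(resno), icode = "",
                       stringsAsFactors = FALSE),
      resnames = rep("ALA", nrow(coords)),
      coords = unname(as.matrix(coords)))
}

collinearTrace <- function() caTrace(rbind(c(0, 0, 0), c(3.8, 0, 0),
                                           c(7.6, 0, 0)))

ringTrace <- function(n = 4, radius = 4) {
  th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  caTrace(cbind(radius * cos(th), radius * sin(th), 0))
}

## random connected weighted graph (edge lengths in (0.1, 1.1))
randomGraph <- function(n, p = 0.3) {
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  ## always include a random spanning chain so the graph is connected
  perm <- sample(n)
  chain <- cbind(perm[-n], perm[-1])
  a <- c(pairs[keep, 1], pmin(chain[, 1], chain[, 2]))
  b <- c(pairs[keep, 2], pmax(chain[, 1], chain[, 2]))
  lo <- pmin(a, b); hi <- pmax(a, b)
  dup <- duplicated(paste(lo, hi))
  lo <- lo[!dup]; hi <- hi[!dup]
  residueGraph(n, lo, hi, runif(length(lo), 0.1, 1.1))
}

## Dijkstra single-source oracle (binary search over unvisited, O(n^2))
dijkstra <- function(g, s) {
  n <- g@n
  e <- g@edges
  adj <- vector("list", n)
  for (r in seq_len(nrow(e))) {
    adj[[e$i[r]]] <- rbind(adj[[e$i[r]]], c(e$j[r], e$w[r]))
    adj[[e$j[r]]] <- rbind(adj[[e$j[r]]], c(e$i[r], e$w[r]))
  }
  dist <- rep(Inf, n); dist[s] <- 0
  done <- rep(FALSE, n)
  repeat {
    u <- which(!done & is.finite(dist))
    if (!length(u)) break
    u <- u[which.min(dist[u])]
    done[u] <- TRUE
    au <- adj[[u]]
    if (is.null(au)) next
    for (r in seq_len(nrow(au))) {
      v <- au[r, 1]
      if (dist[u] + au[r, 2] < dist[v]) dist[v] <- dist[u] + au[r, 2]
    }
  }
  dist
}

## exhaustive shortest-path enumeration: returns per-node and per-edge
## betweenness by listing every shortest path (tiny graphs only)
enumerateBetweenness <- function(g, tol = 1e-9) {
  n <- g@n
  e <- g@edges
  adj <- vector("list", n)
  for (r in seq_len(nrow(e))) {
    adj[[e$i[r]]] <- rbind(adj[[e$i[r]]], c(e$j[r], e$w[r]))
    adj[[e$j[r]]] <- rbind(adj[[e$j[r]]], c(e$i[r], e$w[r]))
  }
  D <- t(vapply(seq_len(n), function(s) dijkstra(g, s), numeric(n)))
  nodeB <- numeric(n)
  edgeB <- numeric(nrow(e))
  edgeKey <- paste(e$i, e$j)
  paths <- function(s, t) {
    ## all shortest s->t paths by DFS with distance pruning
    out <- list()
    walk <- function(v, path, len) {
      if (v == t) { out[[length(out) + 1]] <<- path; return() }
      av <- adj[[v]]
      for (r in seq_len(nrow(av))) {
        w <- av[r, 1]
        if (w %in% path) next
        nl <- len + av[r, 2]
        if (nl + D[w, t] <= D[s, t] + tol)
          walk(w, c(path, w), nl)
      }
    }
    walk(s, s, 0)
    out
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t])) next
    ps <- paths(s, t)
    np <- length(ps)
    for (p in ps) {
      if (length(p) > 2)
        for (v in p[-c(1, length(p))]) nodeB[v] <- nodeB[v] + 1 / np
      for (k in seq_len(length(p) - 1)) {
        ek <- paste(min(p[k], p[k + 1]), max(p[k], p[k + 1]))
        idx <- which(edgeKey == ek)
        edgeB[idx] <- edgeB[idx] + 1 / np
      }
    }
  }
  list(node = nodeB, edge = edgeB)
}

## all set partitions of 1..n (restricted growth strings)
allPartitions <- function(n) {
  out <- list()
  rec <- function(a, k) {
    if (length(a) == n) { out[[length(out) + 1]] <<- a; return() }
    for (v in seq_len(k + 1)) rec(c(a, v), max(k, v))
  }
  rec(integer(0), 0L)
  out
}

## random typed body-bar network (valid bar counts 2/5/6) plus the
## linear-algebra rank oracle for its internal degrees of freedom
randomBodyBar <- function(maxBodies = 6) {
  B <- sample(2:maxBodies, 1)
  pairs <- t(combn(B, 2))
  keep <- runif(nrow(pairs)) < 0.6
  pairs <- pairs[keep, , drop = FALSE]
  if (!nrow(pairs)) pairs <- matrix(c(1, 2), 1)
  bars <- sample(c(2L, 5L, 6L), nrow(pairs), TRUE)
  type <- c("2" = "hydrophobic", "5" = "covalent_rotatable",
            "6" = "covalent_locked")[as.character(bars)]
  atoms <- data.frame(element = "C", name = paste0("C", seq_len(B)),
                      resname = "XXX", chain = "A", resno = seq_len(B),
                      icode = "", x = runif(B) * 10, y = runif(B) * 10,
                      z = runif(B) * 10, stringsAsFactors = FALSE)
  new("ConstraintNetwork",
      bars = data.frame(i = pairs[, 1], j = pairs[, 2], bars = bars,
                        type = type, energy = NA_real_,
                        stringsAsFactors = FALSE),
      nBodies = as.integer(B), atoms = atoms, params = list())
}

## internal DOF of a body-bar network by generic rigidity-matrix rank
rankOracleDof <- function(net) {
  B <- net@nBodies
  bars <- net@bars
  xyz <- as.matrix(net@atoms[, c("x", "y", "z")])
  M <- NULL
  for (r in seq_len(nrow(bars))) {
    for (b in seq_len(bars$bars[r])) {
      i <- bars$i[r]; j <- bars$j[r]
      pa <- xyz[i, ] + runif(3, -1, 1)      # generic attachment points
      pb <- xyz[j, ] + runif(3, -1, 1)
      u <- pa - pb
      row <- numeric(6 * B)
      row[(6 * (i - 1) + 1):(6 * (i - 1) + 3)] <- u
      row[(6 * (i - 1) + 4):(6 * (i - 1) + 6)] <-
        c(pa[2] * u[3] - pa[3] * u[2],
          pa[3] * u[1] - pa[1] * u[3],
          pa[1] * u[2] - pa[2] * u[1])
      row[(6 * (j - 1) + 1):(6 * (j - 1) + 3)] <- -u
      row[(6 * (j - 1) + 4):(6 * (j - 1) + 6)] <-
        -c(pb[2] * u[3] - pb[3] * u[2],
           pb[3] * u[1] - pb[1] * u[3],
           pb[1] * u[2] - pb[2] * u[1])
      M <- rbind(M, row)
    }
  }
  rk <- if (is.null(M)) 0 else qr(M, tol = 1e-9)$rank
  ncomp <- max(AlloDyn:::.components(B, bars))
  6 * B - rk - 6 * ncomp
}

## cached long DMD run shared by the acceptance blocks
.acceptCache <- new.env(parent = emptyenv())
twoLobeLongRun <- function() {
  if (is.null(.acceptCache$run)) {
    trace <- makeTwoLobeToy(20, 20, seed = 1)
    model <- buildGoModel(trace)
    ens <- runDmd(model, trace, nEvents = 1e6, temperature = 1, nu = 1,
                  snapshotEvery = 1000, seed = 11)
    .acceptCache$run <- list(trace = trace, model = model, ensemble = ens)
  }
  .acceptCache$run
}

## constraint network between numbered bodies with given per-pair bar counts
bodyBarNet <- function(i, j, bars) {
  B <- max(i, j)
  type <- c("2" = "hydrophobic", "5" = "covalent_rotatable",
            "6" = "covalent_locked")[as.character(bars)]
  new("ConstraintNetwork",
      bars = data.frame(i = i, j = j, bars = as.integer(bars), type = type,
                        energy = NA_real_, stringsAsFactors = FALSE),
      nBodies = as.integer(B),
      atoms = data.frame(element = "C", name = paste0("C", seq_len(B)),
                         resname = "XXX", chain = "A", resno = seq_len(B),
                         icode = "", x = seq_len(B) * 2, y = 0, z = 0,
                         stringsAsFactors = FALSE),
      params = list())
}
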