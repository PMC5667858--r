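## Alignment handling, Kullback-Leibler column conservation, column mutual
## information, and the Gaussian generalized correlation coefficient r_MI
## used to weight residue-network edges (w_ij = -log r_MI).

## Swiss-Prot amino-acid background frequencies (fractions, sum to 1)
.aaBackground <- c(
  A = 0.0825, R = 0.0553, N = 0.0406, D = 0.0545, C = 0.0138,
  Q = 0.0393, E = 0.0675, G = 0.0707, H = 0.0227, I = 0.0596,
  L = 0.0966, K = 0.0584, M = 0.0242, F = 0.0386, P = 0.0470,
  S = 0.0656, T = 0.0534, W = 0.0108, Y = 0.0292, V = 0.0687)

#' Read an aligned FASTA file or text
#'
#' @param text character vector of FASTA lines, or a path to a file
#' @param ref index of the reference sequence (default 1)
#' @return an Msa
#' @export
readMsa <- function(text, ref = 1L) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    text <- readLines(text)
  lines <- .splitLines(text)
  hdr <- grep("^>", lines)
  if (length(hdr) < 2) stop("need at least 2 FASTA records", call. = FALSE)
  nm <- sub("^>\\s*", "", lines[hdr])
  ends <- c(hdr[-1] - 1, length(lines))
  seqs <- vapply(seq_along(hdr), function(k)
    paste(lines[(hdr[k] + 1):ends[k]], collapse = ""), character(1))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1)
    stop("ragged alignment: sequence lengths differ", call. = FALSE)
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  m[m == "."] <- "-"
  new("Msa", seqs = m, seqnames = nm, ref = as.integer(ref))
}

#' Write an Msa as aligned FASTA
#'
#' @param msa an Msa
#' @param file optional path; when NULL the lines are returned
#' @return character vector of FASTA lines
#' @export
writeMsa <- function(msa, file = NULL) {
  out <- as.vector(rbind(paste0(">", msa@seqnames),
                         apply(msa@seqs, 1, paste, collapse = "")))
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}

#' Filter an alignment by reference coverage
#'
#' Sequences covering less than minCoverage of the reference sequence's
#' non-gap columns are removed (strictly less: exactly 50\% is retained at
#' the default).  The reference itself is always kept.
#'
#' @param msa an Msa
#' @param minCoverage coverage threshold (default 0.5)
#' @return the filtered Msa
#' @export
filterMsa <- function(msa, minCoverage = 0.5) {
  refCols <- which(msa@seqs[msa@ref, ] != "-")
  if (!length(refCols)) stop("reference sequence is all gaps", call. = FALSE)
  cov <- rowMeans(msa@seqs[, refCols, drop = FALSE] != "-")
  keep <- cov >= minCoverage
  keep[msa@ref] <- TRUE
  if (sum(keep) < 2)
    stop("coverage filter removed all non-reference sequences", call. = FALSE)
  new("Msa", seqs = msa@seqs[keep, , drop = FALSE],
      seqnames = msa@seqnames[keep],
      ref = as.integer(which(which(keep) == msa@ref)))
}

#' Kullback-Leibler column conservation
#'
#' Per column, KL = sum_a P(a) ln(P(a)/Q(a)) over amino acids with P(a) > 0,
#' in nats; gaps are excluded from the counts.  A fully conserved column
#' against a uniform background scores ln 20.
#'
#' @param msa an Msa (coverage-filtered)
#' @param background named length-20 frequency vector Q; default: bundled
#'   Swiss-Prot amino-acid frequencies
#' @param pseudocount additive count alpha (default 0)
#' @return a ResidueProfile named "kl_conservation" (units nats), one value
#'   per alignment column
#' @export
klConservation <- function(msa, background = NULL, pseudocount = 0) {
  Q <- if (is.null(background)) .aaBackground else background
  Q <- Q / sum(Q)
  nc <- ncol(msa@seqs)
  kl <- numeric(nc)
  warned <- FALSE
  for (cc in seq_len(nc)) {
    col <- msa@seqs[, cc]
    col <- col[col %in% .AA20]
    if (!length(col)) {
      if (!warned) { warning("all-gap column(s): score 0"); warned <- TRUE }
      next
    }
    cnt <- table(factor(col, levels = .AA20)) + pseudocount
    P <- as.numeric(cnt) / sum(cnt)
    pos <- P > 0
    kl[cc] <- sum(P[pos] * log(P[pos] / Q[.AA20][pos]))
  }
  new("ResidueProfile", values = kl, name = "kl_conservation", units = "nats",
      ids = data.frame(chain = "A", resno = seq_len(nc), icode = "",
                       stringsAsFactors = FALSE))
}

## 1/cluster-size sequence weights at the given identity threshold
.sequenceWeights <- function(seqs, threshold = 0.62) {
  n <- nrow(seqs); nc <- ncol(seqs)
  w <- numeric(n)
  for (s in seq_len(n)) {
    same <- vapply(seq_len(n), function(t) {
      ok <- seqs[s, ] != "-" & seqs[t, ] != "-"
      if (!any(ok)) return(FALSE)
      sum(seqs[s, ok] == seqs[t, ok]) / nc >= threshold
    }, logical(1))
    w[s] <- 1 / sum(same)
  }
  w
}

#' Column mutual information of an alignment
#'
#' MI_xy = sum_ab P(a,b) ln[P(a,b) / (P(a) P(b))] in nats, with gaps
#' excluded pairwise (marginals recomputed from the gap-complete rows of
#' each pair).  The default Miller-Madow correction subtracts the
#' finite-sample bias (R-1)(C-1)/(2n) (R, C: observed alphabet sizes) and
#' floors the result at zero, so independent columns score near 0 rather
#' than near the ~0.036-nat bias of a raw 20x20 table at n = 5000.
#' Optional sequence weighting (1/cluster-size at 62\% identity) and APC
#' background correction MI - MI_x. MI_.y / MI_.. .
#'
#' @param msa an Msa
#' @param weighting apply sequence weights (default TRUE; the clustering is
#'   quadratic in the number of sequences)
#' @param apc apply the average-product correction (default FALSE)
#' @param biasCorrection subtract the Miller-Madow bias and floor at 0
#'   (default TRUE)
#' @param minPairs pairs of columns with fewer ungapped rows are NA
#'   (default 10)
#' @return a CouplingMatrix of kind "sequence_MI" (diagonal NA)
#' @export
columnMi <- function(msa, weighting = TRUE, apc = FALSE,
                     biasCorrection = TRUE, minPairs = 10) {
  seqs <- msa@seqs
  n <- nrow(seqs); nc <- ncol(seqs)
  if (n < 25) warning("fewer than 25 sequences: MI estimates will be noisy")
  w <- if (weighting) .sequenceWeights(seqs) else rep(1, n)
  ## per-column indicator matrices (rows zeroed at gaps)
  ind <- lapply(seq_len(nc), function(cc) {
    M <- matrix(0, n, 20)
    hit <- match(seqs[, cc], .AA20)
    ok <- !is.na(hit)
    M[cbind(which(ok), hit[ok])] <- 1
    M
  })
  mi <- matrix(NA_real_, nc, nc)
  for (a in seq_len(nc - 1)) for (b in (a + 1):nc) {
    ok <- rowSums(ind[[a]]) > 0 & rowSums(ind[[b]]) > 0
    if (sum(ok) < minPairs) next
    joint <- crossprod(ind[[a]] * (w * ok), ind[[b]])
    tot <- sum(joint)
    P <- joint / tot
    Pa <- rowSums(P); Pb <- colSums(P)
    pos <- P > 0
    v <- sum(P[pos] * log(P[pos] / outer(Pa, Pb)[pos]))
    if (biasCorrection) {
      nEff <- sum(ok)
      v <- max(0, v - (sum(Pa > 0) - 1) * (sum(Pb > 0) - 1) / (2 * nEff))
    }
    mi[a, b] <- mi[b, a] <- v
  }
  if (apc) {
    rowm <- rowMeans(mi, na.rm = TRUE)
    allm <- mean(mi[upper.tri(mi)], na.rm = TRUE)
    corr <- outer(rowm, rowm) / allm
    mi <- mi - corr
    diag(mi) <- NA_real_
  }
  new("CouplingMatrix", mat = mi, kind = "sequence_MI",
      meta = list(weighting = weighting, apc = apc, n_seq = n))
}

#' Generalized correlation coefficients from an ensemble
#'
#' Per-residue fluctuation vectors (after superposition onto the ensemble
#' mean) are treated as 3-D Gaussians: MI_ij = 1/2 ln[det C_i det C_j /
#' det C_ij] from the 3x3 marginal and 6x6 joint covariance blocks, and
#' r_MI = sqrt(1 - exp(-2 MI / 3)), clipped to [0, 1].  For a scalar
#' Gaussian pair with correlation rho this reduces exactly to |rho|.
#'
#' @param ensemble an Ensemble with >= 100 frames
#' @param fit superpose frames first (default TRUE)
#' @return a CouplingMatrix of kind "dynamic_rMI" (diagonal 1; singular
#'   pairs NA)
#' @export
dynamicRmi <- function(ensemble, fit = TRUE) {
  arr <- coords(ensemble)
  F <- dim(arr)[1]; n <- dim(arr)[2]
  if (F < 100) stop("need at least 100 frames", call. = FALSE)
  if (fit) {
    ref <- apply(arr, c(2, 3), mean)
    arr <- .superposeFrames(arr, ref)
    ref <- apply(arr, c(2, 3), mean)
    arr <- .superposeFrames(arr, ref)
  }
  mu <- apply(arr, c(2, 3), mean)
  X <- lapply(seq_len(n), function(i)
    sweep(arr[, i, ], 2, mu[i, ]))
  C <- lapply(X, cov)
  detC <- vapply(C, det, numeric(1))
  r <- matrix(NA_real_, n, n)
  diag(r) <- 1
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (detC[i] <= 0 || detC[j] <= 0) next
    Cij <- cov(cbind(X[[i]], X[[j]]))
    dij <- det(Cij)
    if (dij <= 0) next
    mi <- 0.5 * log(detC[i] * detC[j] / dij)
    if (mi < 0) mi <- 0
    r[i, j] <- r[j, i] <- min(1, sqrt(1 - exp(-2 * mi / 3)))
  }
  new("CouplingMatrix", mat = r, kind = "dynamic_rMI",
      meta = list(frames = F, estimator = "gaussian"))
}

#' Edge weight from a generalized correlation value
#'
#' w = -ln(max(r, floor)): perfectly coupled pairs get zero-length edges,
#' uncoupled pairs get long ones; the floor keeps weights finite at r = 0.
#'
#' @param r correlation value(s) in [0, 1]
#' @param floor lower clamp (default 1e-4)
#' @return nonnegative weight(s)
#' @export
edgeWeight <- function(r, floor = 1e-4) {
  if (any(!is.na(r) & (r < -1e-12 | r > 1 + 1e-12)))
    stop("r must lie in [0, 1]", call. = FALSE)
  -log(pmax(pmin(r, 1), floor))
}
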