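toyFasta <- c(">ref", "ACDEF", ">s2", "ACDE-", ">s3", "AC-EF")

test_that("FASTA alignments round-trip", {
  msa <- readMsa(toyFasta)
  expect_equal(nrow(msa@seqs), 3)
  expect_equal(ncol(msa@seqs), 5)
  expect_equal(msa@seqs[2, 5], "-")
  expect_identical(writeMsa(msa), toyFasta)
  expect_identical(readMsa(writeMsa(msa))@seqs, msa@seqs)

  expect_error(readMsa(c(">a", "ACD", ">b", "AC")), "ragged")
  expect_error(readMsa(c(">a", "ACD")), "at least 2")
})

test_that("coverage filter implements the strict <50% rule", {
  msa <- readMsa(c(">ref", "ACDEFGHIKL",
                   ">cov40", "ACDE------",   # 40%: removed
                   ">cov50", "ACDEF-----",   # exactly 50%: retained
                   ">full", "ACDEFGHIKL"))
  filt <- filterMsa(msa)
  expect_setequal(filt@seqnames, c("ref", "cov50", "full"))

  gapFree <- readMsa(c(">a", "ACDEF", ">b", "FEDCA"))
  expect_identical(filterMsa(gapFree)@seqs, gapFree@seqs)
})

test_that("KL conservation matches closed forms", {
  msa <- makeSyntheticMsa(2000, 12, conservedCols = c(4),
                          covaryingPairs = list(c(7, 9)), seed = 6)
  Q <- setNames(rep(1 / 20, 20), AlloDyn:::.AA20)
  kl <- profileValues(klConservation(msa, background = Q))
  expect_equal(kl[4], log(20), tolerance = 1e-9)
  ## conserved column is the top scorer
  expect_equal(which.max(kl), 4)

  ## P = Q exactly gives zero: each column holds every amino acid once
  m0 <- vapply(1:5, function(cc) AlloDyn:::.AA20[(seq_len(20) + cc) %% 20 + 1],
               character(20))
  msa0 <- new("Msa", seqs = m0, seqnames = paste0("s", 1:20), ref = 1L)
  kl0 <- profileValues(klConservation(msa0, background = Q))
  expect_equal(max(abs(kl0)), 0, tolerance = 1e-12)

  allGap <- new("Msa", seqs = cbind(rep("-", 10), rep("A", 10)),
                seqnames = paste0("s", 1:10), ref = 1L)
  expect_warning(klg <- klConservation(allGap, background = Q), "all-gap")
  expect_equal(profileValues(klg)[1], 0)
})

test_that("column MI recovers the planted coupling", {
  msa <- makeSyntheticMsa(5000, 25, covaryingPairs = list(c(6, 19)),
                          seed = 8)
  mi <- columnMi(msa, weighting = FALSE)
  m <- mi@mat
  expect_lt(max(abs(m - t(m)), na.rm = TRUE), 1e-12)
  expect_true(all(is.na(diag(m))))
  expect_equal(m[6, 19], log(2), tolerance = 0.05 * log(2))
  top <- which(m == max(m, na.rm = TRUE), arr.ind = TRUE)[1, ]
  expect_setequal(unname(sort(top)), c(6, 19))
  ## unplanted pairs carry only finite-sample bias
  off <- m[upper.tri(m)]
  off <- off[off < 0.5]                      # drop the planted pair
  expect_lt(max(off, na.rm = TRUE), 0.02)
})

test_that("MI respects gap exclusion and sequence weighting", {
  ## pair with fewer than 10 ungapped rows is flagged missing
  seqs <- matrix("A", 12, 3)
  seqs[, 2] <- c(rep("-", 8), "L", "I", "L", "I")
  seqs[, 3] <- c("V", "A")[1 + (seq_len(12) %% 2)]
  msa <- new("Msa", seqs = seqs, seqnames = paste0("s", 1:12), ref = 1L)
  mi <- suppressWarnings(columnMi(msa, weighting = FALSE))
  expect_true(is.na(mi@mat[1, 2]))
  expect_false(is.na(mi@mat[1, 3]))

  ## duplicating a sequence block changes unweighted MI but weighting
  ## suppresses the redundancy
  set.seed(13)
  base <- makeSyntheticMsa(60, 8, seed = 13)@seqs
  dup <- rbind(base, base[rep(1, 60), ])
  msaD <- new("Msa", seqs = dup, seqnames = paste0("s", seq_len(120)),
              ref = 1L)
  w <- AlloDyn:::.sequenceWeights(dup)
  expect_lt(sum(w[61:120]), 62)              # the clones share weight
  expect_equal(w[2], 1)
})

test_that("generalized correlation matches the Gaussian closed form", {
  ## pair of residues correlated with rho on every axis:
  ## MI = -(3/2) ln(1 - rho^2) and r_MI = rho exactly
  rho <- 0.8
  F <- 10000
  set.seed(17)
  s <- matrix(rnorm(F * 3), F, 3)
  arr <- array(0, c(F, 2, 3))
  arr[, 1, ] <- sqrt(rho) * s + sqrt(1 - rho) * matrix(rnorm(F * 3), F, 3)
  arr[, 2, ] <- sqrt(rho) * s + sqrt(1 - rho) * matrix(rnorm(F * 3), F, 3)
  tr <- caTrace(rbind(c(0, 0, 0), c(3.8, 0, 0)))
  ens <- new("Ensemble", coords = arr, times = seq_len(F), ids = tr@ids,
             resnames = tr@resnames, provenance = list())
  r <- dynamicRmi(ens, fit = FALSE)
  expect_equal(r@mat[1, 2], rho, tolerance = 0.01)
  expect_equal(diag(r@mat), c(1, 1))

  ## plug-in oracle: MI from the planted covariance blocks
  Ci <- diag(3); Cij <- diag(6)
  Cij[cbind(1:3, 4:6)] <- rho; Cij[cbind(4:6, 1:3)] <- rho
  miTrue <- 0.5 * log(det(Ci) * det(Ci) / det(Cij))
  rTrue <- sqrt(1 - exp(-2 * miTrue / 3))
  expect_equal(r@mat[1, 2], rTrue, tolerance = 0.01)

  expect_error(dynamicRmi(
    new("Ensemble", coords = arr[1:50, , ], times = 1:50, ids = tr@ids,
        resnames = tr@resnames, provenance = list())), "100")
})

test_that("r_MI equals |Pearson| for matched Gaussian projections", {
  rho <- 0.6
  F <- 20000
  set.seed(23)
  s <- matrix(rnorm(F * 3), F, 3)
  arr <- array(0, c(F, 2, 3))
  arr[, 1, ] <- sqrt(rho) * s + sqrt(1 - rho) * matrix(rnorm(F * 3), F, 3)
  arr[, 2, ] <- sqrt(rho) * s + sqrt(1 - rho) * matrix(rnorm(F * 3), F, 3)
  tr <- caTrace(rbind(c(0, 0, 0), c(3.8, 0, 0)))
  ens <- new("Ensemble", coords = arr, times = seq_len(F), ids = tr@ids,
             resnames = tr@resnames, provenance = list())
  r <- dynamicRmi(ens, fit = FALSE)@mat[1, 2]
  pearson <- abs(cor(arr[, 1, 1], arr[, 2, 1]))
  expect_gte(r + 0.02, pearson)
  expect_equal(r, pearson, tolerance = 0.03)
})

test_that("edge weights follow w = -log r with a floor", {
  expect_equal(edgeWeight(1), 0)
  expect_equal(edgeWeight(exp(-1)), 1)
  expect_equal(edgeWeight(0), -log(1e-4), tolerance = 1e-12)
  expect_error(edgeWeight(1.5), "\\[0, 1\\]")
  expect_error(edgeWeight(-0.2), "\\[0, 1\\]")
})
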