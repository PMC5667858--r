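pdbLines <- function() c(
  "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
  "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
  "ATOM      3  CA  ALA A   3       7.600   0.000   0.000  1.00  0.00           C")

test_that("readPdb parses ATOM records and MODEL blocks", {
  s <- readPdb(pdbLines())
  expect_length(s, 1)
  expect_equal(nrow(s[[1]]@atoms), 3)
  expect_equal(s[[1]]@atoms$x, c(0, 3.8, 7.6))
  expect_equal(s[[1]]@atoms$resno, 1:3)

  multi <- c("MODEL        1", pdbLines(), "ENDMDL",
             "MODEL        2", pdbLines(), "ENDMDL", "END")
  s2 <- readPdb(multi)
  expect_length(s2, 2)
  expect_equal(s2[[1]]@atoms$resno, s2[[2]]@atoms$resno)
})

test_that("readPdb rejects malformed input with the offending line", {
  expect_error(readPdb("REMARK nothing here"), "no ATOM records")
  bad <- pdbLines()
  bad[2] <- substr(bad[2], 1, 40)             # truncated before z
  expect_error(readPdb(bad), "line 2")
})

test_that("HETATM records are skipped unless requested", {
  lines <- c(pdbLines(),
    "HETATM    4  O   HOH A  90      20.000  20.000  20.000  1.00  0.00           O")
  expect_equal(nrow(readPdb(lines)[[1]]@atoms), 3)
  expect_equal(nrow(readPdb(lines, keepHetatm = TRUE)[[1]]@atoms), 4)
})

test_that("extractCaTrace keeps residue order and handles missing CA", {
  s <- readPdb(pdbLines())[[1]]
  tr <- extractCaTrace(s, chain = "A")
  expect_equal(nResidues(tr), 3)
  expect_equal(coords(tr), rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0)))

  s2 <- s
  s2@atoms$name[2] <- "CB"                    # residue 2 loses its CA
  ## the skip is warned about, and so is the resulting 7.6 A chain gap
  expect_warning(expect_warning(tr2 <- extractCaTrace(s2), "skipped"),
                 "chain break")
  expect_equal(nResidues(tr2), 2)

  expect_error(extractCaTrace(s, chain = "Z"), "no atoms")
})

test_that("superpose recovers rigid motions and is idempotent", {
  set.seed(1)
  ref <- matrix(rnorm(15, sd = 4), 5, 3)
  fit <- superpose(ref, ref)
  expect_lt(fit$rmsd, 1e-12)

  th <- pi / 2
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  mob <- ref %*% t(R) + 5
  fit2 <- superpose(mob, ref)
  expect_lt(fit2$rmsd, 1e-9)
  expect_equal(fit2$coords, ref, tolerance = 1e-9)

  again <- superpose(fit2$coords, ref)
  expect_lt(abs(again$rmsd - fit2$rmsd), 1e-9)

  expect_error(superpose(ref[1:4, ], ref), "differ in size")
})

test_that("superpose matches a brute-force rotation grid on a planar case", {
  ## 4 points in the z = 0 plane, one displaced by 1 A: the optimal proper
  ## rotation is about z, so a 1-degree grid over that angle is an oracle
  ref <- rbind(c(2, 0, 0), c(0, 2, 0), c(-2, 0, 0), c(0, -2, 0))
  mob <- ref
  mob[1, ] <- mob[1, ] + c(1, 0, 0)
  refC <- sweep(ref, 2, colMeans(ref))
  mobC <- sweep(mob, 2, colMeans(mob))
  gridRmsd <- vapply(seq(0, 359.5, by = 0.5) * pi / 180, function(th) {
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    sqrt(mean(rowSums((mobC %*% t(R) - refC)^2)))
  }, numeric(1))
  fit <- superpose(mob, ref)
  expect_equal(fit$rmsd, min(gridRmsd), tolerance = 1e-3)
  expect_lte(fit$rmsd, min(gridRmsd) + 1e-9)
})

test_that("B-factors follow the fluctuation arithmetic", {
  tr <- collinearTrace()
  arr <- array(0, c(4, 3, 3))
  for (f in 1:4) arr[f, , ] <- coords(tr)
  ens <- new("Ensemble", coords = arr, times = 1:4, ids = tr@ids,
             resnames = tr@resnames, provenance = list())
  expect_equal(profileValues(computeBfactors(ens)), rep(0, 3))

  ## residue 2 alternates x = +/- 1 about its mean, fitting disabled:
  ## <dr^2> = 1 so B = 8 pi^2 / 3
  arr2 <- arr
  arr2[c(1, 3), 2, 1] <- arr[c(1, 3), 2, 1] + 1
  arr2[c(2, 4), 2, 1] <- arr[c(2, 4), 2, 1] - 1
  ens2 <- new("Ensemble", coords = arr2, times = 1:4, ids = tr@ids,
              resnames = tr@resnames, provenance = list())
  b <- profileValues(computeBfactors(ens2, fit = FALSE))
  expect_equal(b[2], 8 * pi^2 / 3, tolerance = 1e-12)
  expect_equal(b[c(1, 3)], c(0, 0))

  expect_error(computeBfactors(
    new("Ensemble", coords = arr[1, , , drop = FALSE], times = 1,
        ids = tr@ids, resnames = tr@resnames, provenance = list())),
    "2 frames")
})

test_that("B-factors recover isotropic jitter and ignore rigid motion", {
  set.seed(7)
  tr <- caTrace(matrix(rnorm(15, sd = 6), 5, 3))
  F <- 10000
  arr <- array(0, c(F, 5, 3))
  for (f in seq_len(F))
    arr[f, , ] <- coords(tr) + matrix(rnorm(15, sd = 0.5), 5, 3)
  ens <- new("Ensemble", coords = arr, times = seq_len(F), ids = tr@ids,
             resnames = tr@resnames, provenance = list())
  b <- profileValues(computeBfactors(ens, fit = FALSE))
  expect_equal(mean(b), 8 * pi^2 / 3 * 0.75, tolerance = 0.05)

  ## a global rigid-body motion applied to every frame is removed by fitting
  sub <- arr[1:200, , , drop = FALSE]
  ens0 <- new("Ensemble", coords = sub, times = 1:200, ids = tr@ids,
              resnames = tr@resnames, provenance = list())
  b0 <- profileValues(computeBfactors(ens0))
  moved <- sub
  for (f in 1:200) {
    th <- f / 50
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    moved[f, , ] <- sub[f, , ] %*% t(R) + f * 0.1
  }
  ensM <- new("Ensemble", coords = moved, times = 1:200, ids = tr@ids,
              resnames = tr@resnames, provenance = list())
  bM <- profileValues(computeBfactors(ensM))
  ## two-pass mean-structure fitting removes the rigid motion to ~1e-4
  ## relative; exact invariance would need iterating the fit to convergence
  expect_equal(bM, b0, tolerance = 1e-3)
})

test_that("trajectory writers round-trip", {
  tr <- collinearTrace()
  arr <- array(rnorm(2 * 3 * 3, sd = 0.01), c(2, 3, 3))
  arr[1, , ] <- arr[1, , ] + coords(tr)
  arr[2, , ] <- arr[2, , ] + coords(tr)
  ens <- new("Ensemble", coords = arr, times = 1:2, ids = tr@ids,
             resnames = tr@resnames, provenance = list())

  pdb <- writeTrajectory(ens, "pdb")
  expect_equal(sum(grepl("^MODEL", pdb)), 2)
  back <- readPdb(pdb)
  expect_length(back, 2)
  expect_equal(back[[2]]@atoms$x, arr[2, , 1], tolerance = 1e-3)

  xyz <- writeTrajectory(ens, "xyz")
  expect_length(xyz, 2 * (3 + 2))
  arr2 <- readXyz(xyz)
  expect_equal(arr2, arr, tolerance = 1e-3)

  expect_error(writeTrajectory(ens, "dcd"))
})

test_that("readPdb agrees with bio3d on a written model", {
  skip_if_not_installed("bio3d")
  tr <- makeHelix(8)
  arr <- array(coords(tr), c(1, 8, 3))
  ens <- new("Ensemble", coords = arr, times = 1, ids = tr@ids,
             resnames = tr@resnames, provenance = list())
  f <- tempfile(fileext = ".pdb")
  writeTrajectory(ens, "pdb", file = f)
  ours <- readPdb(readLines(f))[[1]]
  ref <- bio3d::read.pdb(f)
  expect_equal(ours@atoms$x, unname(ref$atom$x), tolerance = 1e-6)
  expect_equal(ours@atoms$resno, unname(ref$atom$resno))
})
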