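## minimal hand-built structure: donor N-H ... O acceptor
hbondProbe <- function(d = 2.8, theta = 180) {
  ## N at origin, H along +x; acceptor placed so the D-H...A angle is theta
  ## N at origin, H at (1,0,0); acceptor in the xy-plane at donor-acceptor
  ## distance d with D-H...A angle theta: A = H + t u, u at angle
  ## (180 - theta) to +x, t the positive root of |H + t u| = d
  th <- theta * pi / 180
  H <- c(1.0, 0, 0)
  u <- c(cos(pi - th), sin(pi - th), 0)
  b <- sum(H * u); cc <- sum(H^2) - d^2
  t <- -b + sqrt(b^2 - cc)
  A <- H + t * u
  atoms <- data.frame(
    element = c("N", "H", "O", "C"),
    name = c("N", "H", "O", "C"),
    resname = c("GLY", "GLY", "GLY", "GLY"),
    chain = "A", resno = c(1L, 1L, 5L, 5L), icode = "",
    x = c(0, H[1], A[1], A[1] + 1.23),
    y = c(0, H[2], A[2], A[2]),
    z = 0, stringsAsFactors = FALSE)
  new("AtomStructure", atoms = atoms,
      bonds = data.frame(i = c(1L, 3L), j = c(2L, 4L),
                         rotatable = c(FALSE, FALSE)),
      model = 1L)
}

test_that("hydrogen-bond energies follow the distance-angle form", {
  ideal <- detectHbonds(hbondProbe(2.8, 180))
  expect_equal(nrow(ideal), 1)
  expect_equal(ideal$energy, -8, tolerance = 1e-6)

  perp <- detectHbonds(hbondProbe(2.8, 90))
  expect_true(nrow(perp) == 0 || all(perp$energy >= -1e-9))

  ## at the 3.6 A candidate limit the distance term gives
  ## 8 (5 (2.8/3.6)^12 - 6 (2.8/3.6)^10) = -1.9305 kcal/mol
  atLimit <- detectHbonds(hbondProbe(3.6, 180))
  expect_equal(atLimit$energy,
               8 * (5 * (2.8 / 3.6)^12 - 6 * (2.8 / 3.6)^10),
               tolerance = 1e-9)
  expect_equal(nrow(detectHbonds(hbondProbe(3.7, 180))), 0)
})

test_that("hydrophobic tethers use vdW radii plus the 0.25 A margin", {
  mk <- function(e1, e2, d) new("AtomStructure", atoms = data.frame(
    element = c(e1, e2), name = c("CB", "CB"), resname = "ALA",
    chain = "A", resno = 1:2, icode = "", x = c(0, d), y = 0, z = 0,
    stringsAsFactors = FALSE),
    bonds = data.frame(i = integer(0), j = integer(0),
                       rotatable = logical(0)), model = 1L)
  expect_equal(nrow(detectHydrophobic(mk("C", "C", 3.60))), 1)  # <= 3.65
  expect_equal(nrow(detectHydrophobic(mk("C", "C", 3.70))), 0)
  expect_equal(nrow(detectHydrophobic(mk("C", "S", 3.74))), 1)  # <= 3.75
})

test_that("constraint network assigns bars by interaction type", {
  ethane <- new("AtomStructure", atoms = data.frame(
    element = c("C", "C"), name = c("C1", "C2"), resname = "ETH",
    chain = "A", resno = c(1L, 1L), icode = "", x = c(0, 1.54), y = 0,
    z = 0, stringsAsFactors = FALSE),
    bonds = data.frame(i = 1L, j = 2L, rotatable = TRUE), model = 1L)
  net <- buildConstraintNetwork(ethane,
    hbonds = data.frame(donor = integer(0), hydrogen = integer(0),
                        acceptor = integer(0), dist = numeric(0),
                        angle = numeric(0), energy = numeric(0)),
    tethers = data.frame(i = integer(0), j = integer(0),
                         dist = numeric(0)))
  expect_equal(net@bars$bars, 5L)

  ## peptide C-N bonds are locked (6 bars) in the helix fixture
  helix <- makeAllAtomHelix(8)
  netH <- buildConstraintNetwork(helix)
  a <- helix@atoms
  pep <- netH@bars[a$name[netH@bars$i] == "C" & a$name[netH@bars$j] == "N" |
                   a$name[netH@bars$i] == "N" & a$name[netH@bars$j] == "C", ]
  expect_true(all(pep$bars == 6L))

  ## a weak hydrogen bond stays out of the network
  weak <- data.frame(donor = 1L, hydrogen = 1L, acceptor = 2L,
                     dist = 3, angle = 150, energy = -0.5)
  net2 <- buildConstraintNetwork(ethane, hbonds = weak,
    tethers = data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  expect_false("hbond" %in% net2@bars$type)
})

test_that("pebble game counts degrees of freedom on canonical cases", {
  d6 <- pebbleGame(bodyBarNet(1, 2, 6))
  expect_equal(length(d6@sizes), 1L)
  expect_equal(d6@dof, 0L)
  expect_equal(d6@freePebbles, 6L)

  d5 <- pebbleGame(bodyBarNet(1, 2, 5))
  expect_equal(length(d5@sizes), 2L)
  expect_equal(d5@dof, 1L)
  expect_equal(d5@freePebbles, 7L)

  chain <- pebbleGame(bodyBarNet(c(1, 2), c(2, 3), c(5, 5)))
  expect_equal(chain@dof, 2L)
  expect_equal(length(chain@sizes), 3L)
  expect_true(all(chain@sizes == 1L))
})

test_that("pebble game DOF equals the rigidity-matrix rank oracle", {
  set.seed(41)
  for (trial in 1:200) {
    net <- randomBodyBar(6)
    expect_equal(pebbleGame(net)@dof, as.integer(rankOracleDof(net)),
                 info = sprintf("trial %d", trial))
  }
})

test_that("decomposition is invariant to body enumeration order", {
  set.seed(43)
  for (trial in 1:10) {
    net <- randomBodyBar(6)
    B <- net@nBodies
    perm <- sample(B)
    bars2 <- net@bars
    bars2$i <- perm[net@bars$i]; bars2$j <- perm[net@bars$j]
    sw <- bars2$i > bars2$j
    tmp <- bars2$i[sw]; bars2$i[sw] <- bars2$j[sw]; bars2$j[sw] <- tmp
    net2 <- new("ConstraintNetwork", bars = bars2, nBodies = net@nBodies,
                atoms = net@atoms[order(perm), ], params = net@params)
    d1 <- pebbleGame(net)
    d2 <- pebbleGame(net2)
    expect_equal(d1@dof, d2@dof)
    expect_equal(sort(d1@sizes), sort(d2@sizes))
    ## same partition up to relabeling
    expect_equal(length(unique(paste(d1@labels,
                                     d2@labels[perm]))),
                 length(unique(d1@labels)))
  }
})

test_that("removing a constraint never tightens the network", {
  set.seed(47)
  for (trial in 1:20) {
    net <- randomBodyBar(6)
    if (nrow(net@bars) < 2) next
    d0 <- pebbleGame(net)
    drop <- sample(nrow(net@bars), 1)
    net2 <- new("ConstraintNetwork", bars = net@bars[-drop, , drop = FALSE],
                nBodies = net@nBodies, atoms = net@atoms,
                params = net@params)
    d1 <- pebbleGame(net2)
    ## free pebbles (uncovered DOF) never decrease on removal; internal DOF
    ## can drop only through the 6-per-component rigid-body bookkeeping
    ## when the removal disconnects the bar graph
    expect_gte(d1@freePebbles, d0@freePebbles)
    expect_lte(max(d1@sizes), max(d0@sizes))
    c0 <- max(AlloDyn:::.components(net@nBodies, net@bars))
    c1 <- max(AlloDyn:::.components(net@nBodies, net2@bars))
    if (c0 == c1) expect_gte(d1@dof, d0@dof)
  }
})

test_that("helix dilution is monotone with a deterministic removal order", {
  helix <- makeAllAtomHelix(12)
  net <- buildConstraintNetwork(helix)
  dil <- hbDilution(net)
  expect_true(all(diff(dil@giantSize) <= 0))
  expect_equal(nrow(dil@order), 8)
  ## degenerate energies: order falls back to atom index, reproducibly
  dil2 <- hbDilution(net)
  expect_identical(dil@order, dil2@order)
  expect_identical(dil@weakSpots, dil2@weakSpots)
  ## weakest first: removal energies are non-increasing
  expect_true(all(diff(dil@order$energy) <= 1e-12))

  ## weak spots are the residues shed at the largest giant-cluster drop
  drops <- -diff(dil@giantSize)
  expect_equal(dil@transition, which.max(drops))
  expect_gt(length(dil@weakSpots), 0)
})

test_that("a purely covalent giant cluster yields no transition", {
  ring <- bodyBarNet(c(1, 2, 3), c(2, 3, 1), c(6, 6, 6))
  expect_warning(dil <- hbDilution(ring), "no hydrogen bonds")
  expect_length(dil@weakSpots, 0)
})

test_that("weak-spot frequencies count and rank over conformers", {
  mk <- function(ws) new("DilutionResult",
    order = data.frame(), giantSize = c(10L, 5L), transition = 1L,
    weakSpots = as.integer(ws))
  single <- weakSpotFrequency(list(mk(c(2, 3))), nRes = 5)
  expect_setequal(unique(single@frequency), c(0, 1))

  two <- weakSpotFrequency(list(mk(1), mk(4)), nRes = 5)
  expect_equal(two@frequency[c(1, 4)], c(0.5, 0.5))

  three <- weakSpotFrequency(list(mk(2), mk(c(2, 5)), mk(3)), nRes = 5)
  expect_equal(three@frequency[2], 2 / 3)
  expect_equal(three@rank[2], 1L)

  expect_error(weakSpotFrequency(list(mk(9)), nRes = 5), "inconsistent")
})
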