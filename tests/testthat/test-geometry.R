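## Distance profiles, straightness, coverage, and pair enumeration against
## the brute-force oracle.

test_that("distance profile matches a brute-force loop and handles rigid shifts", {
  a <- cbind(3.4 * (0:6), 0, 0)
  expect_equal(distanceProfile(a, sweep(a, 2, c(4.8, 0, 0), "+")),
               rep(4.8, 7))
  expect_equal(distanceProfile(matrix(0, 1, 3), matrix(0, 1, 3)), 0)
  set.seed(42)
  b <- a + matrix(rnorm(21), ncol = 3)
  manual <- vapply(1:7, function(k) sqrt(sum((a[k, ] - b[k, ])^2)), numeric(1))
  expect_equal(distanceProfile(a, b), manual)
  expect_error(distanceProfile(a, b[1:3, ]), "equal length")
})

test_that("straightness is 1 for collinear points and 2/pi for a dense semicircle", {
  expect_equal(straightness(cbind(3.4 * (0:5), 0, 0)), 1.0)
  ## dense semicircular arc: polyline contour converges to the half
  ## circumference, so the ratio converges to diameter / (pi R) = 2/pi
  th <- seq(0, pi, length.out = 4001)
  R <- 10
  expect_equal(straightness(cbind(R * cos(th), R * sin(th), 0)), 2 / pi,
               tolerance = 1e-6)
  ## 10-point semicircle: exact discrete closed form 2 / (9 * 2 * sin(pi/18))
  th10 <- seq(0, pi, length.out = 10)
  expect_equal(straightness(cbind(R * cos(th10), R * sin(th10), 0)),
               (2 * R) / (9 * 2 * R * sin(pi / 18)))
  ## ideal alpha-helix trace falls below the default threshold
  i <- 0:11
  helix <- cbind(1.5 * i, 2.3 * cos(i * 100 * pi / 180),
                 2.3 * sin(i * 100 * pi / 180))
  expect_lt(straightness(helix), 0.9)
  expect_error(straightness(helix[1, , drop = FALSE]), ">= 2")
})

test_that("coverage criterion is inclusive at exactly one seventh", {
  expect_true(coverageFilter(2, 14, 14))
  expect_false(coverageFilter(1, 14, 14))
  expect_false(coverageFilter(10, 80, 80))
  ## either-chain rule vs both-chain rule
  expect_true(coverageFilter(3, 14, 80))
  expect_false(coverageFilter(3, 14, 80, GeometryParams(coverageBoth = TRUE)))
})

test_that("a planted two-strand sheet yields exactly one maximal pair", {
  spec <- sheetSpec(strrep("A", 14), 4, 7, nChains = 2)
  s <- generateParallelSheet(spec)
  pp <- findParallelPairs(s)
  expect_equal(nrow(pp), 1)
  expect_equal(pp$start_a, 4)
  expect_equal(pp$start_b, 4)
  expect_equal(pp$length, 7)
  expect_equal(pp$mean_distance, 4.8, tolerance = 1e-9)
  expect_equal(pp$distance_sd, 0, tolerance = 1e-6)
  expect_identical(bfPairs(s)[, c("chain_a", "start_a", "chain_b", "start_b",
                                  "length")],
                   pp[, c("chain_a", "start_a", "chain_b", "start_b", "length")])
})

test_that("hairpins, distant strands and anti-parallel sheets are rejected", {
  hair <- generateDecoy("hairpin")
  expect_equal(nrow(findParallelPairs(hair)), 0)
  far <- generateDecoy("far_pair")
  expect_equal(nrow(findParallelPairs(far)), 0)
  expect_equal(nrow(bfPairs(far)), 0)
  anti <- generateDecoy("antiparallel_pair")
  expect_equal(nrow(findParallelPairs(anti)), 0)
})

test_that("chain breaks terminate segments", {
  ## a numbering gap in the middle of an otherwise perfect sheet
  a <- makeChain(cbind(3.4 * (0:9), 0, 0), resno = c(1:5, 7:11))
  b <- makeChain(cbind(3.4 * (0:9), 0, 4.8), resno = c(1:5, 7:11))
  s <- makeStructure(list(A = a, B = b))
  pp <- findParallelPairs(s)
  expect_true(all(pp$length <= 5))
  expect_equal(nrow(pp), 2)  # one maximal run on each side of the gap
  ## a long CA-CA step does the same
  xyz <- cbind(3.4 * (0:9), 0, 0); xyz[6:10, 1] <- xyz[6:10, 1] + 2
  s2 <- makeStructure(list(A = makeChain(xyz),
                           B = makeChain(cbind(xyz[, 1], 0, 4.8))))
  expect_true(all(findParallelPairs(s2)$length <= 5))
})

test_that("detection is invariant under rigid-body transforms", {
  spec <- sheetSpec("GAQKLVFFAEDGA", 4, 7, nChains = 3, noiseSD = 0.2, seed = 5)
  s <- generateParallelSheet(spec)
  ref <- findParallelPairs(s)
  ## rotation about an arbitrary axis plus translation
  th <- 0.83
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Rx <- rbind(c(1, 0, 0), c(0, cos(1.1), -sin(1.1)), c(0, sin(1.1), cos(1.1)))
  Rot <- Rz %*% Rx
  moved <- s
  for (cid in chainIDs(s)) {
    ch <- moved@models[[1]][[cid]]
    xyz <- as.matrix(ch[, c("x", "y", "z")]) %*% t(Rot)
    xyz <- sweep(xyz, 2, c(12.3, -45.6, 7.8), "+")
    moved@models[[1]][[cid]][, c("x", "y", "z")] <- xyz
  }
  got <- findParallelPairs(moved)
  expect_identical(got[, c("chain_a", "start_a", "chain_b", "start_b", "length")],
                   ref[, c("chain_a", "start_a", "chain_b", "start_b", "length")])
  expect_equal(unlist(got$distances), unlist(ref$distances), tolerance = 1e-6)
})

test_that("pair enumeration agrees with brute force on random small structures", {
  params <- GeometryParams()
  for (seed in 1:60) {
    s <- randomSmallStructure(seed)
    got <- findParallelPairs(s, params)
    want <- bfPairs(s, params)
    expect_identical(
      got[, c("chain_a", "start_a", "chain_b", "start_b", "length")], want,
      label = paste("seed", seed))
  }
})

test_that("offset scanning recovers the in-register pairing of index-shifted chains", {
  ## chain B carries one extra N-terminal residue, so its strand is shifted
  ## by one index position relative to A
  a <- makeChain(cbind(3.4 * (0:7), 0, 0))
  b <- makeChain(rbind(c(-60, 40, 0), cbind(3.4 * (0:7), 0, 4.8)))
  s <- makeStructure(list(A = a, B = b))
  ## default in-register enumeration only sees the skewed offset-0 pairing
  def <- findParallelPairs(s)
  expect_true(all(def$start_b == def$start_a))
  expect_true(all(def$mean_distance > 5.5))
  scan <- GeometryParams(offsetScan = 2L)
  pp <- findParallelPairs(s, scan)
  inreg <- pp[pp$start_b - pp$start_a == 1, ]
  expect_equal(nrow(inreg), 1)
  expect_equal(inreg$length, 8)
  expect_equal(inreg$mean_distance, 4.8, tolerance = 1e-9)
  expect_identical(pp[, c("chain_a", "start_a", "chain_b", "start_b", "length")],
                   bfPairs(s, scan))
})

test_that("relaxing the distance band or sd bound never loses a reported region", {
  strict <- GeometryParams()
  relaxed <- GeometryParams(dMin = 1, dMax = 18, sigmaMax = 2.5)
  checked <- 0L
  for (seed in c(3, 6, 11, 19, 35, 40, 44, 48)) {
    s <- randomSmallStructure(seed)
    sp <- findParallelPairs(s, strict)
    rp <- findParallelPairs(s, relaxed)
    checked <- checked + nrow(sp)
    for (i in seq_len(nrow(sp))) {
      covered <- any(
        rp$chain_a == sp$chain_a[i] & rp$chain_b == sp$chain_b[i] &
          (rp$start_b - rp$start_a) == (sp$start_b[i] - sp$start_a[i]) &
          rp$start_a <= sp$start_a[i] &
          (rp$start_a + rp$length) >= (sp$start_a[i] + sp$length[i]))
      expect_true(covered, label = sprintf("seed %d pair %d", seed, i))
    }
  }
  expect_gt(checked, 0)
})

test_that("each decoy class reports its intended rejection reason", {
  expect_equal(rejectionReason(generateDecoy("helix")), "separate_chains")
  expect_equal(rejectionReason(generateDecoy("hairpin")), "separate_chains")
  expect_equal(rejectionReason(generateDecoy("far_pair")), "distance_band")
  expect_equal(rejectionReason(generateDecoy("curved_pair")), "straightness")
  expect_equal(rejectionReason(generateDecoy("antiparallel_pair")), "direction")
  s <- generateParallelSheet(sheetSpec("GAQKLVFFAEDGA", 4, 7))
  expect_equal(rejectionReason(s), "none")
})
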