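test_that("radius of gyration matches closed forms and the direct formula", {
  expect_equal(radiusOfGyration(rbind(c(1, 2, 3))), 0)
  expect_equal(radiusOfGyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1.0)
  expect_error(radiusOfGyration(matrix(numeric(0), 0, 3)), "at least one atom")

  set.seed(31)
  x <- matrix(rnorm(150), 50, 3)
  m <- runif(50, 0.5, 16)
  direct <- {
    com <- colSums(x * m) / sum(m)
    sqrt(sum(m * rowSums(sweep(x, 2, com)^2)) / sum(m))
  }
  expect_equal(radiusOfGyration(x, m), direct, tolerance = 1e-12)
})

test_that("best-fit RMSD is rigid-motion aware and matches the quaternion oracle", {
  set.seed(32)
  a <- matrix(rnorm(60), 20, 3)
  expect_equal(fitRMSD(a, a), 0, tolerance = 1e-10)
  moved <- a %*% t(randomRotation()) +
    matrix(c(1, -2, 0.5), 20, 3, byrow = TRUE)
  expect_equal(fitRMSD(a, moved), 0, tolerance = 1e-10)

  b <- a + matrix(rnorm(60, sd = 0.7), 20, 3)
  expect_equal(fitRMSD(a, b), bruteForceRMSD(a, b), tolerance = 1e-6)

  # pseudometric: symmetry and triangle inequality on random triples
  for (rep in 1:3) {
    x <- matrix(rnorm(30), 10, 3); y <- matrix(rnorm(30), 10, 3)
    z <- matrix(rnorm(30), 10, 3)
    expect_equal(fitRMSD(x, y), fitRMSD(y, x), tolerance = 1e-9)
    expect_lte(fitRMSD(x, z), fitRMSD(x, y) + fitRMSD(y, z) + 1e-9)
  }
  expect_error(fitRMSD(a, b[1:10, ]), "atom counts differ")
})

test_that("native contacts follow the cutoff and separation rules", {
  # minimal CA-only system: residues i, i+3 at 6.4 A count; i, i+2 never do
  sys <- molecularSystem(rep("CA", 4), 1:4, elements = rep("C", 4))
  conf <- rbind(c(0, 0, 0), c(20, 0, 0), c(40, 0, 0), c(6.4, 0, 0))
  nc <- nativeContacts(conf, conf, sys)
  expect_identical(nc$count, 1L)
  expect_identical(unname(nc$pairs[1, ]), c(1L, 4L))

  close13 <- rbind(c(0, 0, 0), c(3, 0, 0), c(0.1, 0, 0), c(50, 0, 0))
  expect_identical(nativeContacts(close13, close13, sys)$count, 0L)

  # toy helix vs an independent double loop over residue pairs
  toy <- toyFixture()
  ca <- calphaIndices(toy$system)
  nat <- toy$native[ca, ]
  expectPairs <- NULL
  for (i in 1:(nrow(nat) - 1)) for (j in (i + 1):nrow(nat)) {
    if (j - i < 3) next
    if (sqrt(sum((nat[i, ] - nat[j, ])^2)) < 6.5)
      expectPairs <- rbind(expectPairs, c(i, j))
  }
  got <- nativeContacts(toy$native, toy$native, toy$system)
  expect_equal(unname(got$pairs), expectPairs)
  expect_equal(got$fraction, 1)
  # fractions stay in [0, 1] along a dissolving path
  mid <- (toy$native + toy$disordered) / 2
  f <- nativeContacts(mid, toy$native, toy$system)$fraction
  expect_gte(f, 0); expect_lte(f, 1)
})

test_that("backbone hydrogen bonds follow the distance and angle gates", {
  # collinear O...H-N at 2.0 A: angle 180 -> bond
  sys <- molecularSystem(c("N", "H", "CA", "C", "O", "N", "H", "CA", "C", "O"),
                         rep(1:2, each = 5), elements = NULL) |>
    suppressWarnings()
  conf <- rbind(c(0, 0, 0), c(0, 0, 1), c(2, 0, 0), c(3, 0, 0), c(30, 0, 0),
                c(10, 0, 0), c(11, 0, 0), c(12, 0, 0), c(13, 0, 0),
                c(0, 0, 3))
  # residue 2's O at (0,0,3): collinear with H1 (0,0,1) and N1 (0,0,0)
  hb <- backboneHBonds(conf, sys)
  expect_identical(hb$count, 1L)
  hit <- hb$bonds[hb$bonds$oRes == 2 & hb$bonds$hRes == 1, ]
  expect_identical(nrow(hit), 1L)
  expect_equal(hit$dist, 2.0)
  expect_equal(hit$angle, 180)

  # beyond 2.5 A: no bond regardless of angle
  conf[10, ] <- c(0, 0, 4)
  hb <- backboneHBonds(conf, sys)
  expect_identical(hb$count, 0L)

  # helix fixture vs brute-force scan over all O/H pairs (vertex H)
  toy <- toyFixture()
  s <- toy$system
  x <- toy$native
  brute <- 0L
  for (o in which(s@role == "O")) for (h in which(s@role == "H")) {
    d <- sqrt(sum((x[o, ] - x[h, ])^2))
    if (d >= 2.5) next
    n <- which(s@resid == s@resid[h] & s@role == "N")
    u <- x[n, ] - x[h, ]; v <- x[o, ] - x[h, ]
    ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
    if (ang > 135) brute <- brute + 1L
  }
  got <- backboneHBonds(x, s)
  expect_identical(got$count, brute)
  expect_gte(got$count, 1L)
  expect_identical(got$skipped, 1L)       # chain start has no amide H

  # the vertex-N convention is a different, much stricter gate
  gotN <- backboneHBonds(x, s, hbondRule(vertex = "N"))
  expect_lte(gotN$count, got$count)

  # native frame scores fraction 1 against itself
  expect_equal(hbondFraction(x, x, s)$fraction, 1)
})

test_that("group distances support centroid and minimum modes with CA fallback", {
  sys <- suppressWarnings(
    molecularSystem(c("N", "CA", "C", "O", "CB", "N", "CA", "C", "O", "CB"),
                    rep(1:2, each = 5)))
  conf <- matrix(0, 10, 3)
  conf[5, ] <- c(0, 0, 0)    # res 1 side chain
  conf[10, ] <- c(5, 0, 0)   # res 2 side chain
  expect_equal(groupDistance(conf, sys, 1, 2, "centroid"), 5)
  expect_equal(groupDistance(conf, sys, 1, 2, "min"), 5)
  expect_equal(groupDistance(conf, sys, 1, 1), 0)
  expect_error(groupDistance(conf, sys, 1, 9), "unknown residue")

  # glycine-like residue without side-chain atoms falls back to CA
  gly <- suppressWarnings(
    molecularSystem(c("N", "CA", "C", "O", "N", "CA", "C", "O", "CB"),
                    c(1, 1, 1, 1, 2, 2, 2, 2, 2)))
  gconf <- matrix(0, 9, 3)
  gconf[2, ] <- c(1, 1, 0)   # res 1 CA
  gconf[9, ] <- c(4, 5, 0)   # res 2 CB
  expect_equal(groupDistance(gconf, gly, 1, 2), 5)

  # toy fixture: centroid distance equals the hand-computed centroids
  toy <- toyFixture()
  s <- toy$system
  i5 <- which(s@resid == 5 & s@role == "side" & s@elements != "H")
  i9 <- which(s@resid == 9 & s@role == "side" & s@elements != "H")
  hand <- sqrt(sum((colMeans(toy$native[i5, , drop = FALSE]) -
                    colMeans(toy$native[i9, , drop = FALSE]))^2))
  expect_equal(groupDistance(toy$native, s, 5, 9), hand, tolerance = 1e-12)
})

test_that("pearson correlation matches the direct formula and flags degeneracy", {
  set.seed(33)
  x <- rnorm(100); y <- rnorm(100)
  expect_equal(pearsonR(x, x), 1.0)
  expect_equal(pearsonR(x, -x), -1.0)
  direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearsonR(x, y), direct, tolerance = 1e-12)
  expect_error(pearsonR(x, rep(1, 100)), "zero variance")
  expect_error(pearsonR(x, y[1:50]), "lengths differ")
})

test_that("trajectory PCA satisfies its spectral identities and matches an independent solver", {
  toy <- toyFixture()
  s <- toy$system

  # single-direction motion of one atom: first component takes everything
  nres <- residueCount(s)
  base <- toy$native
  frames <- lapply(seq(0, 1, length.out = 8), function(a) {
    x <- base; x[calphaIndices(s)[3], 1] <- x[calphaIndices(s)[3], 1] + a
    as.numeric(t(x))
  })
  p <- newPath(do.call(rbind, frames), delta = 1, masses = s@masses,
               adim = 3L, system = s)
  pca <- pcaTrajectory(p, s, alignment = "none")
  expect_equal(pca@varianceFractions[1], 1.0, tolerance = 1e-10)
  contrib <- residueContribution(pca, 1)
  expect_equal(contrib[3], 1, tolerance = 1e-8)
  expect_lt(max(contrib[-3]), 1e-8)
  expect_error(residueContribution(pca, 500), "out of range")

  # random trajectory: identities + cross-check against an SVD eigensolver
  set.seed(34)
  mini <- suppressWarnings(molecularSystem(rep("CA", 3), 1:3))
  X <- matrix(rnorm(20 * 9), 20, 9)
  rp <- newPath(X, delta = 1, masses = mini@masses, adim = 3L,
                system = mini)
  pca <- pcaTrajectory(rp, mini, alignment = "none")
  C <- crossprod(sweep(X, 2, colMeans(X))) / 20
  expect_equal(sum(pca@values), sum(diag(C)), tolerance = 1e-10)
  expect_equal(sum(pca@varianceFractions), 1, tolerance = 1e-10)
  expect_equal(crossprod(pca@vectors), diag(9), tolerance = 1e-8)
  sv <- svd(sweep(X, 2, colMeans(X)) / sqrt(20))
  expect_equal(pca@values, sv$d^2, tolerance = 1e-8)
  for (k in 1:3)   # eigenvectors agree up to sign
    expect_equal(abs(sum(pca@vectors[, k] * sv$v[, k])), 1, tolerance = 1e-8)
  # per-component projection variance equals the eigenvalue
  projVar <- colMeans(sweep(pca@projections, 2,
                            colMeans(pca@projections))^2)
  expect_equal(projVar, pca@values, tolerance = 1e-8)
  # squared residue contributions sum to one per component
  expect_equal(sum(residueContribution(pca, 2)^2), 1, tolerance = 1e-10)

  # per-frame rigid motions are removed by Kabsch alignment
  aligned <- pcaTrajectory(rp, mini, alignment = "kabsch")
  Xmoved <- t(apply(X, 1, function(fr) {
    x <- matrix(fr, ncol = 3, byrow = TRUE)
    as.numeric(t(x %*% t(randomRotation()) +
                 matrix(rnorm(3), nrow(x), 3, byrow = TRUE)))
  }))
  movedPath <- newPath(Xmoved, delta = 1, masses = mini@masses, adim = 3L,
                       system = mini)
  pcaMoved <- pcaTrajectory(movedPath, mini, alignment = "kabsch")
  expect_equal(pcaMoved@values, aligned@values, tolerance = 1e-6)
})

test_that("the pathway report assembles all traces consistently", {
  toy <- toyFixture()
  s <- toy$system
  natFlat <- as.numeric(t(toy$native))

  # a trajectory of identical native frames
  stillFrames <- matrix(rep(natFlat, 4), 4, byrow = TRUE)
  still <- newPath(stillFrames, delta = 1, masses = s@masses, adim = 3L,
                   system = s)
  rep1 <- pathwayReport(still, toy$native, s)
  expect_identical(nrow(rep1$table), 4L)
  expect_true(all(abs(rep1$table$rmsd) < 1e-6))
  expect_true(all(rep1$table$contactFraction == 1))

  # straight-line interpolation: traces recomputed directly per frame
  straight <- coeffsToPath(toy$disordered, toy$native,
                           zeroCoefficients(8L, 3L * nrow(toy$native)),
                           delta = 1, masses = s@masses, adim = 3L,
                           system = s)
  rep2 <- pathwayReport(straight, toy$native, s, distances = list(c(3, 8)),
                        surface = goChainPotential(s, toy$native))
  expect_identical(nrow(rep2$table), 9L)
  for (f in c(1L, 5L, 9L)) {
    x <- matrix(pathFrames(straight)[f, ], ncol = 3, byrow = TRUE)
    expect_equal(rep2$table$rg[f], radiusOfGyration(x, s@masses),
                 tolerance = 1e-12)
    expect_equal(rep2$table$dist_3_8[f], groupDistance(x, s, 3, 8),
                 tolerance = 1e-12)
  }
  # Rg shrinks monotonically from the disordered to the native endpoint
  expect_true(all(diff(rep2$table$rg) < 0))
  expect_true(!is.null(rep2$correlations))
  expect_true(all(abs(rep2$correlations) <= 1 + 1e-12))
})
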