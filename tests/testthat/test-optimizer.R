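test_that("random trial paths are seeded, reproducible, and endpoint-exact", {
  p0 <- randomTrialPath(0, 4, 20L, seed = 3L, amplitude = 0, delta = 0.1)
  expect_equal(pathFrames(p0)[, 1], seq(0, 4, length.out = 21))

  a <- randomTrialPath(c(0, 0), c(1, 2), 16L, seed = 5L, amplitude = 0.5,
                       delta = 0.1)
  b <- randomTrialPath(c(0, 0), c(1, 2), 16L, seed = 5L, amplitude = 0.5,
                       delta = 0.1)
  expect_identical(pathFrames(a), pathFrames(b))

  c <- randomTrialPath(c(0, 0), c(1, 2), 16L, seed = 6L, amplitude = 0.5,
                       delta = 0.1)
  expect_identical(pathFrames(a)[1, ], pathFrames(c)[1, ])
  expect_identical(pathFrames(a)[17, ], pathFrames(c)[17, ])
  expect_gt(max(abs(pathFrames(a)[2:16, ] - pathFrames(c)[2:16, ])), 0)

  # the caller's RNG stream is left untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(randomTrialPath(0, 1, 8L, 1L, 1, 0.1))
  expect_identical(rnorm(1), before)
})

test_that("the free-particle optimizer recovers the straight line and its action", {
  fp <- freeParticlePotential()
  d <- 4; tau <- 2; K <- 0.5 * (d / tau)^2
  for (seed in 1:3) {
    cfg <- admdConfig(targetEnergy = K, temperature = 2 * K / 3, muE = NA,
                      muK = NA, delta = tau / 20, PSchedule = c(20L, 50L),
                      maxIter = 5000L, gradTol = 1e-10, seed = seed)
    start <- randomTrialPath(0, d, 20L, seed = seed, amplitude = 0.5,
                             delta = tau / 20)
    sol <- minimizePhi(start, fp, cfg)
    expect_lt(abs(solutionBreakdown(sol)@S - 0.5 * d^2 / tau), 1e-6)
    expect_true(solutionConserved(sol))
  }
})

test_that("identical config and seed give bit-identical solutions", {
  fp <- freeParticlePotential()
  cfg <- admdConfig(targetEnergy = 2, muE = NA, muK = 0, delta = 0.1,
                    PSchedule = c(20L, 50L), maxIter = 5000L,
                    gradTol = 1e-10, seed = 7L)
  run <- function() {
    start <- randomTrialPath(0, 4, 20L, seed = 7L, amplitude = 0.5,
                             delta = 0.1)
    minimizePhi(start, fp, cfg)
  }
  s1 <- run(); s2 <- run()
  expect_identical(pathFrames(solutionPath(s1)), pathFrames(solutionPath(s2)))
  expect_identical(s1@breakdown@phi, s2@breakdown@phi)
})

test_that("Phi decreases within levels and doubling muE tightens energy conservation", {
  surf <- harmonicPotential()
  tau <- pi / 2
  start <- randomTrialPath(1, cos(tau), 20L, seed = 5L, amplitude = 0,
                           delta = tau / 20)
  startPhi <- function(muE) {
    cfg <- admdConfig(targetEnergy = 0.7, muE = muE, muK = 0,
                      delta = tau / 20, PSchedule = c(20L, 50L, 100L),
                      maxIter = 8000L, gradTol = 1e-10)
    sol <- minimizePhi(start, surf, cfg)
    entry <- extendedAction(start, surf, cfg)@phi
    expect_lte(sol@phiTrace[1], entry)
    sum((solutionBreakdown(sol)@frameEnergies - 0.7)^2)
  }
  raw <- vapply(c(0.01, 0.02, 0.04, 0.08), startPhi, numeric(1))
  expect_true(all(diff(raw) <= 1e-9))
})

test_that("the annealing protocol finds the analytic energy within one decrement", {
  surf <- harmonicPotential()
  tau <- pi / 2
  cfg <- admdConfig(muE = NA, muK = 0, delta = tau / 20,
                    PSchedule = c(20L, 50L, 100L, 200L), maxIter = 5000L,
                    gradTol = 1e-9, annealDecrement = 0.05, seed = 3L)
  ann <- annealTargetEnergy(1, cos(tau), surf, cfg, EStart = 0.6)
  expect_false(is.null(ann$best))
  expect_lt(abs(ann$best@config@targetEnergy - 0.5), 0.05 + 1e-12)
  # record: strictly decreasing E, conserving until the final failure
  expect_true(all(diff(ann$record$E) < 0))
  n <- nrow(ann$record)
  expect_false(ann$record$conserved[n])
  expect_true(all(ann$record$conserved[-n]))
  # an EStart below the endpoint potential energy is rejected outright
  expect_error(annealTargetEnergy(1, cos(tau), surf, cfg, EStart = 0.3),
               "must exceed both endpoint")
})

test_that("solution diagnostics: Verlet residuals scale as O(delta^2) and rank paths", {
  surf <- harmonicPotential()
  v1 <- verifySolution(harmonicOrbitPath(100L), surf)
  v2 <- verifySolution(harmonicOrbitPath(200L), surf)
  ratio <- v1$maxVerletResidual / v2$maxVerletResidual
  expect_gt(ratio, 3); expect_lt(ratio, 5)

  # exact straight line: residual is zero
  straight <- newPath(cbind(seq(0, 4, length.out = 21)), delta = 0.1)
  expect_lt(verifySolution(straight, freeParticlePotential())$maxVerletResidual,
            1e-12)

  # an optimized path is strictly more Verlet-like than its own trial start
  cfg <- admdConfig(targetEnergy = 0.5, muE = 0.1, muK = 0, delta = pi / 40,
                    PSchedule = c(20L, 50L), maxIter = 5000L, gradTol = 1e-9)
  start <- randomTrialPath(1, cos(pi / 2), 20L, seed = 9L, amplitude = 0.3,
                           delta = pi / 40)
  sol <- minimizePhi(start, surf, cfg)
  before <- verifySolution(start, surf, cfg)
  after <- verifySolution(sol, surf)
  expect_lt(after$onsagerMachlup, before$onsagerMachlup)
  expect_lt(after$maxVerletResidual, before$maxVerletResidual)
})
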