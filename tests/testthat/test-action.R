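test_that("the frame Lagrangian follows the forward-difference definition", {
  fp <- freeParticlePotential()
  # stationary single atom
  still <- newPath(rbind(1, 1, 1, 1), delta = 1)
  expect_equal(lagrangianAt(still, 0, fp), 0)
  # 1 atom, m = 1, delta = 1, q_j = 0, q_{j+1} = 2
  p <- newPath(rbind(0, 2, 2), delta = 1)
  expect_equal(lagrangianAt(p, 0, fp), 2.0)
  expect_equal(frameEnergy(p, 0, fp), 2.0)
  expect_error(lagrangianAt(p, 2, fp), "no forward neighbour")
  expect_error(frameEnergy(p, 2, fp), "no forward neighbour")

  # random multi-atom frames on a harmonic surface vs scalar-loop oracle
  set.seed(11)
  surf <- harmonicPotential(k = 0.8)
  path <- newPath(matrix(rnorm(9 * 15), 9, 15), delta = 0.3,
                  masses = runif(5, 0.5, 2), adim = 3L)
  for (j in c(0, 3, 7)) {
    Q <- pathFrames(path)
    m <- rep(path@masses, each = 3L)
    kin <- sum(m / (2 * 0.3^2) * (Q[j + 1, ] - Q[j + 2, ])^2)
    V <- evaluateSurface(surf, Q[j + 1, ])$energy
    expect_equal(lagrangianAt(path, j, surf), kin - V, tolerance = 1e-12)
    expect_equal(frameEnergy(path, j, surf), kin + V, tolerance = 1e-12)
  }
})

test_that("the total action matches closed forms and the brute-force loop", {
  fp <- freeParticlePotential()
  still <- newPath(matrix(2, 5, 1), delta = 0.5)
  expect_equal(totalAction(still, fp), 0)

  # straight-line free particle: S = d^2 / (2 tau) exactly
  d <- 5; P <- 10L; tau <- 2
  straight <- newPath(cbind(seq(0, d, length.out = P + 1)), delta = tau / P)
  expect_equal(totalAction(straight, fp), 0.5 * d^2 / tau, tolerance = 1e-12)

  set.seed(12)
  surf <- harmonicPotential(k = 1.3)
  path <- newPath(matrix(rnorm(11 * 6), 11, 6), delta = 0.2,
                  masses = runif(2, 0.5, 3), adim = 3L)
  expect_equal(totalAction(path, surf), bruteForceAction(path, surf),
               tolerance = 1e-12)
})

test_that("frame energies of a finely sampled harmonic orbit are constant to O(delta^2)", {
  P <- 2000L
  path <- harmonicOrbitPath(P)
  Ej <- frameEnergies(path, harmonicPotential())
  expect_lt(max(abs(Ej - 0.5)), 10 * (pathDelta(path))^1)  # forward diff: O(delta)
  # and the spread shrinks ~2x when P doubles (first-order difference scheme)
  Ej2 <- frameEnergies(harmonicOrbitPath(2L * P), harmonicPotential())
  expect_lt(diff(range(Ej2)), 0.6 * diff(range(Ej)))
})

test_that("the extended action decomposes exactly and matches brute-force sums", {
  fp <- freeParticlePotential()
  # stationary path, V = 0, E = 1, muE = 1, P = 4 -> penalty = 4
  cfg <- admdConfig(targetEnergy = 1, muE = 1, muK = 0, delta = 1,
                    PSchedule = 4L)
  still <- newPath(matrix(0, 5, 1), delta = 1)
  bd <- extendedAction(still, fp, cfg)
  expect_equal(bd@energyPenalty, 4.0)
  expect_equal(bd@S, 0)
  expect_equal(bd@phi, 4.0)

  # exact-energy path with matching temperature: Phi = S
  d <- 3; P <- 8L; tau <- 2
  straight <- newPath(cbind(seq(0, d, length.out = P + 1)), delta = tau / P)
  K <- 0.5 * (d / tau)^2
  cfgT <- admdConfig(targetEnergy = K, muE = 5, muK = 7,
                     temperature = 2 * K / 3, delta = tau / P, PSchedule = P)
  bd <- extendedAction(straight, fp, cfgT)
  expect_equal(bd@energyPenalty, 0, tolerance = 1e-12)
  expect_equal(bd@kineticRestraint, 0, tolerance = 1e-12)
  expect_equal(bd@phi, bd@S, tolerance = 1e-12)

  # random path: all three terms vs independent scalar re-summation
  set.seed(13)
  surf <- harmonicPotential(k = 0.6)
  masses <- runif(3, 0.5, 2)
  path <- newPath(matrix(rnorm(9 * 9), 9, 9), delta = 0.25,
                  masses = masses, adim = 3L)
  cfg <- admdConfig(targetEnergy = 2, muE = 1.5, muK = 0.7,
                    temperature = 0.4, delta = 0.25, PSchedule = 8L)
  bd <- extendedAction(path, surf, cfg)
  S <- bruteForceAction(path, surf)
  Ej <- vapply(0:7, function(j) bruteForceFrameEnergy(path, surf, j),
               numeric(1))
  Katom <- sapply(1:3, function(I) {
    cols <- (I - 1) * 3 + 1:3
    Q <- pathFrames(path)
    mean(vapply(1:8, function(r)
      sum(masses[I] / (2 * 0.25^2) * (Q[r, cols] - Q[r + 1, cols])^2),
      numeric(1)))
  })
  expect_equal(bd@S, S, tolerance = 1e-12)
  expect_equal(bd@frameEnergies, Ej, tolerance = 1e-12)
  expect_equal(bd@energyPenalty, 1.5 * sum((Ej - 2)^2), tolerance = 1e-12)
  expect_equal(bd@kineticRestraint, 0.7 * sum((Katom - 1.5 * 0.4)^2),
               tolerance = 1e-12)
  expect_equal(bd@phi, bd@S + bd@energyPenalty + bd@kineticRestraint,
               tolerance = 1e-12)
  expect_error(extendedAction(path, surf,
                              admdConfig(muE = NA, delta = 1, PSchedule = 8L)),
               "muE must be")
})

test_that("the coefficient-space gradient matches finite differences and decouples", {
  set.seed(14)
  cfg <- admdConfig(targetEnergy = 1, temperature = 0.3, muE = 2, muK = 1.5,
                    delta = 0.1, PSchedule = 16L)
  surf <- harmonicPotential(k = 1.3)
  q0 <- rnorm(9); qP <- rnorm(9)
  phiOf <- function(A, config) {
    extendedAction(coeffsToPath(q0, qP, A, delta = 0.1), surf, config)@phi
  }
  for (rep in 1:3) {
    A <- matrix(rnorm(15 * 9) * 0.3, 15, 9)
    g <- phiGradient(A, q0, qP, surf, cfg, delta = 0.1)$gradient
    h <- 1e-6
    fd <- matrix(0, 15, 9)
    for (k in 1:15) for (d in 1:9) {
      Ap <- A; Ap[k, d] <- Ap[k, d] + h
      Am <- A; Am[k, d] <- Am[k, d] - h
      fd[k, d] <- (phiOf(Ap, cfg) - phiOf(Am, cfg)) / (2 * h)
    }
    expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-5)
  }
  # with both penalties off the gradient reduces to the gradient of S
  cfg0 <- admdConfig(targetEnergy = 1, muE = 1e-300, muK = 0, delta = 0.1,
                     PSchedule = 16L)
  A <- matrix(rnorm(15 * 9) * 0.3, 15, 9)
  gOn <- phiGradient(A, q0, qP, surf, cfg0, delta = 0.1)
  h <- 1e-6
  sOf <- function(A) totalAction(coeffsToPath(q0, qP, A, delta = 0.1), surf)
  fdS <- (sOf(`[<-`(A, 3, 2, A[3, 2] + h)) -
          sOf(`[<-`(A, 3, 2, A[3, 2] - h))) / (2 * h)
  expect_equal(gOn$gradient[3, 2], fdS, tolerance = 1e-5)
})

test_that("the exact Newtonian path is a stationary point of Phi", {
  # free particle straight line with matched E and T
  d <- 4; P <- 20L; tau <- 2
  K <- 0.5 * (d / tau)^2
  cfg <- admdConfig(targetEnergy = K, temperature = 2 * K / 3, muE = 3,
                    muK = 2, delta = tau / P, PSchedule = P)
  straight <- newPath(cbind(seq(0, d, length.out = P + 1)), delta = tau / P)
  g <- phiGradient(pathToCoeffs(straight), 0, d, freeParticlePotential(),
                   cfg, delta = tau / P)
  expect_lt(max(abs(g$gradient)), 1e-8)

  # harmonic orbit: the real-space gradient of Phi vanishes as the grid
  # refines (the sine transform maps it back from coefficient space)
  norms <- vapply(c(100L, 400L, 1600L), function(P) {
    path <- harmonicOrbitPath(P)
    cfgP <- admdConfig(targetEnergy = 0.5, muE = 1, muK = 0,
                       delta = pathDelta(path), PSchedule = P)
    g <- phiGradient(pathToCoeffs(path), 1, cos(pi / 2),
                     harmonicPotential(), cfgP, delta = pathDelta(path))
    S <- sin(pi * outer(1:(P - 1), 1:(P - 1)) / P)
    max(abs((2 / P) * S %*% g$gradient))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[3], norms[1] / 10)
})
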