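## Minimization of the extended action: random trial paths, multigrid
## L-BFGS relaxation in sine-coefficient space, and solution diagnostics.

## evaluate code with a local, restored RNG state so seeded helpers never
## disturb the caller's random stream
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Random trial pathway between two endpoints
#'
#' Linear interpolation plus seeded random sine coefficients whose amplitude
#' decays as \eqn{1/k}, so the trial path is smooth at large scales and the
#' endpoints are exact.  The same seed always yields the identical path.
#'
#' @param q0,qP endpoint conformations.
#' @param P frame count.
#' @param seed integer seed (sole source of randomness).
#' @param amplitude length scale of the random excursions; 0 gives the
#'   straight line.
#' @param delta time per step.
#' @param masses,adim,system forwarded to [newPath()].
#' @return a [Path].
#' @export
randomTrialPath <- function(q0, qP, P, seed, amplitude, delta, masses = NULL,
                            adim = NULL, system = NULL) {
  stopifnot(amplitude >= 0, P >= 2)
  q0 <- flattenCoords(q0); qP <- flattenCoords(qP)
  D <- length(q0)
  A <- withSeed(seed,
    matrix(stats::rnorm((P - 1L) * D), P - 1L, D) * amplitude / seq_len(P - 1L))
  coeffsToPath(q0, qP, sineCoefficients(A), delta = delta, masses = masses,
               adim = adim, system = system)
}

#' Resolve automatic penalty weights
#'
#' When `muE` or `muK` is `NA`, scales it so the corresponding raw penalty
#' term evaluated on the supplied (initial) path weighs about `factor` times
#' the magnitude of the classical action, making the constraint dominate the
#' optimization from the start.
#'
#' @param path the initial trial [Path].
#' @param surface a [PotentialSurface].
#' @param config an [ADMDConfig]; only `NA` weights are touched.
#' @param factor target ratio between each penalty term and `|S|`.
#' @return the config with `muE` and `muK` resolved to positive numbers.
#' @export
resolvePenaltyWeights <- function(path, surface, config, factor = 100) {
  kin <- .pathKinetics(path)
  P <- frameCount(path)
  V <- surfaceOnFrames(surface, path@frames[1:P, , drop = FALSE])$energy
  S <- sum(kin$Kframe - V) * path@delta
  scaleS <- max(abs(S), 1)
  if (is.na(config@muE)) {
    raw <- sum((kin$Kframe + V - config@targetEnergy)^2)
    config@muE <- factor * scaleS / max(raw, 1e-8)
  }
  if (is.na(config@muK)) {
    targetK <- 1.5 * config@kB * config@temperature
    raw <- sum((kin$KatomMean - targetK)^2)
    config@muK <- factor * scaleS / max(raw, 1e-8)
  }
  config
}

## L-BFGS in coefficient space at a fixed frame count; returns the updated
## path plus iteration count and final Phi.
.relaxAtP <- function(path, surface, config) {
  P <- frameCount(path)
  D <- ncol(path@frames)
  q0 <- path@frames[1L, ]; qP <- path@frames[P + 1L, ]
  masses <- path@masses; adim <- path@adim
  delta <- path@delta
  Smat <- sineBasisMatrix(P)
  makePath <- function(par) {
    A <- matrix(par, P - 1L, D)
    coeffsToPath(q0, qP, sineCoefficients(A), delta = delta,
                 masses = masses, adim = adim, system = path@system)
  }
  # optim calls fn and gr separately at the same point; one evaluation
  # provides both, so cache the last point's results
  cache <- new.env(parent = emptyenv())
  evalAt <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return()
    p <- makePath(par)
    fg <- .phiFrameGradient(p, surface, config)
    phi <- fg$S + fg$penalty + fg$restraint
    if (!is.finite(phi)) {
      bad <- which(!is.finite(fg$Ej))[1L]
      stop("non-finite extended action at frame index ",
           if (is.na(bad)) "P" else bad - 1L)
    }
    g <- Smat %*% fg$grad
    if (!all(is.finite(g)))
      stop("non-finite action gradient at frame index ",
           which(!apply(is.finite(fg$grad), 1L, all))[1L])
    cache$par <- par; cache$phi <- phi; cache$grad <- as.vector(g)
    invisible()
  }
  fn <- function(par) { evalAt(par); cache$phi }
  gr <- function(par) { evalAt(par); cache$grad }
  A0 <- pathToCoeffs(path)@coeffs
  fit <- stats::optim(as.vector(A0), fn = fn, gr = gr, method = "L-BFGS-B",
                      control = list(maxit = config@maxIter,
                                     pgtol = config@gradTol, factr = 10))
  list(path = makePath(fit$par), phi = fit$value,
       iterations = fit$counts[["function"]])
}

#' Potential-energy barrier of a path
#'
#' The potential-energy difference between the highest-potential frame and
#' the initial frame, \eqn{\max_j V(q_j) - V(q_0)}, measured on the
#' potential only.
#' @param path a [Path].
#' @param surface a [PotentialSurface].
#' @return scalar barrier (>= 0 whenever the initial frame has the lowest
#'   potential energy).
#' @export
pathBarrier <- function(path, surface) {
  V <- surfaceOnFrames(surface, path@frames)$energy
  max(V) - V[1L]
}

#' Minimize the extended action over a multigrid schedule
#'
#' For each frame count in the configuration's `PSchedule` (skipping counts
#' at or below the start path's), the current path is refined by sine-basis
#' zero padding and relaxed by L-BFGS in coefficient space until the
#' gradient tolerance or the iteration cap is reached.  `NA` penalty weights
#' are resolved once on the start path via [resolvePenaltyWeights()].
#'
#' @param start the initial [Path]; its endpoints are the boundary
#'   conditions and are never altered.
#' @param surface a [PotentialSurface].
#' @param config an [ADMDConfig].
#' @param logFile optional path of a tab-separated per-level log (level P,
#'   iterations, S, energy penalty, kinetic restraint, Phi, max |E_j - E|).
#' @return a [PathwaySolution].
#' @examples
#' cfg <- admdConfig(targetEnergy = 0.5, delta = pi / 80, PSchedule = c(10, 40))
#' start <- newPath(cbind(seq(1, 0, length.out = 11)), delta = pi / 20)
#' sol <- minimizePhi(start, harmonicPotential(), cfg)
#' solutionConserved(sol)
#' @export
minimizePhi <- function(start, surface, config, logFile = NULL) {
  config <- resolvePenaltyWeights(start, surface, config)
  schedule <- config@PSchedule[config@PSchedule >= frameCount(start)]
  if (!length(schedule)) schedule <- frameCount(start)
  path <- start
  iters <- integer(0)
  phis <- numeric(0)
  logCon <- NULL
  if (!is.null(logFile)) {
    logCon <- file(logFile, "w")
    on.exit(close(logCon))
    writeLines(paste("P", "iterations", "S", "energy_penalty",
                     "kinetic_restraint", "phi", "max_abs_Ej_minus_E",
                     sep = "\t"), logCon)
  }
  for (P in schedule) {
    if (P > frameCount(path)) path <- refinePath(path, P, fixTau = config@fixTau)
    res <- .relaxAtP(path, surface, config)
    path <- res$path
    iters <- c(iters, res$iterations)
    phis <- c(phis, res$phi)
    if (!is.null(logCon)) {
      bd <- extendedAction(path, surface, config)
      writeLines(sprintf("%d\t%d\t%.10g\t%.10g\t%.10g\t%.10g\t%.10g",
                         P, res$iterations, bd@S, bd@energyPenalty,
                         bd@kineticRestraint, bd@phi,
                         max(abs(bd@frameEnergies - config@targetEnergy))),
                 logCon)
    }
  }
  breakdown <- extendedAction(path, surface, config)
  barrier <- pathBarrier(path, surface)
  scale <- max(abs(config@targetEnergy), barrier)
  conserved <- stats::sd(breakdown@frameEnergies) <=
    config@conservationTol * max(scale, .Machine$double.eps)
  new("PathwaySolution", path = path, breakdown = breakdown,
      energyConserved = conserved, barrier = barrier,
      iterations = iters, phiTrace = phis, config = config)
}

#' @rdname minimizePhi
#' @param solution a [PathwaySolution].
#' @return `solutionConserved()`: logical energy-conservation verdict;
#'   `solutionPath()`: the optimized [Path]; `solutionBreakdown()`: the final
#'   [ActionBreakdown].
#' @export
solutionConserved <- function(solution) solution@energyConserved

#' @rdname minimizePhi
#' @export
solutionPath <- function(solution) solution@path

#' @rdname minimizePhi
#' @export
solutionBreakdown <- function(solution) solution@breakdown

#' Quality report for a pathway
#'
#' Reports how Newtonian and energy-conserving a path is: the relative
#' spread of the frame energies, the maximum Verlet residual
#' \eqn{\|m (q_{j+1} - 2 q_j + q_{j-1})/\Delta^2 + \nabla V(q_j)\|} over the
#' interior frames, the Onsager-Machlup diagnostic (sum of squared Verlet
#' residuals; smaller is more Verlet-like), and the potential-energy
#' barrier.
#'
#' @param solution a [PathwaySolution] or a bare [Path].
#' @param surface the [PotentialSurface] the path was optimized on.
#' @param config an [ADMDConfig] (defaults to the solution's own).
#' @return list with `energyStd`, `energyStdRel`, `maxVerletResidual`,
#'   `onsagerMachlup`, `barrier`, `conserved`.
#' @export
verifySolution <- function(solution, surface,
                           config = if (is(solution, "PathwaySolution"))
                             solution@config else NULL) {
  path <- if (is(solution, "PathwaySolution")) solution@path else solution
  Q <- path@frames
  P <- nrow(Q) - 1L
  m <- massPerCoord(path)
  acc <- (Q[3:(P + 1L), , drop = FALSE] - 2 * Q[2:P, , drop = FALSE] +
          Q[1:(P - 1L), , drop = FALSE]) / path@delta^2
  gradV <- surfaceOnFrames(surface, Q[2:P, , drop = FALSE],
                           gradient = TRUE)$gradient
  res <- sweep(acc, 2L, m, "*") + gradV
  norms <- sqrt(rowSums(res^2))
  Ej <- if (!is.null(config)) {
    cfg <- config
    if (is.na(cfg@muE)) cfg@muE <- 1
    extendedAction(path, surface, cfg)@frameEnergies
  } else frameEnergies(path, surface)
  barrier <- pathBarrier(path, surface)
  eStd <- stats::sd(Ej)
  scale <- if (!is.null(config)) max(abs(config@targetEnergy), barrier)
           else max(abs(mean(Ej)), barrier)
  list(energyStd = eStd,
       energyStdRel = eStd / max(abs(mean(Ej)), .Machine$double.eps),
       maxVerletResidual = max(norms),
       onsagerMachlup = sum(norms^2),
       barrier = barrier,
       conserved = if (!is.null(config))
         eStd <= config@conservationTol * max(scale, .Machine$double.eps)
       else NA)
}
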