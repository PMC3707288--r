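## The discretized action, the Passerone-Parrinello total-energy penalty,
## the kinetic-energy restraint, their sum Phi, and the analytic gradient of
## Phi with respect to the sine coefficients.
##
## Discretization conventions (taken literally from the printed sums):
##  - kinetic terms use the forward difference between frames j and j+1,
##  - every sum over frames runs j = 0..P-1, so frame P contributes no
##    potential-only term,
##  - <K_I> averages atom I's per-interval kinetic energy over all P
##    intervals.

## per-interval kinetic energies: returns list with
##   Kcoord (P x D), Kframe (length P), KatomMean (length natoms)
.pathKinetics <- function(path) {
  Q <- path@frames
  P <- nrow(Q) - 1L
  m <- massPerCoord(path)
  Dq <- Q[1:P, , drop = FALSE] - Q[2:(P + 1L), , drop = FALSE]
  Kcoord <- sweep(Dq^2, 2L, m / (2 * path@delta^2), "*")
  atom <- rep(seq_along(path@masses), each = path@adim)
  Katom <- t(rowsum(t(Kcoord), atom))          # P x natoms
  list(Dq = Dq, Kcoord = Kcoord, Kframe = rowSums(Kcoord),
       KatomMean = colMeans(Katom))
}

#' Discretized Lagrangian of one temporal frame
#'
#' \eqn{L_j = \sum_I \frac{m_I}{2\Delta^2} (q_{I,j} - q_{I,j+1})^2 -
#' V(\{q_j\})}: the kinetic term uses the forward difference between frames
#' \eqn{j} and \eqn{j+1}, the potential is evaluated at frame \eqn{j}.
#'
#' @param path a [Path].
#' @param j frame index, 0-based, \eqn{0 \le j \le P-1} (frame \eqn{P} has
#'   no forward neighbour).
#' @param surface a [PotentialSurface].
#' @return scalar Lagrangian.
#' @export
lagrangianAt <- function(path, j, surface) {
  P <- frameCount(path)
  if (j < 0 || j > P - 1L)
    stop("j must lie in 0..P-1 = 0..", P - 1L, " (frame P has no forward neighbour)")
  kin <- .pathKinetics(path)
  V <- surfaceOnFrames(surface, path@frames[j + 1L, , drop = FALSE])$energy
  kin$Kframe[j + 1L] - V
}

#' Classical action of a path
#'
#' \eqn{S = \sum_{j=0}^{P-1} L_j \Delta}.
#'
#' @inheritParams lagrangianAt
#' @return scalar action (energy times time).
#' @export
totalAction <- function(path, surface) {
  P <- frameCount(path)
  kin <- .pathKinetics(path)
  V <- surfaceOnFrames(surface, path@frames[1:P, , drop = FALSE])$energy
  sum(kin$Kframe - V) * path@delta
}

#' Total energy of one frame
#'
#' \eqn{E_j = \sum_I \frac{m_I}{2\Delta^2}(q_{I,j} - q_{I,j+1})^2 +
#' V(\{q_j\})}, the forward-difference kinetic energy plus the potential at
#' frame \eqn{j}.
#'
#' @inheritParams lagrangianAt
#' @return scalar total energy.
#' @export
frameEnergy <- function(path, j, surface) {
  P <- frameCount(path)
  if (j < 0 || j > P - 1L)
    stop("j must lie in 0..P-1 = 0..", P - 1L, " (frame P has no forward neighbour)")
  kin <- .pathKinetics(path)
  V <- surfaceOnFrames(surface, path@frames[j + 1L, , drop = FALSE])$energy
  kin$Kframe[j + 1L] + V
}

#' All frame energies of a path
#' @inheritParams lagrangianAt
#' @return numeric vector \eqn{E_j}, \eqn{j = 0..P-1}.
#' @export
frameEnergies <- function(path, surface) {
  P <- frameCount(path)
  kin <- .pathKinetics(path)
  kin$Kframe + surfaceOnFrames(surface, path@frames[1:P, , drop = FALSE])$energy
}

#' Extended action and its decomposition
#'
#' Evaluates the Passerone-Parrinello action with kinetic restraint,
#' \deqn{\Phi = S + \mu_E \sum_{j=0}^{P-1} (E_j - E)^2 +
#'       \mu_K \sum_I (\langle K_I\rangle - \tfrac32 k_B T)^2,}
#' and returns every term plus the frame energies and per-atom mean kinetic
#' energies it was built from.
#'
#' @inheritParams lagrangianAt
#' @param config an [ADMDConfig]; `muE` must be resolved (positive), `muK`
#'   may be 0.
#' @return an [ActionBreakdown].
#' @export
extendedAction <- function(path, surface, config) {
  muE <- config@muE; muK <- config@muK
  if (is.na(muE) || muE <= 0)
    stop("muE must be a positive number (use resolvePenaltyWeights() for auto)")
  if (is.na(muK)) muK <- 0
  P <- frameCount(path)
  kin <- .pathKinetics(path)
  V <- surfaceOnFrames(surface, path@frames[1:P, , drop = FALSE])$energy
  S <- sum(kin$Kframe - V) * path@delta
  Ej <- kin$Kframe + V
  penalty <- muE * sum((Ej - config@targetEnergy)^2)
  targetK <- 1.5 * config@kB * config@temperature
  restraint <- muK * sum((kin$KatomMean - targetK)^2)
  new("ActionBreakdown", S = S, energyPenalty = penalty,
      kineticRestraint = restraint, phi = S + penalty + restraint,
      frameEnergies = Ej, atomMeanKinetic = kin$KatomMean)
}

## gradient of Phi with respect to the interior frames (rows 1..P-1),
## returned as a (P-1) x D matrix together with the breakdown pieces.
.phiFrameGradient <- function(path, surface, config) {
  muE <- config@muE
  muK <- if (is.na(config@muK)) 0 else config@muK
  Q <- path@frames
  P <- nrow(Q) - 1L
  D <- ncol(Q)
  m <- massPerCoord(path)
  A <- m / path@delta^2                      # per-coordinate m/Delta^2
  kin <- .pathKinetics(path)
  sv <- surfaceOnFrames(surface, Q[1:P, , drop = FALSE], gradient = TRUE)
  Ej <- kin$Kframe + sv$energy
  e <- Ej - config@targetEnergy

  idx <- 2:P                                  # interior frames (1-based rows)
  dN <- kin$Dq[idx, , drop = FALSE]           # d_n  = q_n - q_{n+1}
  dNm1 <- kin$Dq[idx - 1L, , drop = FALSE]    # d_{n-1}
  Gn <- sv$gradient[idx, , drop = FALSE]      # grad V at interior frames
  Ad <- sweep(dN, 2L, A, "*")
  Adm <- sweep(dNm1, 2L, A, "*")

  gS <- path@delta * (Ad - Adm - Gn)
  gPen <- 2 * muE * (e[idx] * (Ad + Gn) - e[idx - 1L] * Adm)
  gRes <- 0
  if (muK > 0) {
    targetK <- 1.5 * config@kB * config@temperature
    devAtom <- kin$KatomMean - targetK
    devCoord <- rep(devAtom, each = path@adim)
    gRes <- (2 * muK / P) * sweep(Ad - Adm, 2L, devCoord, "*")
  }
  list(grad = gS + gPen + gRes, Ej = Ej,
       S = sum(kin$Kframe - sv$energy) * path@delta,
       penalty = muE * sum(e^2),
       restraint = if (muK > 0)
         muK * sum((kin$KatomMean - 1.5 * config@kB * config@temperature)^2)
       else 0,
       V = sv$energy)
}

#' Analytic gradient of the extended action in coefficient space
#'
#' Chain rule through the sine expansion: since \eqn{\partial q_j /
#' \partial a_k = \sin(k\pi j/P)}, the coefficient gradient is the sine
#' basis matrix applied to the interior-frame gradient of \eqn{\Phi}.
#'
#' @param coeffs a [SineCoefficients] (or matrix) with \eqn{P-1} rows.
#' @param q0,qP fixed endpoint conformations.
#' @param surface a [PotentialSurface].
#' @param config an [ADMDConfig] with resolved penalty weights.
#' @param delta time step (defaults to `config@delta`).
#' @param masses,adim per-atom masses and dimensionality for the path.
#' @return list with `gradient` (a \eqn{(P-1) \times D} matrix over the
#'   coefficients), `phi`, and the [ActionBreakdown]-style terms.
#' @export
phiGradient <- function(coeffs, q0, qP, surface, config, delta = config@delta,
                        masses = NULL, adim = NULL) {
  coeffs <- sineCoefficients(coeffs)
  path <- coeffsToPath(q0, qP, coeffs, delta = delta, masses = masses,
                       adim = adim)
  P <- frameCount(path)
  fg <- .phiFrameGradient(path, surface, config)
  gradCoeffs <- sineBasisMatrix(P) %*% fg$grad
  list(gradient = gradCoeffs, phi = fg$S + fg$penalty + fg$restraint,
       S = fg$S, energyPenalty = fg$penalty, kineticRestraint = fg$restraint)
}
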