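## Sine-basis path parameterization and multigrid refinement.
##
## A path with fixed endpoints is represented by the expansion
##   q_j = q_0 + (q_P - q_0) j/P + sum_{k=1}^{P-1} a_k sin(k pi j / P),
## whose basis vanishes identically at j = 0 and j = P, so the endpoints are
## reproduced exactly for every coefficient set.  The map between interior
## frames and coefficients is the orthogonal type-I discrete sine transform;
## refinement to a larger frame count is zero-padding in coefficient space
## followed by re-evaluation of the same continuum curve on the finer grid.

sineBasisMatrix <- function(P) {
  jk <- outer(seq_len(P - 1L), seq_len(P - 1L))
  sin(pi * jk / P)
}

#' @rdname pathToCoeffs
#' @param coeffs numeric matrix with coefficient vector \eqn{a_k} in row
#'   \eqn{k} (or a [SineCoefficients]).
#' @export
sineCoefficients <- function(coeffs) {
  if (is(coeffs, "SineCoefficients")) return(coeffs)
  new("SineCoefficients", coeffs = as.matrix(coeffs))
}

#' @rdname pathToCoeffs
#' @param P frame count.
#' @param D coordinates per frame.
#' @export
zeroCoefficients <- function(P, D)
  sineCoefficients(matrix(0, P - 1L, D))

#' Build a path from sine coefficients
#'
#' Evaluates the sine expansion at \eqn{j = 0..P} for the endpoints
#' \eqn{q_0}, \eqn{q_P}.  All-zero coefficients give the straight-line
#' interpolation; the endpoints are reproduced exactly because every basis
#' function vanishes there.
#'
#' @param q0,qP endpoint conformations (numeric vectors or atoms x 3
#'   matrices).
#' @param coeffs a [SineCoefficients] (or coefficient matrix) with
#'   \eqn{P-1} rows.
#' @param delta time per step.
#' @param masses,adim,system forwarded to [newPath()].
#' @return a [Path] with \eqn{P+1} frames.
#' @examples
#' p <- coeffsToPath(0, 10, zeroCoefficients(10, 1), delta = 1)
#' pathFrames(p)[, 1]  # 0 1 2 ... 10
#' @export
coeffsToPath <- function(q0, qP, coeffs, delta, masses = NULL, adim = NULL,
                         system = NULL) {
  coeffs <- sineCoefficients(coeffs)
  A <- coeffs@coeffs
  q0 <- flattenCoords(q0); qP <- flattenCoords(qP)
  if (length(q0) != length(qP))
    stop("endpoints must have equal dimensionality")
  if (ncol(A) != length(q0))
    stop(sprintf("coefficients have %d coordinates but endpoints have %d",
                 ncol(A), length(q0)))
  P <- nrow(A) + 1L
  if (P < 2L) stop("P must be >= 2")
  tFrac <- seq_len(P - 1L) / P
  linear <- outer(rep(1, P - 1L), q0) + outer(tFrac, qP - q0)
  interior <- linear + sineBasisMatrix(P) %*% A
  frames <- rbind(q0, interior, qP, deparse.level = 0)
  newPath(frames, delta = delta, masses = masses, adim = adim,
          system = system)
}

#' Sine coefficients of a path
#'
#' Exact inverse of [coeffsToPath()] on the interior frames: subtracts the
#' linear interpolation between the endpoints and applies the type-I
#' discrete sine transform, \eqn{a_k = (2/P)\sum_{j=1}^{P-1} r_j
#' \sin(k\pi j/P)}.
#'
#' @param path a [Path] with \eqn{P+1} frames, \eqn{P \ge 2}.
#' @return a [SineCoefficients] with \eqn{P-1} rows.
#' @export
pathToCoeffs <- function(path) {
  P <- frameCount(path)
  if (P < 2L) stop("P must be >= 2")
  Q <- path@frames
  q0 <- Q[1L, ]; qP <- Q[P + 1L, ]
  tFrac <- seq_len(P - 1L) / P
  linear <- outer(rep(1, P - 1L), q0) + outer(tFrac, qP - q0)
  resid <- Q[2:P, , drop = FALSE] - linear
  sineCoefficients((2 / P) * (sineBasisMatrix(P) %*% resid))
}

#' Multigrid refinement of a path
#'
#' Converts the path to sine coefficients, zero-pads to `newP - 1`
#' coefficients, and re-evaluates the identical continuum curve on the finer
#' uniform grid.  The endpoints are carried over bit-for-bit.  By default the
#' duration \eqn{\tau = P\Delta} is held fixed, so \eqn{\Delta} shrinks by
#' `P/newP`; with `fixTau = FALSE` the time step is kept instead and the
#' duration grows.
#'
#' @param path a [Path].
#' @param newP target frame count, strictly greater than the current one.
#' @param fixTau hold the total duration fixed across the refinement?
#' @return a [Path] with `newP + 1` frames.
#' @export
refinePath <- function(path, newP, fixTau = TRUE) {
  P <- frameCount(path)
  newP <- as.integer(newP)
  if (newP <= P) stop("newP (", newP, ") must exceed the current P (", P, ")")
  A <- pathToCoeffs(path)@coeffs
  Apad <- rbind(A, matrix(0, newP - P, ncol(A)))
  delta <- if (fixTau) pathDuration(path) / newP else path@delta
  out <- coeffsToPath(path@frames[1L, ], path@frames[P + 1L, ],
                      sineCoefficients(Apad), delta = delta,
                      masses = path@masses, adim = path@adim,
                      system = path@system)
  # endpoints are boundary data: carry them over exactly
  out@frames[1L, ] <- path@frames[1L, ]
  out@frames[newP + 1L, ] <- path@frames[P + 1L, ]
  out
}

#' Default multigrid frame-count schedule
#'
#' Geometric doubling from `PStart` up to just below `PFinal`, then `PFinal`
#' itself (e.g. 20, 40, ..., 1280, 2000 for the defaults).
#'
#' @param PStart first frame count.
#' @param PFinal final frame count.
#' @return increasing integer vector ending at `PFinal`.
#' @export
multigridSchedule <- function(PStart = 20L, PFinal = 2000L) {
  stopifnot(PStart >= 2L, PFinal >= PStart)
  P <- as.integer(PStart)
  out <- P
  while (2L * P < PFinal) { P <- 2L * P; out <- c(out, P) }
  if (tail(out, 1L) != PFinal) out <- c(out, as.integer(PFinal))
  out
}
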