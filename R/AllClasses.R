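#' @import methods
#' @importFrom stats optim sd cor rnorm runif setNames
#' @importFrom utils read.table write.table head tail
NULL

#' Potential-energy surface
#'
#' A pluggable potential-energy surface \eqn{V(\{q\})} with an analytic
#' gradient.  Surfaces are vectorized over conformations: the energy and
#' gradient closures accept a numeric matrix with one conformation per row
#' (flattened coordinates) and return, respectively, a numeric vector of
#' energies and a matrix of per-coordinate derivatives of the same shape.
#'
#' @slot name surface label, e.g. \code{"harmonic"} or \code{"go_chain"}.
#' @slot dim expected number of coordinates per conformation
#'   (\code{NA_integer_} for surfaces valid in any dimension, such as the
#'   free particle or isotropic harmonic well).
#' @slot energyFn closure: conformation matrix -> energy vector.
#' @slot gradFn closure: conformation matrix -> gradient matrix.
#'
#' @seealso [harmonicPotential()], [doubleWellPotential()],
#'   [muellerBrownPotential()], [ljClusterPotential()], [goChainPotential()],
#'   [evaluateSurface()]
#' @export
setClass("PotentialSurface",
  representation(name = "character", dim = "integer",
                 energyFn = "function", gradFn = "function"),
  validity = function(object) {
    if (length(object@name) != 1L) return("name must be a single string")
    if (length(object@dim) != 1L) return("dim must be a single integer")
    TRUE
  })

#' Static molecular system description
#'
#' Atom-level metadata shared by potentials and observables: names, elements,
#' masses, residue assignment and backbone/side-chain roles.  Coordinates are
#' kept separately (conformation matrices or [Path] objects) so one system can
#' describe many conformations.
#'
#' @slot atomNames PDB-style atom names (\code{"N"}, \code{"CA"}, ...).
#' @slot elements element symbols.
#' @slot masses atomic masses (amu for molecular systems, 1 for toys).
#' @slot resid 1-based residue index per atom.
#' @slot resname residue name per atom.
#' @slot role one of \code{"N"}, \code{"H"}, \code{"CA"}, \code{"C"},
#'   \code{"O"} (backbone) or \code{"side"} per atom.
#' @export
setClass("MolecularSystem",
  representation(atomNames = "character", elements = "character",
                 masses = "numeric", resid = "integer",
                 resname = "character", role = "character"),
  validity = function(object) {
    n <- length(object@atomNames)
    if (any(lengths(list(object@elements, object@masses, object@resid,
                         object@resname, object@role)) != n))
      return("all per-atom slots must have equal length")
    if (any(!is.finite(object@masses)) || any(object@masses <= 0))
      return("masses must be positive and finite")
    ok <- object@role %in% c("N", "H", "CA", "C", "O", "side")
    if (!all(ok)) return(sprintf("unknown role '%s'", object@role[!ok][1L]))
    nres <- length(unique(object@resid))
    if (sum(object@role == "CA") != nres)
      return("exactly one CA per residue is required")
    TRUE
  })

#' Discretized pathway between two fixed conformations
#'
#' An ordered sequence of \eqn{P+1} conformations \eqn{q_0, \dots, q_P} with
#' time step \eqn{\Delta} between frames, so the total duration is
#' \eqn{\tau = P\Delta}.  The endpoints \eqn{q_0} and \eqn{q_P} are the fixed
#' boundary conditions of the action minimization and are never modified by
#' any operation in this package.
#'
#' @slot frames numeric matrix, one conformation per row (\eqn{P+1} rows),
#'   flattened coordinates in columns.
#' @slot delta time per step (model units).
#' @slot masses per-atom masses.
#' @slot adim coordinates per atom (3 for molecular systems, 1 for scalar
#'   test systems).
#' @slot system optional [MolecularSystem] (or \code{NULL} for toys).
#'
#' @seealso [newPath()], [coeffsToPath()], [refinePath()]
#' @export
setClass("Path",
  representation(frames = "matrix", delta = "numeric", masses = "numeric",
                 adim = "integer", system = "ANY"),
  validity = function(object) {
    if (nrow(object@frames) < 3L) return("a path needs P >= 2 (>= 3 frames)")
    if (length(object@delta) != 1L || !is.finite(object@delta) ||
        object@delta <= 0) return("delta must be a single positive number")
    if (!object@adim %in% c(1L, 3L)) return("adim must be 1 or 3")
    if (length(object@masses) * object@adim != ncol(object@frames))
      return(sprintf("masses (%d atoms x %d dims) do not match %d coordinates",
                     length(object@masses), object@adim, ncol(object@frames)))
    if (any(object@masses <= 0)) return("masses must be positive")
    if (!all(is.finite(object@frames))) return("frames must be finite")
    TRUE
  })

#' Sine-basis coefficients of a pathway
#'
#' The interior degrees of freedom of a [Path] in the sine expansion
#' \deqn{q_j = q_0 + (q_P - q_0)\,j/P + \sum_{k=1}^{P-1} a_k \sin(k\pi j/P),}
#' stored as a \eqn{(P-1) \times D} matrix with one basis coefficient vector
#' \eqn{a_k} per row.  All-zero coefficients correspond exactly to linear
#' interpolation between the endpoints.
#'
#' @slot coeffs numeric matrix, row \eqn{k} holding \eqn{a_k}.
#' @seealso [pathToCoeffs()], [coeffsToPath()]
#' @export
setClass("SineCoefficients",
  representation(coeffs = "matrix"),
  validity = function(object) {
    if (nrow(object@coeffs) < 1L) return("need at least one coefficient row")
    if (!all(is.finite(object@coeffs))) return("coefficients must be finite")
    TRUE
  })

#' ADMD run configuration
#'
#' All tunables of a least-action pathway optimization.  \code{muE},
#' \code{muK} and \code{annealDecrement} may be \code{NA}, in which case they
#' are scaled automatically from the initial trial path (see
#' [minimizePhi()] and [annealTargetEnergy()]).
#'
#' @slot targetEnergy target total energy \eqn{E} imposed on every frame.
#' @slot temperature fictitious temperature \eqn{T} of the kinetic-energy
#'   restraint (energy units when \code{kB = 1}); not a physical temperature.
#' @slot muE weight of the total-energy penalty (\code{NA} = auto).
#' @slot muK weight of the kinetic-energy restraint (\code{NA} = auto).
#' @slot delta time step at the first frame count of \code{PSchedule}; the
#'   duration \eqn{\tau} is held fixed across refinements by default.
#' @slot PSchedule strictly increasing frame counts for multigrid refinement.
#' @slot seed integer seed controlling every random draw of a run.
#' @slot gradTol max-norm convergence threshold on the coefficient gradient.
#' @slot maxIter L-BFGS iteration cap per multigrid level.
#' @slot annealDecrement energy step of the annealing protocol (\code{NA} =
#'   5 percent of the initial gap between \eqn{E} and the endpoint energy).
#' @slot conservationTol accepted relative spread of frame energies:
#'   a solution conserves energy when \eqn{sd(E_j) \le} \code{conservationTol}
#'   \eqn{\times \max(|E|, barrier)}.
#' @slot fixTau logical; \code{TRUE} keeps \eqn{\tau = P\Delta} fixed while
#'   refining (\eqn{\Delta} shrinks), \code{FALSE} keeps \eqn{\Delta} fixed.
#' @slot kB Boltzmann constant (1 in model units).
#' @seealso [admdConfig()], [loadConfig()]
#' @export
setClass("ADMDConfig",
  representation(targetEnergy = "numeric", temperature = "numeric",
                 muE = "numeric", muK = "numeric", delta = "numeric",
                 PSchedule = "integer", seed = "integer", gradTol = "numeric",
                 maxIter = "integer", annealDecrement = "numeric",
                 conservationTol = "numeric", fixTau = "logical",
                 kB = "numeric"),
  validity = function(object) {
    P <- object@PSchedule
    if (length(P) < 1L || any(P < 2L)) return("PSchedule needs values >= 2")
    if (length(P) > 1L && any(diff(P) <= 0))
      return("PSchedule must be strictly increasing")
    if (!is.na(object@muE) && object@muE <= 0)
      return("muE must be positive (energy penalty is mandatory)")
    if (!is.na(object@muK) && object@muK < 0) return("muK must be >= 0")
    if (object@temperature < 0) return("temperature must be >= 0")
    if (!is.na(object@annealDecrement) && object@annealDecrement <= 0)
      return("annealDecrement must be positive")
    if (object@delta <= 0) return("delta must be positive")
    if (object@conservationTol <= 0) return("conservationTol must be positive")
    TRUE
  })

#' Decomposition of the extended action
#'
#' The value of the extended action \eqn{\Phi = S + \mu_E \sum_j (E_j - E)^2
#' + \mu_K \sum_I (\langle K_I\rangle - 3 k_B T/2)^2} together with each term
#' and the per-frame total energies it was built from.
#'
#' @slot S classical action.
#' @slot energyPenalty total-energy penalty term (>= 0).
#' @slot kineticRestraint kinetic-energy restraint term (>= 0).
#' @slot phi extended action, identically \code{S + energyPenalty +
#'   kineticRestraint}.
#' @slot frameEnergies total energy \eqn{E_j} for \eqn{j = 0..P-1}.
#' @slot atomMeanKinetic trajectory-averaged kinetic energy per atom.
#' @export
setClass("ActionBreakdown",
  representation(S = "numeric", energyPenalty = "numeric",
                 kineticRestraint = "numeric", phi = "numeric",
                 frameEnergies = "numeric", atomMeanKinetic = "numeric"),
  validity = function(object) {
    if (object@energyPenalty < 0) return("energyPenalty must be >= 0")
    if (object@kineticRestraint < 0) return("kineticRestraint must be >= 0")
    parts <- object@S + object@energyPenalty + object@kineticRestraint
    scale <- max(abs(object@phi), abs(object@S), 1)
    if (abs(parts - object@phi) > 1e-9 * scale)
      return("phi must equal S + energyPenalty + kineticRestraint")
    TRUE
  })

#' Optimized pathway solution
#'
#' @slot path the optimized [Path] at the final frame count.
#' @slot breakdown final [ActionBreakdown].
#' @slot energyConserved whether \eqn{sd(E_j)} met the conservation
#'   tolerance of the configuration.
#' @slot barrier potential-energy barrier: \eqn{\max_j V(q_j) - V(q_0)}.
#' @slot iterations L-BFGS iteration count per multigrid level.
#' @slot phiTrace \eqn{\Phi} at the exit of each multigrid level.
#' @slot config the [ADMDConfig] used.
#' @export
setClass("PathwaySolution",
  representation(path = "Path", breakdown = "ActionBreakdown",
                 energyConserved = "logical", barrier = "numeric",
                 iterations = "integer", phiTrace = "numeric",
                 config = "ADMDConfig"))

#' Principal component analysis of C-alpha fluctuations
#'
#' @slot values eigenvalues of the covariance matrix, descending.
#' @slot vectors orthonormal eigenvectors (columns), \eqn{3 N_\alpha} rows.
#' @slot varianceFractions eigenvalue / trace, summing to one.
#' @slot projections per-frame scores on each component.
#' @slot center mean C-alpha structure (\eqn{N_\alpha \times 3}).
#' @slot resid residue index per C-alpha atom.
#' @export
setClass("PCAResult",
  representation(values = "numeric", vectors = "matrix",
                 varianceFractions = "numeric", projections = "matrix",
                 center = "matrix", resid = "integer"),
  validity = function(object) {
    if (abs(sum(object@varianceFractions) - 1) > 1e-8)
      return("variance fractions must sum to 1")
    if (min(object@values) < -1e-8 * max(abs(object@values), 1))
      return("covariance eigenvalues must be non-negative")
    TRUE
  })

## ---- small constructors / accessors -------------------------------------

#' Construct a Path
#'
#' @param frames numeric matrix of conformations, one frame per row, or a
#'   list of equal-length numeric vectors/matrices.
#' @param delta time per step.
#' @param masses per-atom masses (default all 1).
#' @param adim coordinates per atom (1 or 3).
#' @param system optional [MolecularSystem].
#' @return a [Path].
#' @examples
#' p <- newPath(rbind(0, 0.5, 1), delta = 0.1)
#' frameCount(p)  # P = 2
#' @export
newPath <- function(frames, delta, masses = NULL, adim = NULL, system = NULL) {
  if (is.list(frames))
    frames <- do.call(rbind, lapply(frames, function(f) as.numeric(t(f))))
  fm <- as.matrix(frames)
  frames <- matrix(as.numeric(fm), nrow(fm), ncol(fm))  # strip classes/names
  if (is.null(adim)) {
    adim <- if (!is.null(system)) 3L
            else if (ncol(frames) %% 3L == 0L && ncol(frames) > 1L) 3L else 1L
  }
  adim <- as.integer(adim)
  if (is.null(masses)) {
    masses <- if (!is.null(system)) system@masses
              else rep(1, ncol(frames) %/% adim)
  }
  new("Path", frames = frames, delta = as.numeric(delta),
      masses = as.numeric(masses), adim = adim,
      system = if (is.null(system)) NULL else system)
}

#' @rdname newPath
#' @param path a [Path].
#' @return `frameCount()`: the number of steps \eqn{P} (the path holds
#'   \eqn{P+1} frames).
#' @export
frameCount <- function(path) nrow(path@frames) - 1L

#' @rdname newPath
#' @return `pathFrames()`: the \eqn{(P+1) \times D} frame matrix.
#' @export
pathFrames <- function(path) path@frames

#' @rdname newPath
#' @return `pathDelta()`: the time step \eqn{\Delta}.
#' @export
pathDelta <- function(path) path@delta

#' @rdname newPath
#' @return `pathDuration()`: the total duration \eqn{\tau = P\Delta}.
#' @export
pathDuration <- function(path) frameCount(path) * path@delta

#' Per-coordinate mass vector of a path
#'
#' Replicates each atom's mass over its `adim` Cartesian components, the
#' layout used by all kinetic-energy sums.
#' @param path a [Path].
#' @return numeric vector of length `ncol(pathFrames(path))`.
#' @keywords internal
massPerCoord <- function(path) rep(path@masses, each = path@adim)

#' Residue-level accessors for a molecular system
#'
#' @param system a [MolecularSystem].
#' @return `residueCount()`: number of residues; `calphaIndices()`: atom
#'   indices of the C-alpha atoms in residue order; `atomCount()`: number of
#'   atoms.
#' @export
residueCount <- function(system) length(unique(system@resid))

#' @rdname residueCount
#' @export
calphaIndices <- function(system) {
  idx <- which(system@role == "CA")
  idx[order(system@resid[idx])]
}

#' @rdname residueCount
#' @export
atomCount <- function(system) length(system@atomNames)

#' Coordinates of one frame as an atoms x 3 matrix
#' @param path a [Path].
#' @param j frame index, 0-based as in the action sums (0..P).
#' @return numeric matrix with one atom per row.
#' @export
frameCoords <- function(path, j) {
  P <- frameCount(path)
  if (j < 0 || j > P) stop("frame index must lie in 0..P = 0..", P)
  matrix(path@frames[j + 1L, ], ncol = path@adim, byrow = TRUE)
}

## flattened (row-vector) view of an atoms x adim coordinate matrix
flattenCoords <- function(x) {
  if (is.matrix(x)) as.numeric(t(x)) else as.numeric(x)
}
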