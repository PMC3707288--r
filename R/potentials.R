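## Analytic potential-energy surfaces.  Every surface is vectorized over
## conformations (rows) so the action module can evaluate a whole path in one
## call; gradients are analytic throughout (finite differences are test-only).

newSurface <- function(name, dim, energyFn, gradFn) {
  new("PotentialSurface", name = name, dim = as.integer(dim),
      energyFn = energyFn, gradFn = gradFn)
}

.asConfMatrix <- function(surface, conformation) {
  x <- if (is.matrix(conformation)) conformation
       else matrix(as.numeric(conformation), nrow = 1L)
  if (!is.na(surface@dim) && ncol(x) != surface@dim)
    stop(sprintf("surface '%s' expects %d coordinates, got %d",
                 surface@name, surface@dim, ncol(x)))
  x
}

#' Evaluate a potential surface
#'
#' @param surface a [PotentialSurface].
#' @param conformation numeric vector (flattened coordinates) or an
#'   atoms x 3 matrix for molecular surfaces.
#' @return list with `energy` (scalar) and `gradient` (numeric vector of the
#'   conformation's length).
#' @examples
#' s <- harmonicPotential(k = 1)
#' evaluateSurface(s, 2)  # energy 2, gradient 2
#' @export
evaluateSurface <- function(surface, conformation) {
  x <- .asConfMatrix(surface, flattenCoords(conformation))
  list(energy = as.numeric(surface@energyFn(x))[1L],
       gradient = as.numeric(surface@gradFn(x)[1L, ]))
}

#' Path-wise surface evaluation
#'
#' Energies (and optionally gradients) of every frame of a matrix of
#' conformations in one vectorized call.
#' @param surface a [PotentialSurface].
#' @param frames conformations as rows.
#' @param gradient also return the per-frame gradient matrix?
#' @return list with `energy` vector and, if requested, `gradient` matrix.
#' @export
surfaceOnFrames <- function(surface, frames, gradient = FALSE) {
  x <- .asConfMatrix(surface, frames)
  out <- list(energy = as.numeric(surface@energyFn(x)))
  if (gradient) out$gradient <- surface@gradFn(x)
  out
}

#' Toy potential surfaces
#'
#' @description
#' `freeParticlePotential()`: \eqn{V \equiv 0} in any dimension.
#'
#' `harmonicPotential()`: isotropic well \eqn{V = \sum_c \tfrac12 k (q_c -
#' center)^2} applied per coordinate, valid in any dimension.
#'
#' `doubleWellPotential()`: the 1-D quartic \eqn{V = (q^2 - 1)^2} with minima
#' at \eqn{q = \pm 1} and a barrier of height 1 at \eqn{q = 0}.
#'
#' `muellerBrownPotential()`: the standard two-dimensional Mueller-Brown
#' surface, a sum of four anisotropic Gaussians with three minima and two
#' saddle points; the classic benchmark for transition-path methods.
#'
#' `ljClusterPotential()`: pairwise Lennard-Jones 12-6 cluster of `natoms`
#' atoms in 3-D.
#'
#' @param k force constant.
#' @param center well center (recycled per coordinate).
#' @param natoms number of atoms of the Lennard-Jones cluster.
#' @param epsilon,sigma Lennard-Jones well depth and diameter.
#' @return a [PotentialSurface].
#' @export
freeParticlePotential <- function() {
  newSurface("free_particle", NA_integer_,
             function(x) numeric(nrow(x)),
             function(x) array(0, dim(x)))
}

#' @rdname freeParticlePotential
#' @export
harmonicPotential <- function(k = 1, center = 0) {
  force(k); force(center)
  newSurface("harmonic", NA_integer_,
             function(x) 0.5 * k * rowSums(sweep(x, 2L, center)^2),
             function(x) k * sweep(x, 2L, center))
}

#' @rdname freeParticlePotential
#' @export
doubleWellPotential <- function() {
  newSurface("double_well", 1L,
             function(x) (x[, 1L]^2 - 1)^2,
             function(x) cbind(4 * x[, 1L] * (x[, 1L]^2 - 1)))
}

#' @rdname freeParticlePotential
#' @export
muellerBrownPotential <- function() {
  A <- c(-200, -100, -170, 15)
  a <- c(-1, -1, -6.5, 0.7)
  b <- c(0, 0, 11, 0.6)
  cc <- c(-10, -10, -6.5, 0.7)
  x0 <- c(1, 0, -0.5, -1)
  y0 <- c(0, 0.5, 1.5, 1)
  terms <- function(x) {
    dx <- outer(x[, 1L], x0, "-"); dy <- outer(x[, 2L], y0, "-")
    e <- exp(sweep(dx^2, 2L, a, "*") + dx * dy * rep(b, each = nrow(x)) +
             sweep(dy^2, 2L, cc, "*"))
    list(e = sweep(e, 2L, A, "*"), dx = dx, dy = dy)
  }
  newSurface("mueller_brown", 2L,
    function(x) rowSums(terms(x)$e),
    function(x) {
      t <- terms(x)
      gx <- rowSums(t$e * (2 * sweep(t$dx, 2L, a, "*") +
                           sweep(t$dy, 2L, b, "*")))
      gy <- rowSums(t$e * (sweep(t$dx, 2L, b, "*") +
                           2 * sweep(t$dy, 2L, cc, "*")))
      cbind(gx, gy, deparse.level = 0)
    })
}

#' @rdname freeParticlePotential
#' @export
ljClusterPotential <- function(natoms, epsilon = 1, sigma = 1) {
  natoms <- as.integer(natoms)
  stopifnot(natoms >= 2L)
  pairs <- which(upper.tri(matrix(0, natoms, natoms)), arr.ind = TRUE)
  pairEnergyGrad <- function(x, gradient) {
    n <- nrow(x)
    ax <- (pairs[, 1L] - 1L) * 3L; bx <- (pairs[, 2L] - 1L) * 3L
    E <- numeric(n)
    G <- if (gradient) array(0, dim(x)) else NULL
    d2 <- 0
    for (c in 1:3) d2 <- d2 + (x[, ax + c, drop = FALSE] -
                               x[, bx + c, drop = FALSE])^2
    s6 <- (sigma^2 / d2)^3
    E <- rowSums(4 * epsilon * (s6^2 - s6))
    if (gradient) {
      # dV/dr2 = 4 eps (-12 s12 + 6 s6) / (2 r2) applied to each component
      f <- 4 * epsilon * (-12 * s6^2 + 6 * s6) / d2
      for (c in 1:3) {
        dd <- x[, ax + c, drop = FALSE] - x[, bx + c, drop = FALSE]
        contrib <- f * dd
        for (p in seq_len(nrow(pairs))) {
          G[, ax[p] + c] <- G[, ax[p] + c] + contrib[, p]
          G[, bx[p] + c] <- G[, bx[p] + c] - contrib[, p]
        }
      }
    }
    list(E = E, G = G)
  }
  newSurface("lj_cluster", 3L * natoms,
             function(x) pairEnergyGrad(x, FALSE)$E,
             function(x) pairEnergyGrad(x, TRUE)$G)
}

#' Select a shipped surface by name
#'
#' @param name one of `"free_particle"`, `"harmonic"`, `"double_well"`,
#'   `"mueller_brown"`, `"lj_cluster"`, `"go_chain"`.
#' @param ... forwarded to the surface constructor (e.g. `k`, `natoms`, or
#'   the Go-chain reference system and parameters).
#' @return a [PotentialSurface].
#' @export
potentialByName <- function(name, ...) {
  switch(name,
         free_particle = freeParticlePotential(),
         harmonic = harmonicPotential(...),
         double_well = doubleWellPotential(),
         mueller_brown = muellerBrownPotential(),
         lj_cluster = ljClusterPotential(...),
         go_chain = goChainPotential(...),
         stop("unknown potential: ", name))
}

## ---- stationary-point location ------------------------------------------

numericalHessian <- function(surface, q, h = 1e-5) {
  d <- length(q)
  H <- matrix(0, d, d)
  for (i in seq_len(d)) {
    qp <- q; qp[i] <- qp[i] + h
    qm <- q; qm[i] <- qm[i] - h
    H[i, ] <- (evaluateSurface(surface, qp)$gradient -
               evaluateSurface(surface, qm)$gradient) / (2 * h)
  }
  (H + t(H)) / 2
}

#' Locate minima and saddle points of a low-dimensional surface
#'
#' Dense grid scan of the squared gradient norm followed by local refinement
#' (quasi-Newton polish of \eqn{|\nabla V|^2}) and classification by the
#' eigenvalue signature of a finite-difference Hessian.  Intended as a
#' validation aid for pathway quality on 1-D and 2-D analytic surfaces.
#'
#' @param surface a 1-D or 2-D [PotentialSurface].
#' @param lower,upper numeric bounds of the scan window (length = dim).
#' @param resolution grid spacing of the initial scan.
#' @return data.frame with the stationary point coordinates, `energy`, and
#'   `type` (`"minimum"`, `"saddle"`, `"maximum"`); zero rows (with a
#'   warning) when the window contains no stationary point.
#' @examples
#' locateStationaryPoints(doubleWellPotential(), -2, 2)
#' @export
locateStationaryPoints <- function(surface, lower, upper, resolution = 0.01) {
  d <- surface@dim
  if (is.na(d)) d <- length(lower)        # dimension-agnostic surfaces
  if (!d %in% c(1L, 2L))
    stop("stationary-point scan supports 1-D and 2-D surfaces only")
  stopifnot(length(lower) == d, length(upper) == d, all(upper > lower))
  grids <- lapply(seq_len(d), function(i)
    seq(lower[i], upper[i], by = resolution))
  pts <- as.matrix(expand.grid(grids))
  colnames(pts) <- NULL
  g <- surface@gradFn(pts)
  gn <- rowSums(g^2)
  nx <- length(grids[[1L]])
  candIdx <- if (d == 1L) {
    which(diff(sign(g[, 1L])) != 0)            # sign changes bracket roots
  } else {
    ny <- length(grids[[2L]])
    gnm <- matrix(gn, nrow = nx)               # expand.grid: x varies fastest
    keep <- integer(0)
    inner <- function(m) m[2:(nx - 1L), 2:(ny - 1L)]
    isMin <- inner(gnm) < 1e300
    for (dx in -1:1) for (dy in -1:1) {
      if (dx == 0 && dy == 0) next
      isMin <- isMin & (inner(gnm) <=
        gnm[2:(nx - 1L) + dx, 2:(ny - 1L) + dy])
    }
    ij <- which(isMin, arr.ind = TRUE)
    (ij[, 2L]) * nx + (ij[, 1L] + 1L)          # back to expand.grid index
  }
  found <- list()
  for (i in candIdx) {
    q <- pts[i, ]
    for (it in 1:60) {                       # Newton polish of grad V = 0
      g <- evaluateSurface(surface, q)$gradient
      if (sqrt(sum(g^2)) < 1e-10 * max(1, sqrt(gn[i]))) break
      H <- numericalHessian(surface, q)
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step)) break
      if (sqrt(sum(step^2)) > 5 * resolution)   # keep inside the basin
        step <- step * 5 * resolution / sqrt(sum(step^2))
      q <- q - step
    }
    g <- evaluateSurface(surface, q)$gradient
    if (sqrt(sum(g^2)) > 1e-6 * max(1, sqrt(gn[i]))) next
    if (any(q < lower - resolution) || any(q > upper + resolution)) next
    dup <- any(vapply(found, function(p)
      sqrt(sum((p$q - q)^2)) < 10 * resolution, logical(1)))
    if (dup) next
    ev <- eigen(numericalHessian(surface, q), symmetric = TRUE,
                only.values = TRUE)$values
    type <- if (all(ev > 0)) "minimum"
            else if (all(ev < 0)) "maximum" else "saddle"
    found[[length(found) + 1L]] <-
      list(q = q, energy = evaluateSurface(surface, q)$energy, type = type)
  }
  if (!length(found)) {
    warning("no stationary point found in the scan window")
    out <- as.data.frame(matrix(numeric(0), 0, d))
    names(out) <- paste0("q", seq_len(d))
    out$energy <- numeric(0); out$type <- character(0)
    return(out)
  }
  coords <- do.call(rbind, lapply(found, `[[`, "q"))
  out <- as.data.frame(coords)
  names(out) <- paste0("q", seq_len(d))
  out$energy <- vapply(found, `[[`, numeric(1), "energy")
  out$type <- vapply(found, `[[`, character(1), "type")
  out[order(out$energy), , drop = FALSE]
}
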