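## Structure-based (Go-type) coarse-grained chain potential.  The native
## conformation defines the topology: covalent and 1-3 virtual bonds are
## harmonic at their native lengths, native C-alpha contact pairs get
## attractive 12-6 wells with minima at the native distances, and non-native
## C-alpha pairs feel a force-shifted excluded-volume repulsion that is
## exactly zero beyond its cutoff.  The native conformation is therefore an
## exact stationary point (every term sits at its minimum and the repulsion
## is inactive there, since non-native pairs are >= 6.5 A apart by the
## contact rule while the repulsion cutoff is below that).

.atomIdx <- function(system, resid, role) {
  i <- which(system@resid == resid & system@role == role)
  if (length(i)) i[1L] else NA_integer_
}

.goBondTopology <- function(system) {
  nres <- residueCount(system)
  res <- sort(unique(system@resid))
  pairs <- list()
  add <- function(a, b) if (!is.na(a) && !is.na(b))
    pairs[[length(pairs) + 1L]] <<- c(a, b)
  for (r in res) {
    N <- .atomIdx(system, r, "N");  H <- .atomIdx(system, r, "H")
    CA <- .atomIdx(system, r, "CA"); C <- .atomIdx(system, r, "C")
    O <- .atomIdx(system, r, "O")
    side <- which(system@resid == r & system@role == "side")
    add(N, CA); add(CA, C); add(C, O); add(N, H)
    if (length(side)) add(CA, side[1L])
    # 1-3 virtual bonds freeze the bond angles without angle terms
    add(N, C); add(H, CA); add(O, CA)
    if (length(side)) { add(side[1L], N); add(side[1L], C) }
    if (r < max(res)) {
      Nn <- .atomIdx(system, r + 1L, "N"); CAn <- .atomIdx(system, r + 1L, "CA")
      add(C, Nn); add(CA, Nn); add(C, CAn); add(O, Nn)
      Hn <- .atomIdx(system, r + 1L, "H")
      add(C, Hn)
    }
  }
  do.call(rbind, pairs)
}

## pair distances squared for all frames at once: X is frames x 3N
.pairDist2 <- function(X, a, b) {
  ax <- (a - 1L) * 3L; bx <- (b - 1L) * 3L
  d2 <- 0
  for (c in 1:3) d2 <- d2 + (X[, ax + c, drop = FALSE] -
                             X[, bx + c, drop = FALSE])^2
  d2
}

## accumulate per-pair radial force factors into a gradient matrix.
## fOverR[n, p] must hold (dV/dr)/r for pair p in frame n; the per-atom
## scatter is a single incidence-matrix product per Cartesian component.
.accumulatePairGrad <- function(G, X, a, b, fOverR) {
  natoms <- ncol(X) %/% 3L
  np <- length(a)
  M <- matrix(0, np, natoms)
  M[cbind(seq_len(np), a)] <- M[cbind(seq_len(np), a)] + 1
  M[cbind(seq_len(np), b)] <- M[cbind(seq_len(np), b)] - 1
  atomCols <- (seq_len(natoms) - 1L) * 3L
  for (c in 1:3) {
    dd <- X[, (a - 1L) * 3L + c, drop = FALSE] -
          X[, (b - 1L) * 3L + c, drop = FALSE]
    G[, atomCols + c] <- G[, atomCols + c, drop = FALSE] + (fOverR * dd) %*% M
  }
  G
}

#' Go-type chain potential built from a native reference
#'
#' @param system a [MolecularSystem] describing the chain.
#' @param native native conformation, atoms x 3 matrix (the reference whose
#'   geometry defines every equilibrium value).
#' @param epsilon depth of each native-contact well (model units).
#' @param kBond stiffness of covalent and 1-3 virtual bonds.
#' @param kLocal stiffness of the (i, i+2) C-alpha terms that stand in for
#'   backbone angle bias.
#' @param repEpsilon,repSigma,repCutoff excluded-volume repulsion between
#'   non-native C-alpha pairs: a force-shifted \eqn{(\sigma/r)^{12}} wall,
#'   zero at and beyond `repCutoff` (which must stay below the contact
#'   cutoff so the native state feels no repulsion).
#' @param rule [ContactRule] used to pick the native C-alpha pairs; the same
#'   definition the analysis module uses (one contact definition everywhere).
#' @return a [PotentialSurface] over `3 * atomCount(system)` coordinates.
#' @examples
#' toy <- makeToyProtein(nres = 8, seed = 1)
#' go <- goChainPotential(toy$system, toy$native)
#' evaluateSurface(go, toy$native)$energy < evaluateSurface(go, toy$disordered)$energy
#' @export
goChainPotential <- function(system, native, epsilon = 1, kBond = 200,
                             kLocal = 20, repEpsilon = 1, repSigma = 4,
                             repCutoff = 6, rule = contactRule()) {
  stopifnot(is(system, "MolecularSystem"), is.matrix(native),
            nrow(native) == atomCount(system), ncol(native) == 3L)
  if (repCutoff >= rule@calphaCutoff)
    stop("repCutoff must be below the native-contact cutoff")
  natFlat <- matrix(flattenCoords(native), nrow = 1L)
  bonds <- .goBondTopology(system)
  bondR0 <- sqrt(.pairDist2(natFlat, bonds[, 1L], bonds[, 2L]))[1L, ]

  ca <- calphaIndices(system)
  nres <- length(ca)
  caPairs <- which(upper.tri(matrix(0, nres, nres)), arr.ind = TRUE)
  sep <- caPairs[, 2L] - caPairs[, 1L]
  caD <- sqrt(.pairDist2(natFlat, ca[caPairs[, 1L]], ca[caPairs[, 2L]]))[1L, ]
  isNative <- sep >= rule@minSeparation & caD < rule@calphaCutoff
  isLocal <- sep == 2L
  isRep <- sep >= rule@minSeparation & !isNative

  natA <- ca[caPairs[isNative, 1L]]; natB <- ca[caPairs[isNative, 2L]]
  natR0 <- caD[isNative]
  locA <- ca[caPairs[isLocal, 1L]]; locB <- ca[caPairs[isLocal, 2L]]
  locR0 <- caD[isLocal]
  repA <- ca[caPairs[isRep, 1L]]; repB <- ca[caPairs[isRep, 2L]]

  s12c <- (repSigma / repCutoff)^12
  dudrC <- -12 * repEpsilon * s12c / repCutoff   # u'(cutoff), for force shift

  core <- function(X, gradient) {
    n <- nrow(X)
    E <- numeric(n)
    G <- if (gradient) array(0, dim(X)) else NULL

    if (nrow(bonds)) {
      r <- sqrt(.pairDist2(X, bonds[, 1L], bonds[, 2L]))
      dr <- sweep(r, 2L, bondR0)
      E <- E + 0.5 * kBond * rowSums(dr^2)
      if (gradient)
        G <- .accumulatePairGrad(G, X, bonds[, 1L], bonds[, 2L],
                                 kBond * dr / r)
    }
    if (length(locA)) {
      r <- sqrt(.pairDist2(X, locA, locB))
      dr <- sweep(r, 2L, locR0)
      E <- E + 0.5 * kLocal * rowSums(dr^2)
      if (gradient)
        G <- .accumulatePairGrad(G, X, locA, locB, kLocal * dr / r)
    }
    if (length(natA)) {
      u <- .pairDist2(X, natA, natB)
      s3 <- sweep(1 / u, 2L, natR0^2, "*")^3        # (r0^2/r^2)^3
      E <- E + epsilon * rowSums(s3^2 - 2 * s3)
      if (gradient) {
        dVdu <- 6 * epsilon * (s3 - s3^2) / u       # dV/d(r^2)
        G <- .accumulatePairGrad(G, X, natA, natB, 2 * dVdu)
      }
    }
    if (length(repA)) {
      r <- sqrt(.pairDist2(X, repA, repB))
      inside <- r < repCutoff
      if (any(inside)) {
        s12 <- (repSigma / r)^12
        V <- repEpsilon * s12 - repEpsilon * s12c - dudrC * (r - repCutoff)
        V[!inside] <- 0
        E <- E + rowSums(V)
        if (gradient) {
          dVdr <- -12 * repEpsilon * s12 / r - dudrC
          dVdr[!inside] <- 0
          G <- .accumulatePairGrad(G, X, repA, repB, dVdr / r)
        }
      }
    }
    list(E = E, G = G)
  }
  newSurface("go_chain", 3L * atomCount(system),
             function(x) core(x, FALSE)$E,
             function(x) core(x, TRUE)$G)
}
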