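## Trajectory observables: radius of gyration, best-fit RMSD, native
## contacts, backbone hydrogen bonds, side-chain group distances, and
## correlation coefficients.  All geometric observables take bare atoms x 3
## coordinate matrices so they apply equally to single conformations and to
## frames sliced out of a Path.

#' Contact and hydrogen-bond rules
#'
#' `contactRule()`: a native contact exists between two residues separated
#' by more than two positions in sequence (\eqn{|i-j| \ge 3}) when their
#' C-alpha distance is below the cutoff (default 6.5 A) in the native
#' structure; the same cutoff decides whether the pair is formed in any
#' other frame.
#'
#' `hbondRule()`: a backbone hydrogen bond exists between a carbonyl oxygen
#' and an amide hydrogen closer than the cutoff (default 2.5 A) when the
#' virtual bond angle among oxygen, nitrogen and hydrogen exceeds the
#' threshold (default 135 degrees).  The angle vertex defaults to the
#' hydrogen (the N-H...O angle, 180 degrees for a collinear bond); `vertex =
#' "N"` switches to the angle measured at the nitrogen.
#'
#' @param calphaCutoff C-alpha distance cutoff in Angstrom.
#' @param minSeparation minimum residue-index separation (a pair counts only
#'   when \eqn{|i-j| \ge} `minSeparation`).
#' @param ohCutoff O...H distance cutoff in Angstrom.
#' @param angleThreshold minimum virtual bond angle in degrees.
#' @param vertex atom at which the angle is measured, `"H"` or `"N"`.
#' @return a `ContactRule` / `HBondRule` object.
#' @export
contactRule <- function(calphaCutoff = 6.5, minSeparation = 3L) {
  new("ContactRule", calphaCutoff = calphaCutoff,
      minSeparation = as.integer(minSeparation))
}

#' @rdname contactRule
#' @export
hbondRule <- function(ohCutoff = 2.5, angleThreshold = 135, vertex = "H") {
  new("HBondRule", ohCutoff = ohCutoff, angleThreshold = angleThreshold,
      vertex = match.arg(vertex, c("H", "N")))
}

setClass("ContactRule",
  representation(calphaCutoff = "numeric", minSeparation = "integer"),
  validity = function(object) {
    if (object@calphaCutoff <= 0) return("cutoff must be positive")
    TRUE
  })

setClass("HBondRule",
  representation(ohCutoff = "numeric", angleThreshold = "numeric",
                 vertex = "character"),
  validity = function(object) {
    if (object@ohCutoff <= 0) return("cutoff must be positive")
    if (object@angleThreshold <= 0 || object@angleThreshold >= 180)
      return("angle threshold must lie strictly between 0 and 180 degrees")
    if (!object@vertex %in% c("H", "N")) return("vertex must be 'H' or 'N'")
    TRUE
  })

.asCoordMatrix <- function(conformation) {
  if (is.matrix(conformation) && ncol(conformation) == 3L)
    return(conformation)
  x <- flattenCoords(conformation)
  if (length(x) %% 3L != 0L)
    stop("conformation length is not a multiple of 3")
  matrix(x, ncol = 3L, byrow = TRUE)
}

#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of the atoms from their
#' mass-weighted centroid; set unit masses for the unweighted variant.
#'
#' @param conformation atoms x 3 coordinate matrix (or flattened vector).
#' @param masses per-atom masses (default: all 1).
#' @return scalar length.
#' @examples
#' radiusOfGyration(rbind(c(0, 0, 0), c(2, 0, 0)))  # 1
#' @export
radiusOfGyration <- function(conformation, masses = NULL) {
  x <- .asCoordMatrix(conformation)
  if (nrow(x) < 1L) stop("conformation must contain at least one atom")
  if (is.null(masses)) masses <- rep(1, nrow(x))
  stopifnot(length(masses) == nrow(x), all(masses > 0))
  w <- masses / sum(masses)
  centroid <- colSums(x * w)
  sqrt(sum(w * rowSums(sweep(x, 2L, centroid)^2)))
}

#' Best-fit root-mean-square deviation
#'
#' Minimum RMSD over rigid rotations and translations (Kabsch
#' superposition), computed on the selected atoms (C-alpha by default when a
#' system is supplied, every atom otherwise).
#'
#' @param confA,confB conformations (atoms x 3 matrices or flattened
#'   vectors) with equal selected-atom counts.
#' @param system optional [MolecularSystem] used to resolve the selection.
#' @param selection `"calpha"`, `"backbone"` or `"all"`.
#' @return scalar RMSD (same length unit as the coordinates).
#' @export
fitRMSD <- function(confA, confB, system = NULL,
                    selection = c("calpha", "backbone", "all")) {
  selection <- match.arg(selection)
  a <- .asCoordMatrix(confA); b <- .asCoordMatrix(confB)
  if (!is.null(system)) {
    idx <- switch(selection,
      calpha = calphaIndices(system),
      backbone = which(system@role %in% c("N", "CA", "C", "O")),
      all = seq_len(atomCount(system)))
    a <- a[idx, , drop = FALSE]; b <- b[idx, , drop = FALSE]
  }
  if (nrow(a) != nrow(b))
    stop(sprintf("selected atom counts differ: %d vs %d", nrow(a), nrow(b)))
  # superpose with bio3d's Kabsch fit, then measure at full precision
  flatB <- flattenCoords(b)
  fitted <- bio3d::fit.xyz(fixed = flatB,
                           mobile = matrix(flattenCoords(a), nrow = 1L),
                           fixed.inds = seq_along(flatB),
                           mobile.inds = seq_along(flatB))
  sqrt(mean((as.numeric(fitted) - flatB)^2) * 3)
}

.caDistMatrixPairs <- function(caXYZ, pairs) {
  sqrt(rowSums((caXYZ[pairs[, 1L], , drop = FALSE] -
                caXYZ[pairs[, 2L], , drop = FALSE])^2))
}

#' Native contact pairs of a reference structure
#'
#' @param native native conformation (atoms x 3).
#' @param system a [MolecularSystem].
#' @param rule a `ContactRule`.
#' @return two-column matrix of residue index pairs (i < j).
#' @export
nativeContactPairs <- function(native, system, rule = contactRule()) {
  ca <- calphaIndices(system)
  if (length(ca) != residueCount(system))
    stop("missing C-alpha for residue ",
         setdiff(unique(system@resid), system@resid[ca])[1L])
  x <- .asCoordMatrix(native)[ca, , drop = FALSE]
  nres <- nrow(x)
  pairs <- which(upper.tri(matrix(0, nres, nres)), arr.ind = TRUE)
  pairs <- pairs[pairs[, 2L] - pairs[, 1L] >= rule@minSeparation, ,
                 drop = FALSE]
  d <- .caDistMatrixPairs(x, pairs)
  out <- pairs[d < rule@calphaCutoff, , drop = FALSE]
  dimnames(out) <- list(NULL, c("i", "j"))
  out
}

#' Native contacts formed in a conformation
#'
#' The native pair set is derived from the native conformation by the
#' contact rule; a native pair counts as formed in a frame when its C-alpha
#' distance in that frame satisfies the same cutoff.
#'
#' @param conformation frame to evaluate (atoms x 3).
#' @param native native conformation defining the pair set.
#' @param system a [MolecularSystem].
#' @param rule a `ContactRule`.
#' @return list with `pairs` (native residue pairs), `formed` (logical per
#'   pair), `formedPairs`, `count` and `fraction` (1 when every native pair
#'   is formed; defined as 1 for a structure with no native pairs).
#' @export
nativeContacts <- function(conformation, native, system,
                           rule = contactRule()) {
  pairs <- nativeContactPairs(native, system, rule)
  ca <- calphaIndices(system)
  x <- .asCoordMatrix(conformation)[ca, , drop = FALSE]
  if (nrow(pairs) == 0L)
    return(list(pairs = pairs, formed = logical(0),
                formedPairs = pairs, count = 0L, fraction = 1))
  d <- .caDistMatrixPairs(x, pairs)
  formed <- d < rule@calphaCutoff
  list(pairs = pairs, formed = formed,
       formedPairs = pairs[formed, , drop = FALSE],
       count = sum(formed), fraction = mean(formed))
}

.virtualAngle <- function(o, n, h, vertex) {
  if (vertex == "H") { u <- n - h; v <- o - h }
  else { u <- o - n; v <- h - n }
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Backbone hydrogen bonds of a conformation
#'
#' All carbonyl-oxygen / amide-hydrogen pairs closer than the distance
#' cutoff whose virtual bond angle (see [hbondRule()]) exceeds the angular
#' threshold.  Residues without a backbone amide hydrogen (the chain start,
#' prolines) contribute no donor and are reported in `skipped`.
#'
#' @param conformation atoms x 3 coordinates.
#' @param system a [MolecularSystem] with backbone roles assigned.
#' @param rule an `HBondRule`.
#' @return list with `bonds` (data.frame: `oRes`, `hRes`, `oAtom`, `hAtom`,
#'   `dist`, `angle`), `count`, and `skipped` (residues lacking an amide H).
#' @export
backboneHBonds <- function(conformation, system, rule = hbondRule()) {
  x <- .asCoordMatrix(conformation)
  oIdx <- which(system@role == "O")
  hIdx <- which(system@role == "H")
  res <- sort(unique(system@resid))
  skipped <- setdiff(res, system@resid[hIdx])
  bonds <- data.frame(oRes = integer(0), hRes = integer(0),
                      oAtom = integer(0), hAtom = integer(0),
                      dist = numeric(0), angle = numeric(0))
  for (o in oIdx) for (h in hIdx) {
    d <- sqrt(sum((x[o, ] - x[h, ])^2))
    if (d >= rule@ohCutoff) next
    nIdx <- which(system@resid == system@resid[h] & system@role == "N")
    if (!length(nIdx)) next
    ang <- .virtualAngle(x[o, ], x[nIdx[1L], ], x[h, ], rule@vertex)
    if (ang <= rule@angleThreshold) next
    bonds[nrow(bonds) + 1L, ] <- list(system@resid[o], system@resid[h],
                                      o, h, d, ang)
  }
  list(bonds = bonds, count = nrow(bonds), skipped = skipped)
}

#' Fraction of native hydrogen bonds formed
#'
#' The native bond set is the (oRes, hRes) pair list of the native frame; a
#' frame's fraction is the share of those pairs present in it.
#'
#' @inheritParams backboneHBonds
#' @param native native conformation defining the reference bond set.
#' @return list with `fraction`, `count`, `nativeCount`.
#' @export
hbondFraction <- function(conformation, native, system, rule = hbondRule()) {
  keyOf <- function(b) paste(b$oRes, b$hRes, sep = "-")
  natKeys <- keyOf(backboneHBonds(native, system, rule)$bonds)
  frameBonds <- backboneHBonds(conformation, system, rule)$bonds
  if (!length(natKeys))
    return(list(fraction = 1, count = 0L, nativeCount = 0L))
  present <- natKeys %in% keyOf(frameBonds)
  list(fraction = mean(present), count = sum(present),
       nativeCount = length(natKeys))
}

#' Distance between two residues' side-chain groups
#'
#' Distance between side-chain heavy-atom centroids (default) or the
#' minimum heavy-atom distance; for residues without side-chain atoms
#' (glycine) the C-alpha substitutes for the side chain.
#'
#' @param conformation atoms x 3 coordinates.
#' @param system a [MolecularSystem].
#' @param residueA,residueB 1-based residue indices.
#' @param mode `"centroid"` or `"min"`.
#' @return scalar distance.
#' @export
groupDistance <- function(conformation, system, residueA, residueB,
                          mode = c("centroid", "min")) {
  mode <- match.arg(mode)
  x <- .asCoordMatrix(conformation)
  pick <- function(r) {
    if (!r %in% system@resid) stop("unknown residue index ", r)
    idx <- which(system@resid == r & system@role == "side" &
                 system@elements != "H")
    if (!length(idx)) idx <- which(system@resid == r & system@role == "CA")
    idx
  }
  ia <- pick(residueA); ib <- pick(residueB)
  if (mode == "centroid") {
    sqrt(sum((colMeans(x[ia, , drop = FALSE]) -
              colMeans(x[ib, , drop = FALSE]))^2))
  } else {
    min(sqrt(outer(rowSums(x[ia, , drop = FALSE]^2),
                   rowSums(x[ib, , drop = FALSE]^2), "+") -
             2 * x[ia, , drop = FALSE] %*% t(x[ib, , drop = FALSE])))
  }
}

#' Pearson product-moment correlation
#'
#' @param seriesA,seriesB numeric vectors of equal length (>= 2) with
#'   nonzero variance.
#' @return correlation in \eqn{[-1, 1]}.
#' @export
pearsonR <- function(seriesA, seriesB) {
  if (length(seriesA) != length(seriesB))
    stop("series lengths differ")
  if (length(seriesA) < 2L) stop("need at least two observations")
  if (stats::sd(seriesA) == 0 || stats::sd(seriesB) == 0)
    stop("correlation undefined: a series has zero variance")
  stats::cor(seriesA, seriesB)
}

#' Per-frame observable table for a pathway
#'
#' Computes, for every frame of a trajectory: radius of gyration, best-fit
#' C-alpha RMSD to the native structure, native-contact count and fraction,
#' backbone hydrogen-bond count and native-H-bond fraction, any requested
#' side-chain group distances, and the potential energy when a surface is
#' supplied; plus the pairwise correlation matrix of all numeric traces.
#'
#' @param trajectory a [Path] whose system slot (or the `system` argument)
#'   describes the atoms.
#' @param native native conformation (atoms x 3).
#' @param system a [MolecularSystem].
#' @param rule a `ContactRule`.
#' @param hrule an `HBondRule`.
#' @param distances optional list of residue index pairs, e.g.
#'   `list(c(3, 6))`, reported as `dist_3_6` columns.
#' @param surface optional [PotentialSurface] for a potential-energy column.
#' @return list with `table` (one row per frame) and `correlations` (the
#'   correlation matrix of the non-constant numeric traces).
#' @export
pathwayReport <- function(trajectory, native, system = trajectory@system,
                          rule = contactRule(), hrule = hbondRule(),
                          distances = list(), surface = NULL) {
  if (is.null(system)) stop("a MolecularSystem is required")
  nFrames <- frameCount(trajectory) + 1L
  rows <- vector("list", nFrames)
  for (f in seq_len(nFrames)) {
    x <- matrix(trajectory@frames[f, ], ncol = 3L, byrow = TRUE)
    nc <- nativeContacts(x, native, system, rule)
    hb <- backboneHBonds(x, system, hrule)
    hf <- hbondFraction(x, native, system, hrule)
    row <- list(frame = f - 1L,
                rg = radiusOfGyration(x, system@masses),
                rmsd = fitRMSD(x, native, system, "calpha"),
                contacts = nc$count, contactFraction = nc$fraction,
                hbonds = hb$count, hbondFraction = hf$fraction)
    for (d in distances)
      row[[sprintf("dist_%d_%d", d[1L], d[2L])]] <-
        groupDistance(x, system, d[1L], d[2L])
    rows[[f]] <- row
  }
  tab <- do.call(rbind.data.frame, rows)
  if (!is.null(surface))
    tab$energy <- surfaceOnFrames(surface, trajectory@frames)$energy
  num <- tab[, setdiff(names(tab), "frame"), drop = FALSE]
  num <- num[, vapply(num, function(v) stats::sd(v) > 0, logical(1)),
             drop = FALSE]
  corr <- if (ncol(num) >= 2L) stats::cor(as.matrix(num)) else NULL
  list(table = tab, correlations = corr)
}
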