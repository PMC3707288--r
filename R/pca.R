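## Principal component analysis of C-alpha fluctuations along a pathway.
## The covariance matrix C_ij = <(x_i - <x_i>)(x_j - <x_j>)> is built over
## all frames of the (optionally superposed) C-alpha coordinates and
## diagonalized; eigenvectors with large eigenvalues are the directions of
## large conformational fluctuation.

#' Principal component analysis of a trajectory
#'
#' Optionally superposes every frame onto a reference (default: the final
#' frame, normally the native structure) by Kabsch least-squares fitting,
#' builds the \eqn{3N_\alpha \times 3N_\alpha} covariance matrix of the
#' C-alpha coordinates over all frames, and diagonalizes it.  Without
#' alignment the covariance mixes rigid-body and internal motion (the
#' literal spatial-fluctuation covariance); with alignment it reflects
#' internal motion only.
#'
#' @param trajectory a [Path] over a molecular system.
#' @param system a [MolecularSystem] (defaults to the path's own).
#' @param alignment `"kabsch"` (superpose onto the reference frame) or
#'   `"none"`.
#' @param reference frame used as superposition target, 0-based index
#'   (default: the final frame).
#' @return a [PCAResult].
#' @export
pcaTrajectory <- function(trajectory, system = trajectory@system,
                          alignment = c("kabsch", "none"),
                          reference = frameCount(trajectory)) {
  alignment <- match.arg(alignment)
  if (is.null(system)) stop("a MolecularSystem is required")
  if (nrow(trajectory@frames) < 2L) stop("need at least two frames")
  ca <- calphaIndices(system)
  if (length(ca) < 1L) stop("no C-alpha atoms in the system")
  caCols <- as.vector(t(outer((ca - 1L) * 3L, 1:3, "+")))
  X <- trajectory@frames[, caCols, drop = FALSE]
  if (alignment == "kabsch") {
    refxyz <- X[reference + 1L, ]
    X <- bio3d::fit.xyz(fixed = refxyz, mobile = X,
                        fixed.inds = seq_along(refxyz),
                        mobile.inds = seq_along(refxyz))
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  C <- crossprod(Xc) / nrow(Xc)
  eig <- eigen(C, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  new("PCAResult", values = vals, vectors = eig$vectors,
      varianceFractions = vals / sum(vals),
      projections = Xc %*% eig$vectors,
      center = matrix(mu, ncol = 3L, byrow = TRUE),
      resid = sort(unique(system@resid)))
}

#' @rdname pcaTrajectory
#' @param pca a [PCAResult].
#' @param n number of leading components.
#' @return `varianceExplained()`: cumulative variance fraction of the first
#'   `n` components (the share of total fluctuation they describe).
#' @export
varianceExplained <- function(pca, n = 3L) sum(pca@varianceFractions[1:n])

#' Per-residue contribution to a principal component
#'
#' Euclidean norm of each residue's three eigenvector entries; by
#' eigenvector normalization the squared contributions sum to one per
#' component.
#'
#' @param pca a [PCAResult].
#' @param component component index (1 = largest eigenvalue).
#' @return numeric vector, one magnitude per residue.
#' @export
residueContribution <- function(pca, component) {
  if (component < 1L || component > ncol(pca@vectors))
    stop("component out of range 1..", ncol(pca@vectors))
  v <- pca@vectors[, component]
  sqrt(rowSums(matrix(v, ncol = 3L, byrow = TRUE)^2))
}
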