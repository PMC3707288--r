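# Shared fixtures and independent oracles used across the suite.

# central finite differences of a surface's energy: the gradient oracle
fdGradient <- function(surface, q, h = 1e-5) {
  vapply(seq_along(q), function(i) {
    qp <- q; qp[i] <- qp[i] + h
    qm <- q; qm[i] <- qm[i] - h
    (evaluateSurface(surface, qp)$energy -
     evaluateSurface(surface, qm)$energy) / (2 * h)
  }, numeric(1))
}

# analytic 1-D harmonic orbit q(t) = cos(t) sampled on the uniform grid
harmonicOrbitPath <- function(P, tau = pi / 2) {
  tj <- seq(0, tau, length.out = P + 1)
  newPath(cbind(cos(tj)), delta = tau / P)
}

# brute-force recomputation of the action from scalar loops (no matrix code
# shared with the implementation)
bruteForceAction <- function(path, surface) {
  Q <- pathFrames(path)
  P <- nrow(Q) - 1L
  m <- rep(path@masses, each = path@adim)
  S <- 0
  for (j in 0:(P - 1)) {
    kin <- 0
    for (c in seq_len(ncol(Q)))
      kin <- kin + m[c] / (2 * path@delta^2) * (Q[j + 1, c] - Q[j + 2, c])^2
    S <- S + (kin - evaluateSurface(surface, Q[j + 1, ])$energy) * path@delta
  }
  S
}

bruteForceFrameEnergy <- function(path, surface, j) {
  Q <- pathFrames(path)
  m <- rep(path@masses, each = path@adim)
  kin <- sum(m / (2 * path@delta^2) * (Q[j + 1, ] - Q[j + 2, ])^2)
  kin + evaluateSurface(surface, Q[j + 1, ])$energy
}

# quaternion-grid + polish RMSD oracle, independent of the Kabsch route
bruteForceRMSD <- function(a, b, nGrid = 14L) {
  ac <- sweep(a, 2L, colMeans(a)); bc <- sweep(b, 2L, colMeans(b))
  rotOf <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3L, 3L, byrow = TRUE)
  }
  obj <- function(q) {
    R <- rotOf(q)
    sqrt(mean(rowSums((ac %*% t(R) - bc)^2)))
  }
  rodrigues <- function(w) {
    th <- sqrt(sum(w^2))
    if (th < 1e-12) return(diag(3))
    u <- w / th
    K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
                3, 3, byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  obj3 <- function(w) {
    R <- rodrigues(w)
    sqrt(mean(rowSums((ac %*% t(R) - bc)^2)))
  }
  grid <- as.matrix(expand.grid(rep(list(seq(-1, 1, length.out = nGrid)), 4)))
  grid <- grid[rowSums(grid^2) > 1e-6, ]
  vals <- apply(grid, 1L, obj)
  best <- Inf
  for (i in order(vals)[1:5]) {  # polish leading candidates in axis-angle space
    q <- grid[i, ] / sqrt(sum(grid[i, ]^2))
    th <- 2 * atan2(sqrt(sum(q[2:4]^2)), q[1])
    w0 <- if (sqrt(sum(q[2:4]^2)) < 1e-12) c(0, 0, 0)
          else th * q[2:4] / sqrt(sum(q[2:4]^2))
    fit <- optim(w0, obj3, method = "Nelder-Mead",
                 control = list(reltol = 1e-15, maxit = 10000))
    fit <- optim(fit$par, obj3, method = "Nelder-Mead",
                 control = list(reltol = 1e-15, maxit = 10000))
    best <- min(best, fit$value)
  }
  best
}

randomRotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3L, 3L, byrow = TRUE)
}

# one cached toy-protein fixture shared by analysis and campaign tests
toyFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- makeToyProtein(nres = 12L, seed = 1L)
    cache
  }
})
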