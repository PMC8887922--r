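# Independent oracles and small generators shared across tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rotation matrix from z-y-z Euler angles.
eulerRotation <- function(a, b, g) {
  Rz <- function(t) rbind(c(cos(t), -sin(t), 0), c(sin(t), cos(t), 0),
                          c(0, 0, 1))
  Ry <- function(t) rbind(c(cos(t), 0, sin(t)), c(0, 1, 0),
                          c(-sin(t), 0, cos(t)))
  Rz(a) %*% Ry(b) %*% Rz(g)
}

# All rotations on a 10-degree Euler grid, as an m x 9 matrix of
# column-major vec(R). Built once per test run.
rotationGrid10 <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    step <- 10 * pi / 180
    a <- seq(0, 2 * pi - step, by = step)
    b <- seq(0, pi, by = step)
    g <- seq(0, 2 * pi - step, by = step)
    grid <- expand.grid(a = a, b = b, g = g)
    m <- nrow(grid)
    out <- matrix(NA_real_, m, 9)
    for (k in seq_len(m))
      out[k, ] <- as.vector(eulerRotation(grid$a[k], grid$b[k], grid$g[k]))
    cache <<- out
    out
  }
})

# Brute-force minimum RMSD over the 10-degree rotation grid after
# centering: rmsd^2 = (|P0|^2 + |Q0|^2 - 2 max_R tr(R H)) / n with
# H = t(Q0) P0, and tr(R H) = vec(R) . vec(t(H)).
gridMinRmsd <- function(P, Q) {
  n <- nrow(P)
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  H <- crossprod(Q0, P0)
  tr <- rotationGrid10() %*% as.vector(t(H))
  sqrt(max(0, sum(P0^2) + sum(Q0^2) - 2 * max(tr)) / n)
}

# Brute-force minimum RMSD refined by nested Euler-grid zoom around the
# coarse optimum; independent of the closed-form solvers.
refinedMinRmsd <- function(P, Q) {
  n <- nrow(P)
  P0 <- sweep(P, 2, colMeans(P))
  Q0 <- sweep(Q, 2, colMeans(Q))
  H <- crossprod(Q0, P0)
  vecH <- as.vector(t(H))
  gp <- sum(P0^2); gq <- sum(Q0^2)
  step <- 10 * pi / 180
  grid <- expand.grid(a = seq(0, 2 * pi - step, by = step),
                      b = seq(0, pi, by = step),
                      g = seq(0, 2 * pi - step, by = step))
  evalTr <- function(a, b, g) sum(as.vector(eulerRotation(a, b, g)) * vecH)
  tr <- mapply(evalTr, grid$a, grid$b, grid$g)
  best <- grid[which.max(tr), ]
  bestTr <- max(tr)
  for (lvl in 1:5) {
    local <- expand.grid(a = best$a + seq(-step, step, length.out = 9),
                         b = best$b + seq(-step, step, length.out = 9),
                         g = best$g + seq(-step, step, length.out = 9))
    trL <- mapply(evalTr, local$a, local$b, local$g)
    if (max(trL) > bestTr) {
      bestTr <- max(trL)
      best <- local[which.max(trL), ]
    }
    step <- step / 4
  }
  sqrt(max(0, gp + gq - 2 * bestTr) / n)
}

# Random proper rotation from a seeded quaternion.
randomRotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(
    c(w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2))
}

# Brute-force assignment oracle: minimum-cost permutation by enumeration.
bruteForceAssignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (k in seq_along(v))
      for (p in perms(v[-k])) out[[length(out) + 1]] <- c(v[k], p)
    out
  }
  best <- NULL; bestCost <- Inf
  for (p in perms(seq_len(n))) {
    cc <- sum(cost[cbind(seq_len(n), p)])
    if (cc < bestCost) { bestCost <- cc; best <- p }
  }
  list(assignment = best, cost = bestCost)
}

# Per-step frozen-skeleton assertion for a serial run: every surviving
# atom of step k's input must be bit-identical in step k's output.
expectFrozenAcrossRun <- function(skeleton, run, spec) {
  current <- skeleton
  for (k in seq_along(run$structures)) {
    b <- spec$pairs[k, 1]
    out <- run$structures[[k]]
    survivors <- which(skeletonMask(out))
    expect_identical(coords(out)[survivors, , drop = FALSE],
                     coords(current)[-b, , drop = FALSE])
    current <- out
  }
}

# Ideal methane for I/O and placement tests.
methaneMolecule <- function() {
  d <- 1.09 / sqrt(3)
  Molecule(
    elements = c("C", "H", "H", "H", "H"),
    coords = rbind(c(0, 0, 0), c(d, d, d), c(d, -d, -d),
                   c(-d, d, -d), c(-d, -d, d)),
    bonds = data.frame(i = 1L, j = 2:5, order = 1L),
    name = "methane")
}
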