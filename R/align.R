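## Rigid superposition (Kabsch SVD and Horn quaternion routes) and the
## heavy-atom RMSD used to compare structures from different optimization
## methods. Both routes minimize the same least-squares objective; keeping
## them independent gives a built-in cross-check.

.asPointMatrix <- function(x) {
  if (is(x, "Molecule")) x <- coords(x)
  x <- as.matrix(x)
  if (ncol(x) != 3) stop("point sets must be n x 3 matrices")
  storage.mode(x) <- "double"
  x
}

#' Kabsch superposition
#'
#' Optimal least-squares rigid superposition of two point sets with
#' correspondence given by row index: both sets are centered, the optimal
#' proper rotation is obtained from the SVD of the covariance matrix with
#' the determinant correction that excludes reflections, and the RMSD is
#' evaluated after the transform `q = R p + t`.
#'
#' @param P,Q n x 3 coordinate matrices (or [Molecule-class] objects), same
#'   n; `P` is rotated onto `Q`.
#' @return An [AlignmentResult-class].
#' @seealso [quaternionAlign()], [hrmsd()]
#' @export
kabschAlign <- function(P, Q) {
  P <- .asPointMatrix(P); Q <- .asPointMatrix(Q)
  if (nrow(P) != nrow(Q)) stop("point sets differ in size (",
                               nrow(P), " vs ", nrow(Q), ")")
  if (nrow(P) < 1) stop("need at least one point")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- crossprod(P0, Q0)                    # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  diff <- P0 %*% t(R) - Q0
  rmsd <- sqrt(sum(diff^2) / nrow(P))
  new("AlignmentResult", rotation = R,
      translation = as.numeric(cq - R %*% cp), rmsd = rmsd,
      mapping = integer(0))
}

#' Quaternion superposition
#'
#' Horn's closed-form quaternion solution of the same superposition
#' problem solved by [kabschAlign()]: the optimal rotation is the unit
#' quaternion given by the dominant eigenvector of the 4 x 4 key matrix,
#' which is always a proper rotation. The two routes agree to numerical
#' precision and serve as mutual cross-checks.
#'
#' @inheritParams kabschAlign
#' @return An [AlignmentResult-class].
#' @export
quaternionAlign <- function(P, Q) {
  P <- .asPointMatrix(P); Q <- .asPointMatrix(Q)
  if (nrow(P) != nrow(Q)) stop("point sets differ in size (",
                               nrow(P), " vs ", nrow(Q), ")")
  if (nrow(P) < 1) stop("need at least one point")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  S <- crossprod(P0, Q0)
  key <- rbind(
    c(S[1, 1] + S[2, 2] + S[3, 3],
      S[2, 3] - S[3, 2], S[3, 1] - S[1, 3], S[1, 2] - S[2, 1]),
    c(S[2, 3] - S[3, 2],
      S[1, 1] - S[2, 2] - S[3, 3], S[1, 2] + S[2, 1], S[3, 1] + S[1, 3]),
    c(S[3, 1] - S[1, 3],
      S[1, 2] + S[2, 1], -S[1, 1] + S[2, 2] - S[3, 3], S[2, 3] + S[3, 2]),
    c(S[1, 2] - S[2, 1],
      S[3, 1] + S[1, 3], S[2, 3] + S[3, 2], -S[1, 1] - S[2, 2] + S[3, 3]))
  eg <- eigen(key, symmetric = TRUE)
  q <- eg$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- rbind(
    c(w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y)),
    c(2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x)),
    c(2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2))
  gp <- sum(P0^2); gq <- sum(Q0^2)
  rmsd <- sqrt(max(0, gp + gq - 2 * eg$values[1]) / nrow(P))
  new("AlignmentResult", rotation = R,
      translation = as.numeric(cq - R %*% cp), rmsd = rmsd,
      mapping = integer(0))
}

## Hungarian (shortest augmenting path) solver for the rectangular-free
## square assignment problem; O(n^3). No installed package provides this,
## so it is implemented here and oracle-tested against brute-force
## permutation search in the test suite.
.solveAssignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  if (n == 0) return(integer(0))
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)                       # p[j]: row assigned to column j
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assignment <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0L) assignment[p[j]] <- j - 1L
  assignment                                # assignment[row] = column
}

.heavySubset <- function(mol) {
  keep <- elements(mol) != "H"
  list(elements = elements(mol)[keep],
       coords = coords(mol)[keep, , drop = FALSE])
}

#' Heavy-atom RMSD between two structures
#'
#' Removes hydrogens, optionally re-derives the atom correspondence, and
#' reports the root-mean-square deviation after optimal rigid
#' superposition ([kabschAlign()]). With `reorder = TRUE` the
#' correspondence is chosen per element by minimum-cost assignment
#' (Hungarian) on the inter-structure distance matrix after a provisional
#' centroid alignment — useful when the two files list atoms in different
#' orders. Default is index-matched correspondence, the convention for
#' comparing the same structure optimized by different methods.
#'
#' @param molA,molB [Molecule-class] objects with equal heavy-atom counts
#'   (and equal element multisets when `reorder = TRUE`).
#' @param reorder re-derive atom correspondence per element.
#' @param align superpose before measuring (default `TRUE`); `FALSE` gives
#'   the raw index-matched deviation in the input frames.
#' @return RMSD in Angstrom (a single number).
#' @export
hrmsd <- function(molA, molB, reorder = FALSE, align = TRUE) {
  A <- .heavySubset(molA); B <- .heavySubset(molB)
  if (length(A$elements) != length(B$elements))
    stop("heavy-atom counts differ (", length(A$elements), " vs ",
         length(B$elements), ")")
  if (length(A$elements) == 0) stop("no heavy atoms to compare")
  if (reorder) {
    if (!identical(sort(A$elements), sort(B$elements)))
      stop("element multisets differ; cannot reorder")
    P0 <- sweep(A$coords, 2, colMeans(A$coords))
    Q0 <- sweep(B$coords, 2, colMeans(B$coords))
    perm <- integer(length(A$elements))
    for (el in unique(A$elements)) {
      ia <- which(A$elements == el); ib <- which(B$elements == el)
      if (length(ia) == 1L) {
        perm[ia] <- ib
      } else {
        cost <- .crossDistances(P0[ia, , drop = FALSE],
                                Q0[ib, , drop = FALSE])
        perm[ia] <- ib[.solveAssignment(cost)]
      }
    }
    B <- list(elements = A$elements,
              coords = B$coords[perm, , drop = FALSE])
  }
  if (!align) {
    return(sqrt(sum((A$coords - B$coords)^2) / nrow(A$coords)))
  }
  alignRmsd(kabschAlign(A$coords, B$coords))
}
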