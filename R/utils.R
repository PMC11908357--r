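# Shared numerical helpers.

# All-pairs minimum distance between two coordinate matrices (n x 3, m x 3).
# Returns list(min, i, j). Blocked evaluation keeps memory bounded for large
# chains without changing the result.
min_pair_distance <- function(a, b, block = 2000L) {
  stopifnot(ncol(a) == 3L, ncol(b) == 3L)
  best <- list(min = Inf, i = NA_integer_, j = NA_integer_)
  nb <- nrow(b)
  for (start in seq(1L, nb, by = block)) {
    idx <- start:min(start + block - 1L, nb)
    d2 <- outer(rowSums(a^2), rowSums(b[idx, , drop = FALSE]^2), "+") -
      2 * tcrossprod(a, b[idx, , drop = FALSE])
    d2[d2 < 0] <- 0
    k <- arrayInd(which.min(d2), dim(d2))
    if (d2[k] < best$min^2) {
      best <- list(min = sqrt(d2[k]), i = k[1L], j = idx[k[2L]])
    }
  }
  best
}

# Kabsch superposition: returns rotation R and translation so that
# moving %*% R + t best fits fixed (both n x 3, row-matched).
kabsch <- function(moving, fixed) {
  cm <- colMeans(moving)
  cf <- colMeans(fixed)
  a <- sweep(moving, 2, cm)
  b <- sweep(fixed, 2, cf)
  s <- svd(crossprod(a, b))
  d <- sign(det(tcrossprod(s$v, s$u)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(rotation = rot, translation = cf - as.vector(cm %*% rot))
}

apply_kabsch <- function(xyz, fit) {
  sweep(xyz %*% fit$rotation, 2, fit$translation, "+")
}

# Smallest absolute difference between two angles in degrees, on (-180, 180].
angle_diff_periodic <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

# Dihedral angle (degrees) for points p1..p4, each a length-3 vector.
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) v / vnorm(v)

`%||%` <- function(a, b) if (is.null(a)) b else a
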