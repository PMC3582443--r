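#' Rotation matrix from a rotation vector (Rodrigues formula)
#'
#' @param w numeric length-3 rotation vector; its direction is the rotation
#'   axis and its norm the rotation angle in radians.
#' @return 3x3 proper rotation matrix.
#' @keywords internal
rotvec_to_matrix <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-300) return(diag(3))
  k <- w / th
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Check that a matrix is a proper rotation
#'
#' @param R 3x3 matrix.
#' @param tol maximum absolute elementwise deviation of \code{t(R) \%*\% R}
#'   from the identity.
#' @return logical.
#' @keywords internal
is_rotation_matrix <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || any(dim(R) != c(3L, 3L)) || !all(is.finite(R))) {
    return(FALSE)
  }
  max(abs(crossprod(R) - diag(3))) < tol && det(R) > 0
}

#' Uniformly distributed random rotation matrices
#'
#' Draws rotations from the Haar measure on SO(3) via unit quaternions.
#' Uses R's RNG stream, so results are reproducible under [set.seed()].
#'
#' @param n number of rotations.
#' @return 3x3xn array of rotation matrices.
#' @export
random_rotations <- function(n) {
  q <- matrix(stats::rnorm(4 * n), ncol = 4)
  q <- q / sqrt(rowSums(q^2))
  out <- array(NA_real_, c(3, 3, n))
  for (i in seq_len(n)) {
    a <- q[i, 1]; b <- q[i, 2]; c <- q[i, 3]; d <- q[i, 4]
    out[, , i] <- matrix(c(
      a^2 + b^2 - c^2 - d^2, 2 * (b * c + a * d),   2 * (b * d - a * c),
      2 * (b * c - a * d),   a^2 - b^2 + c^2 - d^2, 2 * (c * d + a * b),
      2 * (b * d + a * c),   2 * (c * d - a * b),   a^2 - b^2 - c^2 + d^2
    ), 3, 3)
  }
  out
}

#' Deterministic near-uniform directions on the unit sphere
#'
#' Fibonacci-spiral point set; deterministic for a given \code{n}, used for
#' orientation-grid (powder) averaging.
#'
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

unit <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("cannot normalize a (near-)zero vector")
  v / nv
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
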