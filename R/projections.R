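#' Squared operator norm of a matrix
#'
#' Largest eigenvalue of \eqn{A^T A}, i.e. \eqn{\|A\|^2}, the quantity
#' entering the step-size bound \eqn{\lambda < 2/\|A\|^2} of the CQ
#' family.  Computed with an exact symmetric eigensolver on the smaller
#' of \eqn{A^T A} and \eqn{A A^T}.
#'
#' @param A numeric matrix with finite entries.
#' @return nonnegative scalar \eqn{\|A\|^2}.
#' @export
operator_norm_sq <- function(A) {
  A <- as.matrix(A)
  if (length(A) == 0L) stop("A must be nonempty")
  if (!all(is.finite(A))) stop("A must have finite entries")
  G <- if (ncol(A) <= nrow(A)) crossprod(A) else tcrossprod(A)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  max(max(ev), 0)
}

#' Projection onto a half-space
#'
#' Euclidean projection of `x` onto \eqn{\{\omega : \langle a, \omega\rangle
#' \le b\}}: the identity on feasible points, otherwise
#' \eqn{x - (\langle a, x\rangle - b)\,a/\|a\|^2}.
#'
#' A zero normal with \eqn{b \ge 0} describes the whole space (returns
#' `x`); a zero normal with \eqn{b < 0} is the empty set and errors.
#'
#' @param x point to project.
#' @param a normal vector.
#' @param b offset scalar.
#' @return the projected vector.
#' @export
project_halfspace <- function(x, a, b) {
  stopifnot(length(a) == length(x), all(is.finite(a)), is.finite(b))
  na2 <- sum(a * a)
  if (na2 == 0) {
    if (b >= 0) return(x)
    stop("empty half-space: zero normal with negative offset")
  }
  viol <- sum(a * x) - b
  if (viol <= 0) x else x - (viol / na2) * a
}

#' Projection onto a Euclidean ball
#'
#' Identity inside the ball, radial scaling outside:
#' \eqn{center + radius\,(x - center)/\|x - center\|}.
#'
#' @param x point to project.
#' @param center ball center.
#' @param radius nonnegative radius.
#' @return the projected vector.
#' @export
project_ball <- function(x, center, radius) {
  if (radius < 0) stop("radius must be nonnegative")
  d <- x - center
  nd <- sqrt(sum(d * d))
  if (nd <= radius) x else center + (radius / nd) * d
}

#' Projection onto an L1 ball
#'
#' Euclidean projection onto \eqn{\{\omega : \|\omega\|_1 \le \gamma\}}
#' by the sort-and-threshold algorithm: soft-threshold the magnitudes by
#' the level \eqn{\theta} at which the shrunk absolute values sum to
#' \eqn{\gamma}.
#'
#' @param x point to project.
#' @param gamma positive L1 radius.
#' @return the projected vector, with \eqn{\|\cdot\|_1 \le \gamma + 10^{-10}}.
#' @export
project_l1_ball <- function(x, gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("gamma must be a positive scalar")
  ax <- abs(x)
  if (sum(ax) <= gamma) return(x)
  u <- sort(ax, decreasing = TRUE)
  cs <- cumsum(u)
  k <- max(which(u - (cs - gamma) / seq_along(u) > 0))
  theta <- (cs[k] - gamma) / k
  sign(x) * pmax(ax - theta, 0)
}
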