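#' Per-iteration relaxation of a constraint set
#'
#' The relaxed CQ family replaces the exact set \eqn{C = \{c \le 0\}} at
#' iteration n by the superset
#' \deqn{C_n = \{\omega : c(y_n) \le \langle \varrho_n, y_n - \omega\rangle
#'   - \tfrac{\alpha}{2}\|y_n - \omega\|^2\},}
#' where \eqn{\varrho_n \in \partial c(y_n)} and \eqn{\alpha \ge 0}.  With
#' \eqn{\alpha = 0} this is the classical subgradient half-space; with
#' \eqn{\alpha > 0} it is a ball (complete the square).  Convexity of `c`
#' guarantees \eqn{C \subseteq C_n}, so projecting onto \eqn{C_n} is a
#' valid surrogate with a closed form.
#'
#' `build_relaxed_set` evaluates the constraint's value and subgradient
#' oracles at the anchor and freezes them into a `relaxed_set` object.
#'
#' @param constraint a [convex_constraint].
#' @param anchor numeric vector, the point \eqn{y_n} (or \eqn{A y_n})
#'   where the oracles are evaluated.
#' @param curvature nonnegative scalar \eqn{\alpha} (or \eqn{\beta});
#'   0 gives the half-space relaxation.
#' @return an object of class `relaxed_set` with fields `anchor`, `fval`,
#'   `subgrad`, `curvature`.
#' @seealso [project_relaxed()], [relaxed_membership()]
#' @export
build_relaxed_set <- function(constraint, anchor, curvature = 0) {
  stopifnot(inherits(constraint, "convex_constraint"),
            is.numeric(anchor), all(is.finite(anchor)),
            is.numeric(curvature), length(curvature) == 1L, curvature >= 0)
  fval <- constraint$value(anchor)
  g <- constraint$subgrad(anchor)
  if (!is.finite(fval) || !all(is.finite(g)))
    stop("constraint oracle returned non-finite values at the anchor")
  structure(list(anchor = anchor, fval = fval, subgrad = g,
                 curvature = curvature),
            class = "relaxed_set")
}

#' Membership value of a point in a relaxed set
#'
#' Returns \eqn{m(\omega) = c(y_n) - \langle \varrho_n, y_n - \omega\rangle
#' + \tfrac{\alpha}{2}\|y_n - \omega\|^2}; the point belongs to the set
#' iff \eqn{m(\omega) \le 0}.
#'
#' @param S a `relaxed_set`.
#' @param w numeric vector.
#' @return scalar membership value.
#' @export
relaxed_membership <- function(S, w) {
  d <- S$anchor - w
  S$fval - sum(S$subgrad * d) + (S$curvature / 2) * sum(d * d)
}

#' Projection onto a relaxed set
#'
#' Closed-form Euclidean projection onto the half-space
#' (`curvature == 0`) or ball (`curvature > 0`) form of the relaxation.
#'
#' For `curvature == 0` the membership inequality rewrites to
#' \eqn{\langle \varrho_n, \omega\rangle \le \langle \varrho_n, y_n\rangle
#' - c(y_n)}, a half-space with normal \eqn{\varrho_n}.  For
#' `curvature > 0`, completing the square gives the ball with center
#' \eqn{y_n - \varrho_n/\alpha} and squared radius
#' \eqn{\|\varrho_n\|^2/\alpha^2 - 2 c(y_n)/\alpha}; a negative squared
#' radius means the relaxation is empty, which signals an invalid
#' curvature choice and is a hard error.
#'
#' @param x point to project.
#' @param S a `relaxed_set` built by [build_relaxed_set()].
#' @return the projected vector.
#' @export
project_relaxed <- function(x, S) {
  stopifnot(inherits(S, "relaxed_set"))
  if (S$curvature == 0) {
    if (all(S$subgrad == 0)) {
      if (S$fval <= 0) return(x)
      stop("empty relaxed set: zero subgradient with positive value")
    }
    return(project_halfspace(x, S$subgrad,
                             sum(S$subgrad * S$anchor) - S$fval))
  }
  r2 <- sum(S$subgrad^2) / S$curvature^2 - 2 * S$fval / S$curvature
  if (r2 < 0)
    stop("empty relaxed set: negative squared radius (curvature too large)")
  project_ball(x, S$anchor - S$subgrad / S$curvature, sqrt(r2))
}

#' @export
print.relaxed_set <- function(x, ...) {
  cat(sprintf("<relaxed_set> dim %d, fval %.4g, curvature %g (%s)\n",
              length(x$anchor), x$fval, x$curvature,
              if (x$curvature == 0) "half-space" else "ball"))
  invisible(x)
}
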