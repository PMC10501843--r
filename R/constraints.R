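#' Convex constraint described by a level-set function
#'
#' A closed convex set is represented as the zero sublevel set
#' \eqn{\{\omega : c(\omega) \le 0\}} of a convex function `c`, together
#' with a subgradient oracle returning one element of the subdifferential
#' \eqn{\partial c(\omega)}.  This is the representation the relaxed CQ
#' family of solvers consumes: at each iteration the set is replaced by a
#' half-space (or ball) superset built from `value` and `subgrad` at an
#' anchor point, so only those two oracles are ever needed.  When a
#' closed-form Euclidean projection onto the exact set is known it can be
#' supplied as `project`; the Byrne CQ baseline requires it.
#'
#' @param value function of a numeric vector returning the scalar
#'   \eqn{c(\omega)}.
#' @param subgrad function of a numeric vector returning one subgradient
#'   of `c` at that point (the gradient where `c` is differentiable).
#' @param label short human-readable description.
#' @param project optional function giving the exact Euclidean projection
#'   onto \eqn{\{c \le 0\}}.
#' @param params named list of the parameters that define the set (kept
#'   for serialization and printing).
#' @return an object of class `convex_constraint`.
#' @seealso [cc_l1_ball()], [cc_l2_ball()], [cc_ball()], [cc_halfspace()],
#'   [cc_singleton()], [cc_box()] for the stock constructors, and
#'   [build_relaxed_set()] for the per-iteration relaxation.
#' @export
convex_constraint <- function(value, subgrad, label = "constraint",
                              project = NULL, params = list()) {
  stopifnot(is.function(value), is.function(subgrad))
  structure(
    list(value = value, subgrad = subgrad, label = label,
         project = project, params = params),
    class = "convex_constraint"
  )
}

#' @export
print.convex_constraint <- function(x, ...) {
  cat("<convex_constraint> ", x$label, "\n", sep = "")
  if (length(x$params))
    cat("  params:", paste(names(x$params), unlist(lapply(x$params, function(p)
      paste(signif(p, 4), collapse = ","))), sep = "=", collapse = "; "), "\n")
  cat("  exact projection:", if (is.null(x$project)) "none" else "closed form", "\n")
  invisible(x)
}

#' L1-ball constraint
#'
#' The set \eqn{\{\omega : \|\omega\|_1 \le \gamma\}} encoded by
#' \eqn{c(\omega) = \|\omega\|_1 - \gamma}.  The subgradient is the sign
#' vector, with 0 at zero coordinates (a valid subdifferential element
#' that keeps the relaxed half-space as large as possible and makes the
#' oracle deterministic).
#'
#' @param gamma positive radius of the ball in the L1 norm.
#' @return a [convex_constraint].
#' @export
cc_l1_ball <- function(gamma) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma > 0)
  convex_constraint(
    value   = function(w) sum(abs(w)) - gamma,
    subgrad = function(w) sign(w),
    label   = sprintf("l1_ball(gamma=%g)", gamma),
    project = function(x) project_l1_ball(x, gamma),
    params  = list(kind = "l1_ball", gamma = gamma)
  )
}

#' L2-ball constraint (squared-norm form)
#'
#' The set \eqn{\{\omega : \|\omega\|_2^2 \le \gamma\}} encoded by
#' \eqn{c(\omega) = \|\omega\|^2 - \gamma}, i.e. the Euclidean ball of
#' radius \eqn{\sqrt{\gamma}}.  `c` is differentiable with gradient
#' \eqn{2\omega}.
#'
#' @inheritParams cc_l1_ball
#' @return a [convex_constraint].
#' @export
cc_l2_ball <- function(gamma) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma > 0)
  convex_constraint(
    value   = function(w) sum(w * w) - gamma,
    subgrad = function(w) 2 * w,
    label   = sprintf("l2_ball(gamma=%g)", gamma),
    project = function(x) project_ball(x, numeric(length(x)), sqrt(gamma)),
    params  = list(kind = "l2_ball", gamma = gamma)
  )
}

#' Euclidean ball constraint with arbitrary center
#'
#' \eqn{c(\omega) = \|\omega - center\|^2 - radius^2}; gradient
#' \eqn{2(\omega - center)}.
#'
#' @param center numeric vector.
#' @param radius nonnegative scalar.
#' @return a [convex_constraint].
#' @export
cc_ball <- function(center, radius) {
  stopifnot(is.numeric(center), is.numeric(radius), length(radius) == 1L,
            radius >= 0)
  force(center); force(radius)
  convex_constraint(
    value   = function(w) sum((w - center)^2) - radius^2,
    subgrad = function(w) 2 * (w - center),
    label   = sprintf("ball(radius=%g)", radius),
    project = function(x) project_ball(x, center, radius),
    params  = list(kind = "ball", center = center, radius = radius)
  )
}

#' Half-space constraint
#'
#' \eqn{\{\omega : \langle a, \omega\rangle \le b\}} encoded by the affine
#' function \eqn{c(\omega) = \langle a, \omega\rangle - b}.
#'
#' @param a normal vector.
#' @param b offset scalar.
#' @return a [convex_constraint].
#' @export
cc_halfspace <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b), length(b) == 1L, all(is.finite(a)))
  force(a); force(b)
  convex_constraint(
    value   = function(w) sum(a * w) - b,
    subgrad = function(w) a,
    label   = "halfspace",
    project = function(x) project_halfspace(x, a, b),
    params  = list(kind = "halfspace", a = a, b = b)
  )
}

#' Singleton constraint
#'
#' The one-point set \eqn{\{v\}} encoded by the smooth function
#' \eqn{q(\omega) = \tfrac12\|\omega - v\|^2}, whose zero sublevel set is
#' exactly \eqn{\{v\}} and whose gradient is \eqn{\omega - v}.  This is
#' the target-side set of the constrained least-squares training problem,
#' where Q collapses to the target vector.
#'
#' @param v the point.
#' @return a [convex_constraint].
#' @export
cc_singleton <- function(v) {
  stopifnot(is.numeric(v))
  force(v)
  convex_constraint(
    value   = function(w) 0.5 * sum((w - v)^2),
    subgrad = function(w) w - v,
    label   = "singleton",
    project = function(x) v,
    params  = list(kind = "singleton", v = v)
  )
}

#' Box constraint
#'
#' \eqn{\{\omega : lower \le \omega \le upper\}} coordinatewise, encoded
#' by \eqn{c(\omega) = \max_j \max(lower_j - \omega_j, \omega_j - upper_j)}.
#' The subgradient is the signed unit vector of the (first) most violated
#' coordinate, or zero in the interior.
#'
#' @param lower,upper numeric vectors (recycled scalars allowed).
#' @return a [convex_constraint].
#' @export
cc_box <- function(lower, upper) {
  stopifnot(all(lower <= upper))
  force(lower); force(upper)
  convex_constraint(
    value = function(w) max(pmax(lower - w, w - upper)),
    subgrad = function(w) {
      lo <- lower - w
      hi <- w - upper
      g <- numeric(length(w))
      m <- max(pmax(lo, hi))
      if (m >= 0) {            # on or outside the boundary
        j <- which.max(pmax(lo, hi))
        g[j] <- if (lo[j] >= hi[j]) -1 else 1
      }
      g
    },
    label   = "box",
    project = function(x) pmin(pmax(x, lower), upper),
    params  = list(kind = "box", lower = lower, upper = upper)
  )
}

#' Build a constraint from a configuration list
#'
#' Maps the keyword representation used in config files (`kind` plus
#' parameters) onto the stock constructors.
#'
#' @param cfg named list with element `kind` in
#'   `c("l1_ball", "l2_ball", "ball", "halfspace", "singleton", "box")`
#'   and that kind's parameters.
#' @return a [convex_constraint].
#' @export
constraint_from_config <- function(cfg) {
  stopifnot(is.list(cfg), !is.null(cfg$kind))
  switch(as.character(cfg$kind),
    l1_ball   = cc_l1_ball(cfg$gamma),
    l2_ball   = cc_l2_ball(cfg$gamma),
    ball      = cc_ball(unlist(cfg$center), cfg$radius),
    halfspace = cc_halfspace(unlist(cfg$a), cfg$b),
    singleton = cc_singleton(unlist(cfg$v)),
    box       = cc_box(unlist(cfg$lower), unlist(cfg$upper)),
    stop("unknown constraint kind: ", cfg$kind)
  )
}

#' Split feasibility problem instance
#'
#' Bundles the linear operator `A` with level-set descriptions of the two
#' constraint sets: find \eqn{\omega \in C} with \eqn{A\omega \in Q}.
#' When a known solution is supplied (synthetic instances) it is checked
#' for feasibility: \eqn{c(\omega^*) \le 10^{-10}} and
#' \eqn{q(A\omega^*) \le 10^{-10}}.
#'
#' @param A numeric matrix (m x n), finite entries.
#' @param Cset,Qset [convex_constraint] descriptions of C and Q.
#' @param known_solution optional numeric vector, a point of the solution
#'   set (used by tests and residual reporting).
#' @return an object of class `sfp_instance`.
#' @export
sfp_instance <- function(A, Cset, Qset, known_solution = NULL) {
  A <- as.matrix(A)
  if (!all(is.finite(A))) stop("A must have finite entries")
  stopifnot(inherits(Cset, "convex_constraint"),
            inherits(Qset, "convex_constraint"))
  if (!is.null(known_solution)) {
    stopifnot(length(known_solution) == ncol(A))
    cv <- Cset$value(known_solution)
    qv <- Qset$value(drop(A %*% known_solution))
    if (cv > 1e-10 || qv > 1e-10)
      stop(sprintf(
        "known_solution is not feasible: c = %.3g, q = %.3g", cv, qv))
  }
  structure(list(A = A, Cset = Cset, Qset = Qset,
                 known_solution = known_solution),
            class = "sfp_instance")
}

#' @export
print.sfp_instance <- function(x, ...) {
  cat(sprintf("<sfp_instance> A: %d x %d\n", nrow(x$A), ncol(x$A)))
  cat("  C:", x$Cset$label, "\n  Q:", x$Qset$label, "\n")
  cat("  known solution:", if (is.null(x$known_solution)) "no" else "yes", "\n")
  invisible(x)
}
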