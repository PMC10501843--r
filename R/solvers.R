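#' Solver configuration
#'
#' Parameters shared by the four SFP iteration schemes.  The defaults are
#' the experimental settings of the classification study: extrapolation
#' bound `sigma = 0.9999`, relative step `lambda_rel = 0.9999` (so that
#' \eqn{\lambda_n = 0.9999/\|A\|^2} satisfies the step-size condition
#' \eqn{\limsup \lambda_n < 2/\|A\|^2}), Mann averaging weight
#' `alpha_mann = 1/1.2`, and Wang--Yu step factor `epsilon_n = 0.1`.
#'
#' `alpha_mann = 0` is accepted even though the convergence theory needs
#' a strictly positive weight: it degenerates the Mann step to the plain
#' gradient iterate \eqn{y_n}, which is useful as an algebraic reduction
#' check.
#'
#' @param sigma extrapolation bound \eqn{\sigma \in [0, 1)}.
#' @param lambda_rel relative step size in \eqn{(0, 2)};
#'   \eqn{\lambda_n = } `lambda_rel` \eqn{/\|A\|^2}.
#' @param alpha_mann Mann averaging weight in \eqn{[0, 1)}, held constant.
#' @param epsilon_n step factor of the self-adaptive IGRCQ step, in
#'   \eqn{(0, 4)}.
#' @param curvature_c,curvature_q nonnegative curvatures \eqn{\alpha},
#'   \eqn{\beta} of the generalized relaxations of C and Q (0 recovers
#'   the classical half-spaces).
#' @param max_iter iteration budget.
#' @param tol stop when the residual \eqn{f_n} falls to or below this;
#'   0 disables the residual stop (the run then always uses the full
#'   `max_iter` budget).
#' @param N iteration count before which the extrapolation decay of the
#'   IMRCQM/IGRCQ schedule is suppressed (`sigma_n = sigma` while
#'   `n <= N`); 0 keeps the decay active from the start, which is what
#'   the summability condition on \eqn{\sigma_n} requires.
#' @param igrcq_anchor where the self-adaptive step of IGRCQ evaluates
#'   \eqn{f_n} and \eqn{\nabla f_n}: at the extrapolated point `"rho"`
#'   (default, matching the gradient actually used by the update) or at
#'   the literal iterate `"omega"`.
#' @param seed integer seed recorded with runs that draw random starts.
#' @return an object of class `solver_config`.
#' @export
solver_config <- function(sigma = 0.9999, lambda_rel = 0.9999,
                          alpha_mann = 1 / 1.2, epsilon_n = 0.1,
                          curvature_c = 0, curvature_q = 0,
                          max_iter = 5000L, tol = 1e-10, N = 0L,
                          igrcq_anchor = c("rho", "omega"), seed = 1L) {
  igrcq_anchor <- match.arg(igrcq_anchor)
  cfg <- structure(
    list(sigma = sigma, lambda_rel = lambda_rel, alpha_mann = alpha_mann,
         epsilon_n = epsilon_n, curvature_c = curvature_c,
         curvature_q = curvature_q, max_iter = as.integer(max_iter),
         tol = tol, N = as.integer(N), igrcq_anchor = igrcq_anchor,
         seed = as.integer(seed)),
    class = "solver_config")
  validate_solver_config(cfg)
  cfg
}

validate_solver_config <- function(cfg) {
  if (!(cfg$sigma >= 0 && cfg$sigma < 1))
    stop("sigma must lie in [0, 1): the extrapolation summability ",
         "condition fails otherwise (got ", cfg$sigma, ")")
  if (!(cfg$lambda_rel > 0 && cfg$lambda_rel < 2))
    stop("lambda_rel must lie in (0, 2) so that lambda_n < 2/||A||^2 ",
         "(got ", cfg$lambda_rel, ")")
  if (!(cfg$alpha_mann >= 0 && cfg$alpha_mann < 1))
    stop("alpha_mann must lie in [0, 1) (got ", cfg$alpha_mann, ")")
  if (!(cfg$epsilon_n > 0 && cfg$epsilon_n < 4))
    stop("epsilon_n must lie in (0, 4) (got ", cfg$epsilon_n, ")")
  if (cfg$curvature_c < 0 || cfg$curvature_q < 0)
    stop("curvatures must be nonnegative")
  if (cfg$max_iter < 1L) stop("max_iter must be at least 1")
  if (cfg$tol < 0) stop("tol must be nonnegative")
  invisible(cfg)
}

#' Proximity function and gradient for a relaxed target set
#'
#' The relaxed CQ methods minimize
#' \eqn{f_n(x) = \tfrac12 \|(I - P_{Q_n}) A x\|^2}
#' with gradient \eqn{\nabla f_n(x) = A^T (I - P_{Q_n}) A x}, where
#' \eqn{P_{Q_n}} is the closed-form projection onto the iteration's
#' relaxation of Q.  Both are returned together since they share the
#' projection.
#'
#' @param A numeric matrix.
#' @param Qrelax a `relaxed_set` for Q (anchored in the image space).
#' @param x point in the domain space.
#' @return list with elements `value` (\eqn{f_n(x)}) and `grad`
#'   (\eqn{\nabla f_n(x)}).
#' @export
grad_fn <- function(A, Qrelax, x) {
  Ax <- drop(A %*% x)
  r <- Ax - project_relaxed(Ax, Qrelax)
  list(value = 0.5 * sum(r * r), grad = drop(crossprod(A, r)))
}

#' Extrapolation schedule of the inertial Mann solver
#'
#' \deqn{\sigma_n = \frac{\sigma}{n^2 \max\{\|\Delta_n\|^2, \|\Delta_n\|\}}}
#' when `n > N` and \eqn{\Delta_n = \omega_n - \omega_{n-1} \ne 0}, and
#' \eqn{\sigma_n = \sigma} otherwise.  On the decay branch
#' \eqn{\sigma_n \max\{\|\Delta_n\|^2, \|\Delta_n\|\} = \sigma/n^2}, so the
#' inertial summability condition holds by comparison with
#' \eqn{\sum 1/n^2}.
#'
#' @param sigma bound \eqn{\sigma \in [0, 1)}.
#' @param n iteration index (>= 1).
#' @param delta the difference \eqn{\omega_n - \omega_{n-1}}.
#' @param N decay-suppression horizon (see [solver_config()]).
#' @return scalar \eqn{\sigma_n}.
#' @export
sigma_schedule <- function(sigma, n, delta, N = 0L) {
  nd <- sqrt(sum(delta * delta))
  if (n > N && nd > 0) sigma / (n^2 * max(nd^2, nd)) else sigma
}

#' Extrapolation cap of the inertial CQ method of Dang et al.
#'
#' \deqn{\bar\sigma_n = \min\{\sigma,\; 1/\max\{n^2\|\Delta_n\|^2,
#'   n^2\|\Delta_n\|\}\}} when \eqn{\Delta_n \ne 0}, else \eqn{\sigma}.
#'
#' @inheritParams sigma_schedule
#' @return scalar \eqn{\bar\sigma_n}.
#' @export
dang_sigma <- function(sigma, n, delta) {
  nd <- sqrt(sum(delta * delta))
  if (nd == 0) return(sigma)
  min(sigma, 1 / max(n^2 * nd^2, n^2 * nd))
}

#' Self-adaptive step size of the IGRCQ method
#'
#' \eqn{\lambda_n = \varepsilon_n f_n / \|\nabla f_n\|^2} when the
#' gradient is nonzero, and 0 otherwise.  Independent of \eqn{\|A\|}.
#'
#' @param f_val scalar \eqn{f_n} at the anchor point.
#' @param grad gradient \eqn{\nabla f_n} at the anchor point.
#' @param epsilon_n factor in \eqn{(0, 4)}.
#' @return scalar step size.
#' @export
igrcq_stepsize <- function(f_val, grad, epsilon_n) {
  g2 <- sum(grad * grad)
  if (g2 == 0) 0 else epsilon_n * f_val / g2
}

#' Solve a split feasibility problem
#'
#' Runs one of four projection schemes on an [sfp_instance()]:
#'
#' * `"imrcqm"` — inertial modified relaxed CQ Mann algorithm: inertial
#'   extrapolation \eqn{\rho_n = \omega_n + \sigma_n(\omega_n -
#'   \omega_{n-1})}, gradient step \eqn{y_n = \rho_n - \lambda_n \nabla
#'   f_n(\rho_n)}, second gradient step \eqn{t_n = y_n - \lambda_n \nabla
#'   f_n(y_n)}, projection \eqn{z_n = P_{C_n}(t_n)}, and Mann averaging
#'   \eqn{\omega_{n+1} = (1-\alpha_n) y_n + \alpha_n z_n}.  The relaxed
#'   target set \eqn{Q_n} is anchored at \eqn{A\rho_n} (the only point
#'   available when it is first needed) and reused for the \eqn{t_n}
#'   step; \eqn{C_n} is anchored at \eqn{y_n}.
#' * `"dang"` — inertial relaxed CQ: \eqn{\omega_{n+1} =
#'   P_{C_n}(\rho_n - \lambda \nabla f_n(\rho_n))} with the capped
#'   extrapolation [dang_sigma()] and classical half-space relaxations.
#' * `"igrcq"` — inertial generalized relaxed CQ of Wang and Yu, with the
#'   self-adaptive step [igrcq_stepsize()].
#' * `"byrne"` — the CQ baseline \eqn{\omega_{n+1} = P_C(\omega_n -
#'   \lambda A^T(I - P_Q) A \omega_n)} using the exact projections, which
#'   both constraint sets must therefore provide.
#'
#' Iterations stop when the residual (\eqn{f_n(y_n)} for IMRCQM,
#' \eqn{f_n(\rho_n)} for the inertial relaxed schemes, \eqn{f(\omega_n)}
#' for Byrne) falls to `tol`, or at `max_iter`.
#'
#' @param problem an [sfp_instance()].
#' @param method one of `"imrcqm"`, `"dang"`, `"igrcq"`, `"byrne"`.
#' @param config a [solver_config()].
#' @param omega0 starting point; default the zero vector (feasible for
#'   the norm-ball constraint sets used throughout).
#' @param store_iterates keep the full iterate history (needed to replay
#'   learning curves); scalars are always recorded.
#' @return an object of class `sfp_run`: list with `omega` (final
#'   iterate), `iterates` (matrix, rows \eqn{\omega_1, \omega_2, \ldots}
#'   when stored), `trace` (data frame with `n`, `sigma_n`, `lambda_n`,
#'   `residual`, `delta_norm`, `step_norm`, and `dist_sol` when the
#'   instance has a known solution), `stop_reason`
#'   (`"tol_reached"`/`"max_iter"`), `n_iter`, `c1_sum` (realized
#'   \eqn{\sum_n \sigma_n \max\{\|\Delta_n\|^2, \|\Delta_n\|\}}), and the
#'   resolved `method`, `config`, `lambda`.
#' @export
sfp_solve <- function(problem, method = c("imrcqm", "dang", "igrcq", "byrne"),
                      config = solver_config(), omega0 = NULL,
                      store_iterates = TRUE) {
  stopifnot(inherits(problem, "sfp_instance"))
  method <- match.arg(method)
  validate_solver_config(config)

  A <- problem$A
  Cc <- problem$Cset
  Qc <- problem$Qset
  n_dim <- ncol(A)
  if (is.null(omega0)) omega0 <- numeric(n_dim)
  stopifnot(length(omega0) == n_dim, all(is.finite(omega0)))

  if (method == "byrne" && (is.null(Cc$project) || is.null(Qc$project)))
    stop("the Byrne CQ baseline needs exact projections onto C and Q")

  normA2 <- operator_norm_sq(A)
  lambda <- config$lambda_rel / normA2
  wsol <- problem$known_solution

  max_iter <- config$max_iter
  sig_v <- lam_v <- res_v <- del_v <- stp_v <- dst_v <- numeric(max_iter)
  iter_m <- if (store_iterates) matrix(NA_real_, max_iter, n_dim) else NULL

  omega_prev <- omega0
  omega <- omega0
  stop_reason <- "max_iter"
  c1_sum <- 0
  n_done <- 0L

  for (n in seq_len(max_iter)) {
    delta <- omega - omega_prev
    nd <- sqrt(sum(delta * delta))

    if (method == "imrcqm") {
      sn <- sigma_schedule(config$sigma, n, delta, config$N)
      rho <- omega + sn * delta
      Qn <- build_relaxed_set(Qc, drop(A %*% rho), config$curvature_q)
      gr <- grad_fn(A, Qn, rho)
      y <- rho - lambda * gr$grad
      gy <- grad_fn(A, Qn, y)
      Cn <- build_relaxed_set(Cc, y, config$curvature_c)
      t_n <- y - lambda * gy$grad
      z <- project_relaxed(t_n, Cn)
      # y + alpha*(z - y) rather than (1-alpha)*y + alpha*z: exact when
      # z == y, so a solution stays a fixed point to the last bit
      omega_next <- y + config$alpha_mann * (z - y)
      residual <- gy$value
      lam_n <- lambda
    } else if (method == "dang") {
      sn <- dang_sigma(config$sigma, n, delta)
      rho <- omega + sn * delta
      Qn <- build_relaxed_set(Qc, drop(A %*% rho), 0)
      gr <- grad_fn(A, Qn, rho)
      Cn <- build_relaxed_set(Cc, rho, 0)
      omega_next <- project_relaxed(rho - lambda * gr$grad, Cn)
      residual <- gr$value
      lam_n <- lambda
    } else if (method == "igrcq") {
      sn <- sigma_schedule(config$sigma, n, delta, config$N)
      rho <- omega + sn * delta
      Qn <- build_relaxed_set(Qc, drop(A %*% rho), config$curvature_q)
      gr <- grad_fn(A, Qn, rho)
      anch <- if (config$igrcq_anchor == "rho") gr else grad_fn(A, Qn, omega)
      lam_n <- igrcq_stepsize(anch$value, anch$grad, config$epsilon_n)
      Cn <- build_relaxed_set(Cc, rho, config$curvature_c)
      omega_next <- project_relaxed(rho - lam_n * gr$grad, Cn)
      residual <- gr$value
    } else { # byrne
      sn <- 0
      Ax <- drop(A %*% omega)
      r <- Ax - Qc$project(Ax)
      residual <- 0.5 * sum(r * r)
      omega_next <- Cc$project(omega - lambda * drop(crossprod(A, r)))
      lam_n <- lambda
    }

    if (!all(is.finite(omega_next)))
      stop("solver diverged: non-finite iterate at n = ", n)

    n_done <- n
    sig_v[n] <- sn
    lam_v[n] <- lam_n
    res_v[n] <- residual
    del_v[n] <- nd
    stp_v[n] <- sqrt(sum((omega_next - omega)^2))
    dst_v[n] <- if (is.null(wsol)) NA_real_
                else sqrt(sum((omega_next - wsol)^2))
    if (store_iterates) iter_m[n, ] <- omega_next
    c1_sum <- c1_sum + sn * max(nd^2, nd)

    omega_prev <- omega
    omega <- omega_next

    if (config$tol > 0 && residual <= config$tol) {
      stop_reason <- "tol_reached"
      break
    }
  }

  keep <- seq_len(n_done)
  trace <- data.frame(n = keep, sigma_n = sig_v[keep], lambda_n = lam_v[keep],
                      residual = res_v[keep], delta_norm = del_v[keep],
                      step_norm = stp_v[keep], dist_sol = dst_v[keep])
  structure(
    list(omega = omega, omega0 = omega0,
         iterates = if (store_iterates) iter_m[keep, , drop = FALSE] else NULL,
         trace = trace, stop_reason = stop_reason, n_iter = n_done,
         c1_sum = c1_sum, method = method, config = config,
         lambda = lambda, norm_A_sq = normA2),
    class = "sfp_run")
}

#' @export
print.sfp_run <- function(x, ...) {
  cat(sprintf("<sfp_run> %s: %d iterations (%s), final residual %.3g\n",
              x$method, x$n_iter, x$stop_reason,
              x$trace$residual[x$n_iter]))
  if (!all(is.na(x$trace$dist_sol)))
    cat(sprintf("  distance to known solution: %.3g\n",
                x$trace$dist_sol[x$n_iter]))
  invisible(x)
}

#' Write a solver trace as delimited text
#'
#' @param run an `sfp_run`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(run, path) {
  stopifnot(inherits(run, "sfp_run"))
  utils::write.csv(run$trace, path, row.names = FALSE)
  invisible(path)
}
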