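test_that("proximity function and gradient have their closed-form values", {
  # image point inside the relaxed set: residual and gradient vanish
  A <- matrix(c(1, 0, 0, 1), 2)
  Qn <- build_relaxed_set(cc_ball(c(0, 0), 2), c(0.5, 0.5))
  g <- grad_fn(A, Qn, c(0.3, -0.2))
  expect_equal(g$value, 0)
  expect_equal(g$grad, c(0, 0))

  # half-space {w1 <= 0}: f(2,1) = 2, grad = (2, 0)
  Qh <- build_relaxed_set(cc_halfspace(c(1, 0), 0), c(1, 1))
  g <- grad_fn(diag(2), Qh, c(2, 1))
  expect_equal(g$value, 2)
  expect_equal(g$grad, c(2, 0))
})

test_that("gradient of the proximity function matches finite differences", {
  set.seed(31)
  A <- matrix(rnorm(12), 4, 3)
  for (Qc in list(cc_halfspace(c(1, 0.5, -1, 2), -0.2),
                  cc_singleton(rnorm(4)),
                  cc_ball(rnorm(4), 0.3))) {
    for (kap in c(0, 0.5)) {
      x <- rnorm(3, sd = 2)
      Qn <- build_relaxed_set(Qc, drop(A %*% x) + rnorm(4, sd = 0.1), kap)
      fx <- function(v) grad_fn(A, Qn, v)$value
      g <- grad_fn(A, Qn, x)
      if (sqrt(sum(g$grad^2)) > 1e-3)  # away from the kink at f = 0
        expect_equal(g$grad, num_grad(fx, x), tolerance = 1e-5)
    }
  }
})

test_that("extrapolation schedules follow their formulas", {
  # stationary iterates keep the full sigma
  expect_equal(sigma_schedule(0.9999, 5, c(0, 0)), 0.9999)
  # decay branch: sigma / (n^2 * max{||d||^2, ||d||})
  expect_equal(sigma_schedule(0.9, 2, c(2, 0)), 0.9 / 16)
  # small steps use the linear norm in the max
  expect_equal(sigma_schedule(0.9, 2, c(0.5, 0)), 0.9 / (4 * 0.5))
  # decay suppressed while n <= N
  expect_equal(sigma_schedule(0.9, 2, c(2, 0), N = 10), 0.9)

  expect_equal(dang_sigma(0.9999, 3, c(0, 0)), 0.9999)
  expect_equal(dang_sigma(0.9999, 1, c(1, 0)), 0.9999)
  expect_equal(dang_sigma(0.9999, 10, c(1, 0)), 0.01)

  # realized inertial weight sums below sigma * pi^2 / 6 for arbitrary
  # iterate gaps
  set.seed(13)
  for (rep in 1:5) {
    deltas <- lapply(1:1000, function(i) rnorm(3, sd = runif(1, 0, 10)))
    s <- sum(vapply(seq_along(deltas), function(n) {
      d <- deltas[[n]]
      nd <- sqrt(sum(d^2))
      sigma_schedule(0.9999, n, d) * max(nd^2, nd)
    }, numeric(1)))
    expect_lte(s, 0.9999 * pi^2 / 6)
  }
})

test_that("self-adaptive step size follows the zero-gradient convention", {
  expect_equal(igrcq_stepsize(0.5, c(0, 0), 0.1), 0)
  expect_equal(igrcq_stepsize(0.5, c(2, 0), 0.1), 0.0125)
  # scaling the gradient by t scales the step by 1/t^2
  g <- c(1.2, -0.7)
  expect_equal(igrcq_stepsize(2, 3 * g, 0.5),
               igrcq_stepsize(2, g, 0.5) / 9)
})

test_that("a known solution is a fixed point of every method", {
  for (constraint in c("l2_ball", "l1_ball")) {
    p <- tiny_sfp(seed = 2, constraint = constraint)
    for (m in c("imrcqm", "dang", "igrcq", "byrne")) {
      run <- sfp_solve(p, m, solver_config(max_iter = 5, tol = 0),
                       omega0 = p$known_solution)
      expect_lte(max(run$trace$step_norm), 1e-12, label = m)
      expect_lte(sqrt(sum((run$omega - p$known_solution)^2)), 1e-12,
                 label = m)
    }
  }
})

test_that("IMRCQM without inertia or averaging is the plain gradient iteration", {
  p <- tiny_sfp(seed = 4)
  cfg <- solver_config(sigma = 0, alpha_mann = 0, max_iter = 40, tol = 0)
  run <- sfp_solve(p, "imrcqm", cfg)

  # hand-rolled gradient iteration with the relaxed target set anchored
  # at the current point
  lam <- cfg$lambda_rel / operator_norm_sq(p$A)
  w <- numeric(ncol(p$A))
  for (n in 1:40) {
    Qn <- build_relaxed_set(p$Qset, drop(p$A %*% w), 0)
    w <- w - lam * grad_fn(p$A, Qn, w)$grad
    expect_equal(run$iterates[n, ], w, tolerance = 1e-12)
  }
})

test_that("Byrne CQ reaches the ball solution in one exact step", {
  # A = I, C = Q = unit ball, start (2, 0), lambda = 1:
  # Proj_C((2,0) - ((2,0) - (1,0))) = (1, 0)
  p <- sfp_instance(diag(2), cc_l2_ball(1), cc_l2_ball(1))
  run <- sfp_solve(p, "byrne", solver_config(lambda_rel = 1, max_iter = 3),
                   omega0 = c(2, 0))
  expect_equal(run$iterates[1, ], c(1, 0))
  expect_equal(run$omega, c(1, 0))
  expect_equal(run$stop_reason, "tol_reached")
})

test_that("all four methods solve a feasible instance to small residual", {
  p <- tiny_sfp(seed = 5)
  for (m in c("imrcqm", "dang", "igrcq", "byrne")) {
    run <- sfp_solve(p, m, solver_config(tol = 1e-10, max_iter = 5000))
    expect_equal(run$stop_reason, "tol_reached", label = m)
    expect_lte(min(run$trace$residual), 1e-8)
    expect_lte(p$Cset$value(run$omega), 1e-6)
  }
})

test_that("inertial summability holds along realized IMRCQM runs", {
  for (s in 1:3) {
    run <- sfp_solve(tiny_sfp(seed = s), "imrcqm", solver_config())
    expect_lte(run$c1_sum, 0.9999 * pi^2 / 6)
    # recompute the sum from the trace
    expect_equal(run$c1_sum,
                 sum(run$trace$sigma_n *
                       pmax(run$trace$delta_norm^2, run$trace$delta_norm)))
  }
})

test_that("the Fejer-type inequality holds per iteration on feasible runs", {
  for (s in 1:3) {
    p <- tiny_sfp(seed = s)
    run <- sfp_solve(p, "imrcqm", solver_config(tol = 1e-10))
    d0 <- sqrt(sum((run$omega0 - p$known_solution)^2))
    dist <- c(d0, run$trace$dist_sol)
    lhs <- dist[-1]
    rhs <- dist[-length(dist)] +
      run$trace$sigma_n * run$trace$delta_norm + 1e-9
    expect_true(all(lhs <= rhs))
  }
})

test_that("solver configuration bounds are enforced", {
  expect_error(solver_config(sigma = 1.5), "\\[0, 1\\)")
  expect_error(solver_config(sigma = -0.1), "\\[0, 1\\)")
  expect_error(solver_config(lambda_rel = 2.5), "\\(0, 2\\)")
  expect_error(solver_config(alpha_mann = 1), "\\[0, 1\\)")
  expect_error(solver_config(epsilon_n = 5), "\\(0, 4\\)")
  expect_error(solver_config(curvature_c = -1), "nonnegative")
})

test_that("igrcq can anchor its step at the literal iterate", {
  # with a half-space relaxation of Q the ratio f/||grad f||^2 is the
  # same at every infeasible point (the residual is parallel to the
  # normal), so the anchor choice is only observable with curvature;
  # q(w) = 0.5*||w - R||^2 is 1-strongly convex, so beta = 0.5 is valid
  p <- tiny_sfp(seed = 6)
  cfg_rho <- solver_config(max_iter = 400, tol = 0, curvature_q = 0.5)
  cfg_om <- solver_config(max_iter = 400, tol = 0, curvature_q = 0.5,
                          igrcq_anchor = "omega")
  r1 <- sfp_solve(p, "igrcq", cfg_rho)
  r2 <- sfp_solve(p, "igrcq", cfg_om)
  expect_gt(max(abs(r1$trace$lambda_n - r2$trace$lambda_n)), 0)
  # both variants still drive the residual down
  expect_lt(min(r1$trace$residual), 1e-4)
  expect_lt(min(r2$trace$residual), 1e-4)
})
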