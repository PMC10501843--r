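test_that("operator_norm_sq matches the largest squared singular value", {
  expect_equal(operator_norm_sq(diag(4)), 1)
  expect_equal(operator_norm_sq(diag(c(3, 4))), 16)

  set.seed(42)
  for (i in 1:5) {
    A <- matrix(rnorm(40), 8, 5)
    expect_equal(operator_norm_sq(A), max(svd(A)$d)^2, tolerance = 1e-10)
  }
  # wide matrices go through the A A^T branch
  B <- matrix(rnorm(40), 5, 8)
  expect_equal(operator_norm_sq(B), max(svd(B)$d)^2, tolerance = 1e-10)

  expect_error(operator_norm_sq(matrix(c(1, NA), 1)), "finite")
})

test_that("half-space projection: closed form, feasibility, degeneracies", {
  expect_equal(project_halfspace(c(-1, 2), c(1, 0), 0), c(-1, 2))
  expect_equal(project_halfspace(c(2, 3), c(1, 0), 0), c(0, 3))

  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(5); b <- rnorm(1); x <- rnorm(5, sd = 2)
    p <- project_halfspace(x, a, b)
    expect_lte(sum(a * p) - b, 1e-12)
  }
  # zero normal: whole space vs empty set
  expect_equal(project_halfspace(c(1, 2), c(0, 0), 1), c(1, 2))
  expect_error(project_halfspace(c(1, 2), c(0, 0), -1), "empty")
})

test_that("ball projection: interior identity and radial scaling", {
  expect_equal(project_ball(c(0.3, 0.4), c(0, 0), 1), c(0.3, 0.4))
  expect_equal(project_ball(c(3, 4), c(0, 0), 1), c(0.6, 0.8))
  expect_equal(project_ball(c(2, 1), c(2, 1), 0), c(2, 1))
  expect_error(project_ball(c(1, 0), c(0, 0), -0.1), "nonnegative")
})

test_that("L1-ball projection: sort-and-threshold stays inside the ball", {
  expect_equal(project_l1_ball(c(0.5, 0.2), 1), c(0.5, 0.2))
  expect_equal(project_l1_ball(c(2, 0), 1), c(1, 0))

  set.seed(11)
  for (i in 1:50) {
    x <- rnorm(10, sd = 3)
    p <- project_l1_ball(x, 1.5)
    expect_lte(sum(abs(p)), 1.5 + 1e-10)
    # projection preserves signs and shrinks coordinates
    expect_true(all(abs(p) <= abs(x) + 1e-12))
    expect_true(all(p * x >= -1e-12))
  }
  expect_error(project_l1_ball(c(1, 2), 0), "positive")
})

test_that("relaxed sets freeze the oracles and contain the true set", {
  # L2 ball gamma = 17 anchored at the origin relaxes to the whole space
  S <- build_relaxed_set(cc_l2_ball(17), c(0, 0))
  expect_equal(S$fval, -17)
  expect_equal(S$subgrad, c(0, 0))
  expect_equal(project_relaxed(c(5, -3), S), c(5, -3))

  # L1 subgradient is the sign vector (0 kept at zero coordinates)
  S1 <- build_relaxed_set(cc_l1_ball(7), c(3, -1))
  expect_equal(S1$fval, -3)
  expect_equal(S1$subgrad, c(1, -1))
  S0 <- build_relaxed_set(cc_l1_ball(7), c(3, 0))
  expect_equal(S0$subgrad, c(1, 0))

  # set nesting: every feasible point of C satisfies the relaxed
  # membership inequality.  Positive curvature preserves nesting only
  # when the level function is at least that strongly convex (modulus 2
  # for the squared-norm balls); the merely-convex functions get the
  # half-space relaxation.
  set.seed(3)
  specs <- list(
    list(cons = cc_l1_ball(2), kmax = 0),
    list(cons = cc_halfspace(c(1, -2, 0.5), 0.3), kmax = 0),
    list(cons = cc_box(rep(-1, 3), rep(2, 3)), kmax = 0),
    list(cons = cc_l2_ball(4), kmax = 2),
    list(cons = cc_ball(c(1, 1, 1), 1.5), kmax = 2))
  for (sp in specs) {
    cons <- sp$cons
    for (i in 1:20) {
      anchor <- rnorm(3, sd = 2)
      kap <- if (sp$kmax > 0) runif(1, 0, sp$kmax) else 0
      S <- build_relaxed_set(cons, anchor, kap)
      # rejection-sample a feasible point
      repeat {
        w <- rnorm(3, sd = 1.5)
        if (cons$value(w) <= 0) break
        w <- cons$project(w)
        break
      }
      expect_lte(relaxed_membership(S, w), 1e-10)
    }
  }
})

test_that("relaxed projection handles half-space, ball and empty cases", {
  # whole space: nonpositive value with zero subgradient
  S <- structure(list(anchor = c(0, 0), fval = -1, subgrad = c(0, 0),
                      curvature = 0), class = "relaxed_set")
  expect_equal(project_relaxed(c(4, 4), S), c(4, 4))

  # half-space case written out: {w : 1 <= <(1,0), -w>} = {w1 <= -1}
  S <- structure(list(anchor = c(0, 0), fval = 1, subgrad = c(1, 0),
                      curvature = 0), class = "relaxed_set")
  expect_equal(project_relaxed(c(0, 0), S), c(-1, 0))

  # curvature 2 completes the square to the unit ball at (-1, 0)
  S <- structure(list(anchor = c(0, 0), fval = 0, subgrad = c(2, 0),
                      curvature = 2), class = "relaxed_set")
  expect_equal(project_relaxed(c(1, 0), S), c(0, 0))
  expect_equal(project_relaxed(c(-1, 0.5), S), c(-1, 0.5))

  # empty relaxations are hard errors
  Sneg <- structure(list(anchor = c(0, 0), fval = 5, subgrad = c(0.1, 0),
                         curvature = 2), class = "relaxed_set")
  expect_error(project_relaxed(c(0, 0), Sneg), "empty")
  Szero <- structure(list(anchor = c(0, 0), fval = 2, subgrad = c(0, 0),
                          curvature = 0), class = "relaxed_set")
  expect_error(project_relaxed(c(0, 0), Szero), "empty")
})

test_that("differentiable constraints have subgradient equal to the gradient", {
  set.seed(5)
  for (cons in list(cc_l2_ball(3), cc_ball(c(0.5, -1, 2), 1.2),
                    cc_singleton(c(1, -1, 0)))) {
    for (i in 1:5) {
      w <- rnorm(3, sd = 2)
      g <- cons$subgrad(w)
      gn <- num_grad(cons$value, w)
      expect_equal(g, gn, tolerance = 1e-5)
    }
  }
})

test_that("projections agree with the generic convex-program oracle", {
  set.seed(19)
  kinds <- c("halfspace", "ball", "l1", "relaxed_half", "relaxed_ball")
  insts <- unlist(lapply(kinds, function(k)
    replicate(6, random_proj_instance(k), simplify = FALSE)),
    recursive = FALSE)
  ours <- lapply(insts, pkg_project)
  ref <- qp_project_oracle(insts)
  for (i in seq_along(insts))
    expect_equal(ours[[i]], ref[[i]], tolerance = 1e-6,
                 label = sprintf("instance %d (%s)", i, insts[[i]]$kind))
})

test_that("exact-set projections are firmly nonexpansive and idempotent", {
  set.seed(23)
  projs <- list(
    function(x) project_halfspace(x, c(1, -2, 0.5, 1), 0.3),
    function(x) project_ball(x, c(0.5, 0, -1, 2), 1.3),
    function(x) project_l1_ball(x, 1.2),
    function(x) project_relaxed(
      x, build_relaxed_set(cc_l2_ball(2), c(1.5, 0.2, -0.4, 1), 0.5)))
  for (P in projs) {
    for (i in 1:50) {
      x <- rnorm(4, sd = 2); y <- rnorm(4, sd = 2)
      px <- P(x); py <- P(y)
      expect_lte(sum((px - py)^2), sum((px - py) * (x - y)) + 1e-10)
      expect_equal(P(px), px, tolerance = 1e-12)
    }
  }
})
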