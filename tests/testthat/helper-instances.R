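# Random projection-problem generators shared by the unit and
# acceptance suites.  Dimensions are kept <= 10 so the SLSQP oracle is
# exact to well below the comparison tolerance.

random_proj_instance <- function(kind, dim = sample(2:10, 1)) {
  x <- rnorm(dim, sd = 2)
  switch(kind,
    halfspace = list(kind = "halfspace", x = x, a = rnorm(dim),
                     b = rnorm(1)),
    ball = list(kind = "ball", x = x, center = rnorm(dim),
                radius = runif(1, 0.2, 2)),
    l1 = list(kind = "l1", x = x, gamma = runif(1, 0.5, 3)),
    relaxed_half = {
      # nonempty by construction: half-space form of a relaxation
      list(kind = "relaxed", x = x, anchor = rnorm(dim),
           fval = rnorm(1), subgrad = rnorm(dim), curvature = 0)
    },
    relaxed_ball = {
      # curvature > 0 with nonnegative squared radius
      kap <- runif(1, 0.5, 2)
      g <- rnorm(dim)
      r2max <- sum(g^2) / kap^2
      fval <- runif(1, 0, 0.45) * kap * r2max  # 2*fval/kap <= 0.9*r2max
      list(kind = "relaxed", x = x, anchor = rnorm(dim),
           fval = fval, subgrad = g, curvature = kap)
    },
    stop("unknown kind"))
}

# apply the package's closed-form projection to an instance
pkg_project <- function(inst) {
  switch(inst$kind,
    halfspace = project_halfspace(inst$x, inst$a, inst$b),
    ball = project_ball(inst$x, inst$center, inst$radius),
    l1 = project_l1_ball(inst$x, inst$gamma),
    relaxed = project_relaxed(
      inst$x,
      structure(list(anchor = inst$anchor, fval = inst$fval,
                     subgrad = inst$subgrad, curvature = inst$curvature),
                class = "relaxed_set")))
}

# small, quickly-solved feasible SFP fixture
tiny_sfp <- function(seed = 1, constraint = "l2_ball", q_kind = "singleton") {
  make_sfp_instance(m = 20L, n = 10L, constraint = constraint,
                    q_kind = q_kind, seed = seed)
}
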