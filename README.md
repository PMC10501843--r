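# relaxcq

Projection algorithms for the **split feasibility problem** (SFP) —
find ω ∈ C with Aω ∈ Q for closed convex sets C, Q and a linear
operator A — and their application to training an **extreme learning
machine** (ELM) under a norm constraint for binary classification of
tabular clinical data (mammographic-mass severity: benign vs
malignant).

The centerpiece is an inertial modified relaxed CQ **Mann** algorithm
(IMRCQM). Writing Δₙ = ωₙ − ωₙ₋₁ and fₙ(x) = ½‖(I − P_{Qₙ})Ax‖² for a
per-iteration half-space/ball relaxation Qₙ of Q:

    ρₙ = ωₙ + σₙ Δₙ                      (inertial extrapolation)
    yₙ = ρₙ − λₙ ∇fₙ(ρₙ)                 (gradient step)
    tₙ = yₙ − λₙ ∇fₙ(yₙ)
    zₙ = P_{Cₙ}(tₙ)                      (relaxed projection)
    ωₙ₊₁ = (1 − αₙ) yₙ + αₙ zₙ           (Mann averaging)

with σₙ decaying so that Σ σₙ·max{‖Δₙ‖², ‖Δₙ‖} < ∞,
λₙ = 0.9999/‖A‖², and αₙ = 1/1.2. Three comparison solvers share the
interface: the Byrne CQ baseline (exact projections), the inertial
relaxed CQ method of Dang et al., and the self-adaptive inertial
generalized relaxed CQ (IGRCQ) method of Wang–Yu.

ELM training is posed as the constrained least-squares SFP

    min_{ω ∈ C} ‖Hω − R‖²,   C = {‖ω‖₁ ≤ γ}  or  {‖ω‖₂² ≤ γ},

with A = H (the random-hidden-layer output matrix), Q = {R} the target
vector, solved by any of the four methods. Constraint sets are
described by convex level functions with subgradient oracles
(`cc_l1_ball`, `cc_l2_ball`, `cc_halfspace`, `cc_singleton`, `cc_box`,
…), so every projection the solvers take is closed-form.

Also included: a reader/cleaner for the UCI mammographic-mass CSV
dialect (6 comma-separated fields, `?` for missing), synthetic
generators for feasible SFP instances with planted solutions and for
labelled feature tables with the published attribute marginals,
confusion-matrix metrics, binary cross-entropy learning curves,
stratified k-fold cross-validation, and a small CLI
(`inst/cli/relaxcq`: `solve`, `benchmark`, `simulate`, `elm-train`).

See the vignette in `vignettes/constrained-elm-sfp.Rmd` for the
methods account: relaxation geometry (including when positive
curvature is sound), anchor-order decisions, schedule and parameter
defaults, and what the synthetic generator does and does not emulate.

## Worked example

```r
library(relaxcq)

# a feasible 20x10 SFP instance with a planted solution
p <- make_sfp_instance(m = 20, n = 10, constraint = "l2_ball", seed = 1)
run <- sfp_solve(p, "imrcqm", solver_config(tol = 1e-10))
run
#> <sfp_run> imrcqm: 160 iterations (tol_reached), final residual 6.75e-11
#>   distance to known solution: 1.52e-05

# synthetic stand-in for the clinical table (961 rows, 445 malignant)
d <- make_classification_table(seed = 1)
d
#> <training_set> 961 samples x 5 features, 445 positive

# 5-fold cross-validated ELM trained by IMRCQM under the L2 ball
cv <- cross_validate(d, k = 5, seed = 1, n_hidden = 160,
                     constraint = "l2_ball", gamma = 17,
                     method = "imrcqm",
                     config = solver_config(max_iter = 500, tol = 1e-6))
cv
#> <cv_result> 5 folds, mean 500 iterations
#>   mean accuracy 85.85  precision 84.16  recall 85.62  F1 84.81
```

The solver run converges to the planted solution (residual is
fₙ(yₙ); the distance column certifies against the known ω*). The
cross-validation numbers are percentages on held-out folds: at the
generator's default moderate class separation the constrained ELM
plateaus in the mid-80s, the regime the published benchmark reports
for this task.

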