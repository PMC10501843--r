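---
title: "Inertial relaxed CQ methods for split feasibility problems, and norm-constrained ELM training"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inertial relaxed CQ methods for split feasibility problems, and norm-constrained ELM training}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relaxcq)
```

## The problem

The split feasibility problem (SFP) asks for a point
$\omega^* \in C$ with $A\omega^* \in Q$, where $C \subseteq \mathbb{R}^n$
and $Q \subseteq \mathbb{R}^m$ are closed convex sets and $A$ an
$m \times n$ matrix. Byrne's CQ algorithm solves it by the
projected-gradient iteration
$$\omega_{n+1} = P_C\!\left(\omega_n - \lambda A^{T}(I - P_Q)A\omega_n\right),
\qquad 0 < \lambda < 2/\|A\|^2,$$
which needs the exact projections $P_C$, $P_Q$. When those are
expensive, the *relaxed* CQ family replaces $C$ and $Q$ at each
iteration by supersets with closed-form projections, built from the
level-set representation $C = \{\omega : c(\omega) \le 0\}$,
$Q = \{\omega : q(A\omega) \le 0\}$ with convex $c, q$ and subgradient
oracles. This package represents those descriptions as
`convex_constraint` objects and ships the stock constructors
(`cc_l1_ball`, `cc_l2_ball`, `cc_ball`, `cc_halfspace`, `cc_singleton`,
`cc_box`).

## Relaxed sets and their geometry

At an anchor $y_n$ the generalized relaxation of $C$ is
$$C_n = \left\{\omega : c(y_n) \le \langle \varrho_n, y_n - \omega\rangle
 - \tfrac{\alpha}{2}\|y_n - \omega\|^2 \right\},
 \qquad \varrho_n \in \partial c(y_n),\ \alpha \ge 0,$$
and analogously $Q_n$ with curvature $\beta$ at $A y_n$. With
$\alpha = 0$ this is the classical subgradient half-space; with
$\alpha > 0$, completing the square turns it into the Euclidean ball of
center $y_n - \varrho_n/\alpha$ and squared radius
$\|\varrho_n\|^2/\alpha^2 - 2c(y_n)/\alpha$. Both forms have one-line
projections (`project_relaxed`), and both are what the solvers actually
project onto.

One point deserves emphasis because it constrains valid parameter
choices. The containment $C \subseteq C_n$ — the property that makes
projecting onto the relaxation sound — follows from convexity of $c$
only when $\alpha = 0$. For $\alpha > 0$ it requires $c$ to be
$\alpha$-strongly convex: the subgradient inequality must hold with an
extra $\tfrac{\alpha}{2}\|\cdot\|^2$ term. Of the stock constraints,
the squared-norm balls (`cc_l2_ball`, `cc_ball`; modulus 2) and the
singleton (`cc_singleton`, $q(\omega)=\tfrac12\|\omega-R\|^2$; modulus
1) support positive curvature; the L1 ball, half-space and box do not.
The experiments behind the default settings never state curvature
values, so **both curvatures default to 0**, which recovers the
classical half-spaces and is valid for every constraint. The test
suite checks the nesting invariant on sampled feasible points exactly
under these modulus bounds. A curvature too large for the anchor can
produce an empty relaxation (negative squared radius); that is a hard
error, not a silent skip, because it signals an invalid $\alpha/\beta$
choice for which no fallback is defined.

The L1 subgradient at zero coordinates is taken as 0 — a valid element
of the subdifferential that keeps the relaxed set as large as possible
and makes the oracle deterministic.

## The four solvers

`sfp_solve()` implements, with a shared trace format:

* **imrcqm** — the inertial modified relaxed CQ Mann algorithm, the
  package's centerpiece. With $\Delta_n = \omega_n - \omega_{n-1}$ and
  $f_n(x) = \tfrac12\|(I - P_{Q_n})Ax\|^2$,
  $$\rho_n = \omega_n + \sigma_n \Delta_n,\quad
    y_n = \rho_n - \lambda_n \nabla f_n(\rho_n),\quad
    t_n = y_n - \lambda_n \nabla f_n(y_n),$$
  $$z_n = P_{C_n}(t_n),\qquad
    \omega_{n+1} = (1-\alpha_n) y_n + \alpha_n z_n .$$
  The convergence conditions are: (C1) summability of
  $\sigma_n \max\{\|\Delta_n\|^2, \|\Delta_n\|\}$; (C2)
  $0 < \liminf \lambda_n \le \limsup \lambda_n < 2/\|A\|^2$; (C3)
  $0 < \liminf \alpha_n \le \limsup \alpha_n < 1$.
* **dang** — the inertial relaxed CQ method with the capped
  extrapolation $\bar\sigma_n = \min\{\sigma, 1/\max\{n^2\|\Delta_n\|^2,
  n^2\|\Delta_n\|\}\}$ and classical half-space relaxations.
* **igrcq** — the inertial generalized relaxed CQ method with the
  self-adaptive, $\|A\|$-free step
  $\lambda_n = \varepsilon_n f_n/\|\nabla f_n\|^2$ ($0$ when the
  gradient vanishes).
* **byrne** — the exact-projection CQ baseline above.

Two places in these schemes were genuinely open and were resolved as
follows.

**Anchor order.** The relaxation definitions anchor both $C_n$ and
$Q_n$ at $y_n$, but $y_n$ is itself computed with $\nabla f_n$, which
needs $Q_n$ — a circularity. The implementation anchors $Q_n$ at
$A\rho_n$, the only point available when $Q_n$ is first needed, reuses
that single $Q_n$ for the $t_n$ step (the convergence argument
evaluates $\nabla f_n$ at both $\rho_n$ and $y_n$ with one $Q_n$ per
iteration), and anchors $C_n$ at $y_n$ as written.

**IGRCQ step anchor.** The self-adaptive step is printed with anchor
$\omega_n$ while the update moves from $\rho_n$; the default here
anchors it at $\rho_n$ so the step matches the gradient actually used
(`igrcq_anchor = "omega"` switches to the literal form). A small
geometric fact makes this near-moot in the common case: against a
*half-space* relaxation of $Q$ the residual $(I - P_{Q_n})Ax$ of every
infeasible point is parallel to the half-space normal, so the ratio
$f_n/\|\nabla f_n\|^2$ — hence the step — is the same at $\rho_n$ and
$\omega_n$. The two anchors only produce different runs when the
relaxation is a ball (positive curvature).

**Extrapolation schedule.** The decaying schedule used by imrcqm and
igrcq is
$$\sigma_n = \begin{cases}
  \dfrac{\sigma}{n^2\max\{\|\Delta_n\|^2, \|\Delta_n\|\}}
    & n > N,\ \Delta_n \ne 0,\\[2ex]
  \sigma & \text{otherwise,}\end{cases}$$
so that on the decay branch
$\sigma_n\max\{\|\Delta_n\|^2,\|\Delta_n\|\} = \sigma/n^2$ and (C1)
holds by comparison with $\sum 1/n^2 = \pi^2/6$. The branch horizon
$N$ ("suppress decay for the first $N$ iterations") defaults to 0:
(C1) is what the convergence proof consumes, and a positive $N$ would
suspend it during the run. The solver records the realized sum so
tests can assert the bound $\sigma \pi^2/6$ directly. Stationarity
($\Delta_n = 0$) is detected by exact equality, not an epsilon — it is
the schedule's own branch condition, and the fixed-point tests depend
on it being exact.

**Numerical form of the Mann step.** The update is computed as
$y_n + \alpha_n(z_n - y_n)$ rather than
$(1-\alpha_n)y_n + \alpha_n z_n$. Algebraically identical, but the
first form returns $y_n$ *exactly* when $z_n = y_n$, so a planted
solution is a bitwise fixed point. The distinction matters because the
decay schedule normalizes the inertial kick to magnitude
$\sigma/n^2$ whatever the size of $\Delta_n$: floating-point dust of
$10^{-17}$ in $\Delta_n$ would otherwise be amplified into an $O(\sigma/n^2)$
perturbation.

### Default parameters

| parameter | default | meaning |
|---|---|---|
| `sigma` | 0.9999 | extrapolation bound $\sigma \in [0,1)$ |
| `lambda_rel` | 0.9999 | $\lambda_n = $ `lambda_rel`$/\|A\|^2$, constant (C2) |
| `alpha_mann` | $1/1.2 \approx 0.833$ | Mann weight $\alpha_n$, constant (C3) |
| `epsilon_n` | 0.1 | IGRCQ step factor in $(0,4)$ |
| `curvature_c`, `curvature_q` | 0 | relaxation curvatures $\alpha, \beta$ |
| `tol` | $10^{-10}$ | residual stop on $f_n$; 0 disables the stop |
| `max_iter` | 5000 | iteration budget |

These are the published experimental settings of the classification
study this package reimplements (the Mann weight is printed there in a
typographically collapsed form best read as $1/1.2$), with the
norm budgets $\gamma = 7$ (L1) and $\gamma = 17$ (L2). `alpha_mann = 0`
is accepted although (C3) requires it positive: it reduces the scheme
exactly to the gradient iteration on $f_n$, which the test suite uses
as an algebraic cross-check. `operator_norm_sq` computes $\|A\|^2$
with an exact symmetric eigensolver on $A^TA$ — desk-scale matrices do
not justify a power method, and exactness keeps runs deterministic.

## ELM training as a norm-constrained SFP

The extreme learning machine draws hidden weights $c_i$ and biases
$e_i$ once, uniformly on $[-1,1]$ from a stated seed (the literature
rarely reports the distribution; uniform is the common choice and the
seed makes every run reproducible), and fits only the output weight
$w$. With hidden matrix $H_{si} = \mathrm{sigmoid}(\langle c_i,
\mu_s\rangle + e_i)$ and 0/1 target vector $R$, training solves
$$\min_{\omega \in C} \|H\omega - R\|_2^2,\qquad
  C = \{\|\omega\|_1 \le \gamma\} \text{ or } \{\|\omega\|_2^2 \le \gamma\},$$
encoded as the SFP with $A = H$, $Q = \{R\}$ described by
$q(\omega) = \tfrac12\|\omega - R\|^2$, and started from
$\omega_0 = \omega_1 = 0$ (feasible for both balls since
$c(0) = -\gamma < 0$). Targets are a single 0/1 column (malignant
$= 1$): that is what the 0.5 decision threshold and the binary
cross-entropy monitor presuppose, and nothing in the published setup
indicates one-hot coding. Features are standardized to zero mean and
unit variance before the hidden layer (standard ELM practice with
bounded activations; toggleable with `standardize = FALSE`); the
scaling is stored in the model and re-applied at prediction.

The decision rule is `label 1 iff output >= threshold` with threshold
0.5; ties go to the positive class by the `>=` convention.

For the loss curves, raw ELM outputs are clipped into
$[10^{-7}, 1-10^{-7}]$ before the logarithm — they are unbounded, and
binary cross-entropy is otherwise undefined. Note a consequence for
zero-initialized weights: the first recorded output is $H\cdot 0 = 0$,
which clips to $10^{-7}$, so the loss trace starts at
$-\log(10^{-7})$ times the positive rate, *not* at $\ln 2$; it drops
toward the $\ln 2$ neighbourhood within the first few iterations as
the outputs move into $(0,1)$. Validation curves are produced by
replaying the solver's iterate history against the held-out fold — the
trace is a matrix, so the whole replay is two matrix products.

## The synthetic generator

No clinical data ships with the package; generators stand in for the
two input kinds.

`make_sfp_instance()` draws a Gaussian $A$, plants
$\omega^*$ at 80% of the constraint radius (strictly interior, so
feasibility checks have slack), and sets $Q$ to the singleton
$\{A\omega^*\}$ or a ball around it. Every instance therefore has a
nonempty solution set and carries its certificate.

`make_classification_table()` emulates the published attribute
overview of the mammographic-mass screening table: five integer-valued
features (BI-RADS 1–6, age 18–96, shape 1–4, margin 1–5, density 1–4)
with printed means/sds as overall marginals, 961 samples, 445
malignant. Class separation is a single knob: class means displaced
symmetrically by `separation` pooled sds along every feature, with
within-class variance shrunk so the *overall* marginal variance is
preserved (possible while $p(1-p)\,\mathrm{sep}^2 < 1$; beyond that the
within-class sd is floored at 20% of the marginal). The default
`separation = 1` yields cross-validated ELM accuracies in the mid-80s —
the regime the published benchmark reports — while `separation = 3`
gives an essentially separable table used by the end-to-end tests, and
`separation = 0` a no-signal control. Integer rounding and range
clipping slightly bias higher moments, so the law-of-large-numbers
checks on means and sds run with `round_integers = FALSE`.

What the generator does **not** emulate: ordinal features are
conditionally independent Gaussians, with none of the correlation
structure (BI-RADS is itself an assessment of the other findings),
missingness mechanism, or label noise of the real table. Passing tests
therefore certify the optimization and evaluation machinery, not
clinical performance; the published accuracy (85.03% for the Mann
algorithm under the L2 ball) depends on the external download, an
unstated cleaning rule and unseeded initialization, and is treated as a
replication note, not a test target (see the README).

The cleaning rule for real CSVs drops rows with missing fields, then
rows with any attribute outside the printed min–max ranges — the only
outlier information the source table provides.

## Problem sizes in the test and acceptance runs

Projection oracle equivalence uses 100 random instances per projection
kind at dimension ≤ 10, checked against an SLSQP solve of the
projection program to $10^{-6}$; operator properties use 1000 random
pairs per projection at $10^{-10}$. Solver properties (fixed point,
Fejér inequality, convergence to residual $10^{-8}$ with feasibility
$c(\omega) \le 10^{-6}$, $\mathrm{dist}(A\omega, Q) \le 10^{-4}$,
(C1) summability) run on twenty seeded $20\times 10$ feasible
instances. The end-to-end classification check uses $n = 400$,
$d = 5$, separation 3, $M = 160$ hidden nodes, 5-fold CV. These sizes
are the package's chosen desk-scale study conditions: large enough
that every property is exercised away from trivial regimes, small
enough that the whole suite runs in well under a minute.

## Known limitations

* Finite-dimensional, dense-matrix setting only; no matrix-free
  operators or infinite-dimensional constructions.
* Weak-convergence theory is exercised as runtime properties (Fejér
  inequality, summability, residual decay), not proved or certified.
* Positive relaxation curvature is only sound for suitably strongly
  convex level functions (above); the solvers do not detect an
  invalid modulus beyond the empty-relaxation error.
* The stopping rule is residual-plus-budget; the published comparison
  reports bare iteration counts whose stopping rule is unstated, so
  iteration counts are not comparable across implementations.
* Single binary output; no multi-class or kernel ELM variants.
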