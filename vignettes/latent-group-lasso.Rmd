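---
title: "Latent group lasso regression by proximal gradient descent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent group lasso regression by proximal gradient descent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overlasso)
```

## The model

`overlasso` fits sparse logistic and Cox proportional-hazards regression
models in which variables are penalized in groups that may overlap.  The
smooth part of the objective is the negative log-likelihood

$$-L(\beta) = -\sum_i \left[ y_i x_i^\top\beta - \log(1 + e^{x_i^\top\beta}) \right]$$

for binary outcomes, or the negative log partial likelihood

$$-L(\beta) = -\sum_i \delta_i \left[ x_i^\top\beta -
  \log \textstyle\sum_{l : y_l \ge y_i} e^{x_l^\top\beta} \right]$$

for right-censored survival outcomes, where $y_i$ is the observed time,
$\delta_i$ the event indicator, and the risk set uses the non-strict
comparison $y_l \ge y_i$ with Breslow's shared denominator for tied event
times.  The partial likelihood eliminates the baseline hazard, so the
package estimates regression coefficients only; survival-curve or
absolute-risk prediction is out of scope.

The penalty is the latent group lasso.  Given a collection $G$ of groups
$g \subseteq \{1,\dots,p\}$, each group receives its own latent
coefficient block $\gamma_g \in \mathbb{R}^{|g|}$, and the observed
coefficients are the sum of the group contributions,
$\beta = A\gamma = \sum_g P_g \gamma_g$, where $P_g$ scatters a block onto
the variables of $g$ and $A = (P_g)_{g \in G}$ is a sparse 0/1 matrix
with exactly one unit entry per column.  The fitted problem is the
unconstrained convex program

$$\min_\gamma \; -L(A\gamma) + \lambda \sum_{g \in G} \sqrt{|g|}\,
  \lVert \gamma_g \rVert_2 ,$$

with weights proportional to the square root of group size.  Because the
latent blocks are disjoint even when the groups overlap, the penalty's
proximal operator separates over blocks, and a zeroed block removes one
group's *contribution* without forcing a shared variable to zero: the
selected support is a union of groups.  With disjoint groups the penalty
reduces to the classical group lasso, and with all-singleton groups to
the plain lasso.

## The solver

The objective is minimized by plain proximal gradient descent with the
constant step $\alpha = 1/M$:

1. pull the loss gradient back to the latent space,
   $\nabla_\gamma = A^\top \nabla(-L)(A\gamma^{(k)})$;
2. take the gradient step $z = \gamma^{(k)} - \alpha \nabla_\gamma$;
3. soft-threshold every block simultaneously,
   $\gamma_g^{(k+1)} = (1 - \alpha\lambda_g / \lVert z_g\rVert_2)_+ z_g$.

Here $M$ bounds the Lipschitz constant of the latent gradient:
$M = \tfrac14 \lVert \tilde X^\top \tilde X \rVert_2$ for logistic and
$M = 2 \lVert \tilde X^\top \tilde X \rVert_2$ for Cox models, with
$\tilde X = XA$ applied as an operator.  The spectral norm is estimated
by power iteration to relative tolerance $10^{-6}$ from a deterministic
start vector, with an iteration cap that errors rather than returning a
doubtful bound.  Any step in $[\varepsilon, 2/M - \varepsilon]$ is
admissible; a user-supplied step outside that interval is rejected.  The
step is held constant across iterations, there is no acceleration, line
search or screening rule, and the initialization is $\gamma^{(0)} = 0$
(or a warm start), which makes the $\lambda_{\max}$ characterization
below exact.

Convergence is declared when the windowed relative change

$$\frac{\lvert F(\gamma^{(k)}) - F(\gamma^{(k-100)}) \rvert}
       {\lvert F(\gamma^{(k)}) \rvert + 1} \le \mathrm{tol}$$

holds; the check runs at every iteration once $k$ reaches the window
(the alternative of checking only every 100th iteration gives the same
floor of one window's worth of iterations and differs only in stopping
granularity).  The defaults are $5\times10^{-4}$ for path and
cross-validation fits and $1\times10^{-5}$ for the final refit, with
window 100.  Hitting the iteration cap is reported through
`converged = FALSE` and a warning rather than an error, so a path fit
can be inspected.  `kkt_residual()` reports per-group stationarity
residuals as an independent diagnostic of solution quality.

Two implementation points matter for scale.  First, the solver operates
only through the original $n \times p$ matrix and the sparse map $A$;
the $n \times \sum|g|$ column-duplicated design that a naive overlapping
implementation builds is never materialized, so the overhead of overlap
is $O(\sum|g|)$ latent coefficients, not $O(n \sum|g|)$ matrix entries.
Second, the Cox loss and gradient are computed with cumulative sums over
the time-sorted sample in $O(n\log n + np)$, with linear predictors
centered by their maximum before exponentiation for overflow safety.

## Penalty grids and model selection

$\lambda_{\max} = \max_g \lVert P_g^\top \nabla(-L)(\beta_0)\rVert_2 /
\sqrt{|g|}$ (over penalized groups, with $\beta_0$ the partial optimum
over any unpenalized variables, or zero when there are none) is the
smallest penalty whose solution keeps every penalized block at zero.
`lambda_grid()` builds descending, equally log-spaced grids between
user-chosen bounds — grid bounds are data- and study-specific, so the
package deliberately has no automatic bound rule; 100 grid points is the
default count.  `fit_path()` fits the grid in decreasing order with warm
starts and records per-penalty sparsity.

`cross_validate()` assigns folds by a seeded permutation stratified by
class label (logistic) or event indicator (Cox), with the fold counter
continuing across strata so that small strata still spread over all
folds and leave-one-out assignment degenerates correctly.  Training
folds without a single event trigger one re-stratification attempt and
then an error.  Held-out performance is the binomial deviance
(logistic; probabilities clipped to $[10^{-12}, 1-10^{-12}]$) or
Harrell's C-index (Cox; comparable pairs $y_i < y_j$ with
$\delta_i = 1$, risk-score ties counting $1/2$).  The selected penalty
is the best mean metric with ties resolved toward the larger (sparser)
penalty; no one-standard-error rule is applied.  The final model is
refitted on all data at the selected penalty at the tighter tolerance.
Given the data, grid, fold count and seed, the whole procedure is
deterministic.

Variables can be excluded from regularization (clinical covariates such
as age or cancer type adjusted "for free").  Such variables are removed
from any penalized group they appear in and handled as zero-weight
singleton latent blocks that receive plain gradient steps.  Variables
appearing in no group become penalized singletons, so the expansion map
always spans all of $\beta$; this completion is this package's choice
for otherwise-unspecified variables.

Column standardization (optional, on by default in the command-line
interface) centers each column and scales by the population standard
deviation (divisor $n$); zero-variance columns are centered only, with a
warning.  Observed variables are standardized individually — there is no
within-group orthonormalization, which behaves poorly when continuous
and count variables are mixed.  Coefficients are reported on both the
standardized and original scales.  The logistic model includes an
optional unpenalized intercept (default on in the CLI), implemented as
an appended constant column; the Cox partial likelihood absorbs any
intercept, so the flag is ignored there.

## The simulation generator

`simulate_dataset()` emulates a controlled overlapping-group design:
$R$ groups of $S$ adjacent variables in which consecutive groups share
$T$ variables, so group $j$ spans indices $(S-T)(j-1)+1$ through
$(S-T)(j-1)+S$ and $p = (R-1)(S-T) + S$.  True coefficients are
$\beta_j = (-1)^j e^{-(j-1)/W}$ — alternating signs with geometric
decay, so $W$ sets the effective sparsity.  Design entries are i.i.d.
standard normal.  Binary outcomes follow the logistic model.  Survival
times are unit exponential with independent unit-exponential censoring,
which censors half the sample in expectation; note this default carries
*no covariate effect*, so Cox fits cannot recover $\beta$ from it.  A
flagged `cox_mode = "proportional"` extension draws
$t_i \sim \mathrm{Exp}(e^{x_i^\top\beta})$ for recovery experiments.
One root seed feeds deterministic per-generator sub-seeds, so adding a
generator never perturbs the others.

What the generator does *not* emulate: correlated designs (LD blocks,
co-expression), heavy-tailed or count-valued covariates, group sizes
that vary within a run, informative censoring, and case-control
imbalance.  Tests passing on this generator therefore establish
correctness of the optimization and selection machinery, not robustness
to those features of real omics data.

## Numerical choices and test problem sizes

Default tolerances and the window follow the convergence criterion
above.  Degenerate inputs are rejected up front: all-censored survival
outcomes, non-binary labels, nonpositive times, out-of-range or
duplicated group memberships.  A zero design matrix is an error (no
finite step exists).  Ties in the selection metric go to the larger
penalty; block norms at zero are handled without dividing by zero.

The test suite validates the solver against independent oracles — finite
differences for gradients, `glm`/`coxph` for unpenalized fits, a
block-coordinate proximal routine for non-overlapping group problems,
and coordinate-descent lasso in the all-singleton limit — on problems of
a few hundred samples and tens of variables, where those oracles are
exact and fast.  The scalability check runs a full 100-penalty
warm-started logistic path at $n = 500$, $p = 19\,990$ (222 overlapping
groups of 100), a size chosen so the whole suite completes on a single
CPU in minutes while still exercising the operator-based memory layout;
parameter-recovery checks use $R = 10$, $S = 20$, $T = 2$, $W = 10$,
$n = 500$ over ten seeds.

## Known limitations

Plain PGD takes at least one convergence window of iterations per
penalty and converges linearly at best; FISTA-style acceleration,
screening rules, and stochastic gradients are deliberately absent.
For Cox models the step bound $2\lVert X^\top X\rVert_2$ is loose
relative to the true partial-likelihood curvature, so the windowed
objective criterion at $10^{-5}$ typically stops while per-group
stationarity residuals (on the sum-scale gradient) are still of order
$10^{-2}$; `kkt_residual()` makes this visible, and tightening the
tolerance shrinks the residual roughly proportionally.  Logistic
models, whose bound $\tfrac14\lVert X^\top X\rVert_2$ is nearly sharp,
reach residuals below $10^{-6}$ at the same tolerance.
Nonconvex group penalties (MCP, SCAD), Efron tie handling, stratified
Cox models, baseline-hazard estimation and within-group orthonormal
standardization are out of scope.  The command-line reader loads dense
matrices into memory; MatrixMarket input stays sparse, but requesting
standardization densifies it.
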