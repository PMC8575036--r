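# overlasso

Latent (overlapping) group lasso regression for high-dimensional
biomedical data, fitted by proximal gradient descent.

## The problem

Omics platforms report many variables that jointly describe one
biological entity — the SNPs under a linkage block, the probes along a
gene's regulatory regions, the genes of a pathway — and a variable often
belongs to several such groups at once.  When a sparse multivariable
model is wanted, the penalty should respect that structure: variables in
the same group should enter or leave the model together, and a variable
shared by two groups should be allowed in through either.

The classical group lasso handles disjoint groups only; applied naively
to overlapping groups it selects *complements* of group unions (a gene
shared with an unselected pathway is forced to zero).  The latent group
lasso fixes this by decomposing the coefficient vector as a sum of
group-supported latent components and penalizing those:

    minimize over gamma:   -L(A gamma) + lambda * sum_g sqrt(|g|) * ||gamma_g||_2

where `L` is the log-likelihood of a logistic model or the log partial
likelihood of a Cox proportional-hazards model, `gamma_g` is a latent
coefficient block for group `g`, and `A = (P_g)` is the sparse 0/1 map
with `beta = A gamma = sum_g P_g gamma_g`.  Selected models are unions
of groups, which is the interpretable behavior one wants from biological
priors.

Because the latent blocks do not overlap, proximal gradient descent
(PGD) applies directly: a gradient step on the smooth loss pulled back
through `A`, followed by closed-form block soft-thresholding of every
group simultaneously.  Crucially the solver only ever touches the
original `n x p` design matrix and the sparse map `A` — the
column-duplicated `n x sum|g|` matrix that makes naive overlapping-group
implementations run out of memory is never formed.

## What is in the package

* `group_structure()`, `expand_coefficients()`, `collapse_vector()`,
  `group_weights()` — overlapping groups and the latent expansion map,
  with size-proportional weights `lambda_g = lambda * sqrt(|g|)` and
  support for variables excluded from regularization.
* `logistic_data()` / `cox_data()`, `logistic_loss_grad()` /
  `cox_loss_grad()`, `lipschitz_constant()` — the two losses with
  `O(n log n + np)` Cox evaluation (Breslow ties) and the step-size
  bounds `M = ||X'X||_2 / 4` (logistic) and `2 ||X'X||_2` (Cox)
  estimated by power iteration through the operators.
* `fit_pgd()`, `kkt_residual()`, `lambda_max()` — the solver with the
  windowed convergence criterion
  `|F(k) - F(k-100)| / (|F(k)| + 1) <= tol` and stationarity
  diagnostics.
* `lambda_grid()`, `fit_path()`, `cross_validate()`,
  `harrell_c_index()`, `binomial_deviance()` — log-spaced grids,
  warm-started paths, stratified k-fold cross-validation scored by
  binomial deviance (logistic) or Harrell's C-index (Cox).
* `simulate_dataset()` and friends — the overlapping adjacent-group
  simulation design parameterized by `(R, S, T, W)`.
* `read_design_matrix()`, `read_outcome()`, `standardize_columns()`,
  `write_fit()` / `write_path()`, `cli_main()` — TSV/CSV/MatrixMarket
  input, id-joined outcome alignment, population-sd standardization and
  a `simulate` / `fit` / `cv` command line (`inst/cli/overlasso`).

## Worked example

Simulate a logistic dataset with 10 overlapping groups of 20 adjacent
variables (overlap 2, so p = 182), cross-validate a 20-value penalty
grid, and compare the selected fit with the generating coefficients:

```r
library(overlasso)

sim <- simulate_dataset(R = 10, S = 20, T = 2, W = 10, n = 500,
                        model = "logistic", seed = 1)
ds <- sim$dataset; gs <- sim$gs
print(gs)
#> Group structure: 182 variables, 10 groups (10 penalized), latent dimension 200
#>   overlap: 18 duplicated latent coordinates

lmx <- lambda_max(ds, gs)          # 36.94: smallest all-zero penalty
cv <- cross_validate(ds, gs, lambda_grid(lmx, 0.02 * lmx, 20),
                     k = 5, seed = 1)
print(cv)
#> Regularization path: 20 lambdas in [0.738806, 36.9403]
#>   selected lambda = 5.79062 (deviance)
print(cv$final_fit)
#> PGD fit: lambda = 5.79062, 101 iterations, converged, objective 251.491,
#>   166 nonzero coefficients

b <- cv$final_fit$beta
sum(b * sim$true_beta) / sqrt(sum(b^2) * sum(sim$true_beta^2))
#> [1] 0.933
```

The cross-validation table (`cv$cv_table`) records, per penalty, the
mean and standard error of the held-out deviance and the number of
selected groups and variables; at the largest penalty nothing is
selected, and the model densifies as the penalty decreases.  The cosine
similarity of 0.93 between the fitted and generating coefficients shows
the selected model recovering the simulated signal.

The same analysis from the shell:

```sh
Rscript inst/cli/overlasso simulate --model logistic --R 10 --S 20 --T 2 \
    --W 10 --n 500 --seed 1 --out sim
Rscript inst/cli/overlasso cv --model logistic --matrix sim_X.tsv \
    --outcome sim_outcome.tsv --groups sim_groups.tsv \
    --lambda-max 37 --lambda-min 0.7 --n-lambda 20 --folds 5 --seed 1 \
    --out fit
```

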