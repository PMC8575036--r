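# Independent oracles used to check the solver and losses.

# Central finite-difference gradient of a scalar function.
fd_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# Central finite-difference Jacobian of a vector-valued function
# (columns indexed by the perturbed coordinate).
fd_grad_matrix <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(j) {
    e <- numeric(length(x)); e[j] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(length(f(x))))
}

# Naive Cox negative log partial likelihood (risk sets by explicit
# comparison, Breslow ties); quadratic in n, test-scale only.
naive_cox_loss <- function(X, time, status, beta) {
  eta <- as.vector(X %*% beta)
  s <- 0
  for (i in seq_along(time)) {
    if (status[i] == 1) {
      s <- s + log(sum(exp(eta[time >= time[i]]))) - eta[i]
    }
  }
  s
}

# Block coordinate proximal-gradient oracle for the latent group lasso
# objective: cycles through the groups, taking one prox-gradient step per
# block with the block-specific step 1/M_g, until the objective stalls.
# A different algorithm and update order than the simultaneous PGD sweep,
# converging to the same minimum of the convex objective.
bcd_oracle <- function(ds, gs, pen, max_sweeps = 5000, tol = 1e-12) {
  cfac <- if (inherits(ds, "logistic_data")) 0.25 else 2
  d <- gs$latent_dim
  gamma <- numeric(d)
  idx <- split(seq_len(d), gs$block)
  vars <- gs$groups
  step <- vapply(seq_along(vars), function(g) {
    Xg <- as.matrix(ds$X[, vars[[g]], drop = FALSE])
    1 / (cfac * norm(Xg, "2")^2)
  }, numeric(1))
  obj <- function(g) objective_value(ds, gs, pen, g)
  f_old <- obj(gamma)
  for (s in seq_len(max_sweeps)) {
    for (g in seq_along(idx)) {
      beta <- expand_coefficients(gs, gamma)
      grad_g <- .loss_grad_oracle(ds, beta)[vars[[g]]]
      z <- gamma[idx[[g]]] - step[g] * grad_g
      gamma[idx[[g]]] <- prox_block_l2(z, step[g] * pen$weights[g])
    }
    f_new <- obj(gamma)
    if (abs(f_old - f_new) <= tol * (abs(f_new) + 1)) break
    f_old <- f_new
  }
  list(gamma = gamma, objective = f_new)
}

# Loss gradient for the oracle, written independently of the package's
# cumulative-sum path (direct formulas, O(n^2) for Cox).
.loss_grad_oracle <- function(ds, beta) {
  eta <- as.vector(ds$X %*% beta)
  if (inherits(ds, "logistic_data")) {
    return(as.vector(crossprod(as.matrix(ds$X), plogis(eta) - ds$y)))
  }
  w <- exp(eta)
  n <- ds$n
  r <- numeric(n)
  for (j in seq_len(n)) {
    r[j] <- w[j] * sum(ds$status * (ds$time[j] >= ds$time) /
                         vapply(seq_len(n), function(i)
                           sum(w[ds$time >= ds$time[i]]), numeric(1))) -
      ds$status[j]
  }
  as.vector(crossprod(as.matrix(ds$X), r))
}

# Exhaustive-pair concordance oracle.
brute_c_index <- function(time, status, risk) {
  conc <- 0; comp <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (time[i] < time[j] && status[i] == 1) {
      comp <- comp + 1
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] == risk[j]) conc <- conc + 0.5
    }
  }
  conc / comp
}

# Small random instances shared across tests.
random_logistic <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n)
  beta <- rnorm(p) / 2
  y <- rbinom(n, 1, plogis(as.vector(X %*% beta)))
  if (all(y == y[1])) y[1] <- 1 - y[1]
  logistic_data(X, y)
}

random_cox <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n)
  time <- rexp(n)
  status <- rbinom(n, 1, 0.7)
  if (!any(status == 1)) status[1] <- 1
  cox_data(X, time, status)
}
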