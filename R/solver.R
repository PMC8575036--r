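#' Block soft-thresholding (proximal operator of the group-l2 norm)
#'
#' Shrinks the Euclidean norm of a block by `threshold`, returning the
#' zero vector when the norm does not exceed the threshold:
#' `(1 - t/||z||_2) * z` if `||z||_2 > t`, else `0`.
#'
#' @param z numeric block vector.
#' @param threshold nonnegative scalar `t`.
#' @return the shrunken block vector.
#' @export
#' @examples
#' prox_block_l2(c(3, 4), 2.5)  # norm 5, factor 0.5 -> c(1.5, 2)
prox_block_l2 <- function(z, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0) {
    stop("`threshold` must be a single nonnegative number", call. = FALSE)
  }
  if (threshold == 0) return(z)
  nz <- sqrt(sum(z * z))
  if (nz > threshold) (1 - threshold / nz) * z else rep(0, length(z))
}

#' Solver options for proximal gradient descent
#'
#' @param step_size step `alpha`; `NULL` (default) means `1/M` with `M`
#'   the Lipschitz constant of the latent gradient.  A supplied value must
#'   lie in the admissible interval `[epsilon, 2/M - epsilon]`.
#' @param tol relative-change tolerance of the windowed convergence
#'   criterion `|F(k) - F(k - window)| / (|F(k)| + 1) <= tol`.
#' @param window iteration lag of the convergence check (checked at every
#'   iteration once `k >= window`).
#' @param max_iter iteration cap; exhaustion sets `converged = FALSE` with
#'   a warning rather than an error.
#' @param epsilon safety margin of the admissible step interval; `NULL`
#'   picks `min(1, 1/M) / 2`.
#' @return a list of class `"solver_options"`.
#' @export
solver_options <- function(step_size = NULL, tol = 1e-5, window = 100L,
                           max_iter = 50000L, epsilon = NULL) {
  if (!is.null(step_size) &&
      (!is.numeric(step_size) || length(step_size) != 1L || step_size <= 0)) {
    stop("`step_size` must be a positive scalar or NULL", call. = FALSE)
  }
  if (!is.numeric(tol) || length(tol) != 1L || tol <= 0) {
    stop("`tol` must be positive", call. = FALSE)
  }
  if (!is.numeric(window) || length(window) != 1L || window < 1) {
    stop("`window` must be >= 1", call. = FALSE)
  }
  if (!is.numeric(max_iter) || length(max_iter) != 1L || max_iter < 1) {
    stop("`max_iter` must be >= 1", call. = FALSE)
  }
  structure(list(step_size = step_size, tol = tol,
                 window = as.integer(window),
                 max_iter = as.integer(max_iter), epsilon = epsilon),
            class = "solver_options")
}

#' Latent objective value
#'
#' Evaluates `F(gamma) = loss(A gamma) + sum_g lambda_g ||gamma_g||_2`.
#'
#' @param ds a [logistic_data()] or [cox_data()] object.
#' @param gs a [group_structure()]; `NULL` takes the one in `pen`.
#' @param pen a [group_weights()] penalty specification.
#' @param gamma latent coefficient vector.
#' @return scalar objective value.
#' @export
objective_value <- function(ds, gs = NULL, pen, gamma) {
  gs <- gs %||% pen$gs
  .check_pen(gs, pen)
  beta <- expand_coefficients(gs, gamma)
  loss <- .loss_grad(ds, beta)$loss
  loss + sum(pen$weights * .block_norms(gs, gamma))
}

.check_pen <- function(gs, pen) {
  stopifnot(inherits(gs, "group_structure"), inherits(pen, "penalty_spec"))
  if (length(pen$weights) != length(gs$groups)) {
    stop("penalty weights do not match the group structure; use the `gs` returned inside the penalty spec",
         call. = FALSE)
  }
}

#' Fit by proximal gradient descent
#'
#' Minimizes the latent objective
#' `F(gamma) = loss(A gamma) + lambda * sum_g sqrt(|g|) ||gamma_g||_2`
#' by iterating a gradient step on the smooth loss followed by
#' simultaneous block soft-thresholding of every group:
#' `z = gamma - alpha * t(A) grad(loss)(A gamma)`, then
#' `gamma_g <- prox_block_l2(z_g, alpha * lambda_g)`.
#'
#' Iteration stops when the windowed relative change of the objective
#' falls below `opts$tol` (see [solver_options()]) or at `opts$max_iter`
#' with `converged = FALSE`.
#'
#' @param ds a [logistic_data()] or [cox_data()] object.
#' @param gs a [group_structure()]; `NULL` takes the one carried by `pen`.
#' @param pen a [group_weights()] penalty specification.
#' @param opts a [solver_options()] list.
#' @param gamma0 optional warm-start latent vector; default zero.
#' @param M optional precomputed [lipschitz_constant()]; path and
#'   cross-validation code computes it once per dataset and passes it down
#'   rather than rerunning the power iteration at every penalty.
#' @return an object of class `"pgd_fit"`: `gamma`, `beta`
#'   (`= A gamma`), `objective_trace` (per-iteration `F`), `n_iter`,
#'   `converged`, `lambda`, `step_size`.
#' @export
fit_pgd <- function(ds, gs = NULL, pen, opts = solver_options(),
                    gamma0 = NULL, M = NULL) {
  stopifnot(inherits(ds, "pgd_data"), inherits(opts, "solver_options"))
  gs <- gs %||% pen$gs
  .check_pen(gs, pen)
  if (ds$p != gs$p) {
    stop(sprintf("data has %d variables but group structure covers %d",
                 ds$p, gs$p), call. = FALSE)
  }
  d <- gs$latent_dim
  gamma <- gamma0 %||% numeric(d)
  if (length(gamma) != d) {
    stop("`gamma0` length must equal the latent dimension", call. = FALSE)
  }

  M <- M %||% lipschitz_constant(ds, gs)
  if (M <= 0) stop("design matrix is identically zero", call. = FALSE)
  alpha <- opts$step_size %||% (1 / M)
  eps <- opts$epsilon %||% (min(1, 1 / M) / 2)
  if (alpha < eps - 1e-12 || alpha > 2 / M - eps + 1e-12) {
    stop(sprintf("step size %g outside admissible interval [%g, %g]",
                 alpha, eps, 2 / M - eps), call. = FALSE)
  }

  thr <- alpha * pen$weights          # per-group prox thresholds
  block <- gs$block
  trace <- numeric(opts$max_iter)
  converged <- FALSE
  k <- 0L
  # penalty term of the current iterate; after a prox step the block norms
  # are available in closed form (zn - thr, floored at 0), so only the
  # warm start needs an explicit block-norm pass
  pen_term <- sum(pen$weights * .block_norms(gs, gamma))

  repeat {
    k <- k + 1L
    beta <- as.vector(gs$A %*% gamma)
    lg <- .loss_grad(ds, beta)
    f <- lg$loss + pen_term
    if (!is.finite(f)) {
      stop(sprintf("objective diverged (non-finite) at iteration %d", k),
           call. = FALSE)
    }
    trace[k] <- f
    if (k > opts$window &&
        abs(trace[k] - trace[k - opts$window]) / (abs(trace[k]) + 1) <=
          opts$tol) {
      converged <- TRUE
      break
    }
    if (k >= opts$max_iter) break

    z <- gamma - alpha * as.vector(Matrix::crossprod(gs$A, lg$grad))
    zn <- .block_norms(gs, z)
    gn <- ifelse(thr == 0, zn, pmax(zn - thr, 0))
    # shrinkage via the difference form so a block exactly at the
    # threshold (lambda == lambda_max) zeroes out exactly
    fac <- ifelse(thr == 0, 1, gn / pmax(zn, .Machine$double.xmin))
    gamma <- z * fac[block]
    pen_term <- sum(pen$weights * gn)
  }

  if (!converged) {
    warning(sprintf("proximal gradient descent hit max_iter = %d without meeting the convergence criterion",
                    opts$max_iter), call. = FALSE)
  }
  structure(list(gamma = gamma,
                 beta = expand_coefficients(gs, gamma),
                 objective_trace = trace[seq_len(k)],
                 n_iter = k, converged = converged,
                 lambda = pen$lambda, step_size = alpha),
            class = "pgd_fit")
}

#' @export
print.pgd_fit <- function(x, ...) {
  cat(sprintf(
    "PGD fit: lambda = %g, %d iterations, %s, objective %.6g, %d nonzero coefficients\n",
    x$lambda, x$n_iter,
    if (x$converged) "converged" else "NOT converged",
    x$objective_trace[x$n_iter], sum(x$beta != 0)))
  invisible(x)
}

#' Karush-Kuhn-Tucker stationarity residuals
#'
#' Per-group diagnostic of how far `gamma` is from satisfying the
#' first-order optimality conditions of the latent objective: for a zero
#' block, `max(0, ||grad_g||_2 - lambda_g)`; for a nonzero block,
#' `||grad_g + lambda_g * gamma_g / ||gamma_g||_2||_2`, where
#' `grad_g = t(P_g) grad(loss)(A gamma)`.
#'
#' @inheritParams objective_value
#' @return numeric vector of residuals, one per group.
#' @export
kkt_residual <- function(ds, gs = NULL, pen, gamma) {
  gs <- gs %||% pen$gs
  .check_pen(gs, pen)
  beta <- expand_coefficients(gs, gamma)
  grad <- as.vector(Matrix::crossprod(gs$A, .loss_grad(ds, beta)$grad))
  gn <- .block_norms(gs, gamma)
  nonzero <- gn > 0
  scale <- ifelse(nonzero, pen$weights / pmax(gn, .Machine$double.xmin), 0)
  v <- grad + scale[gs$block] * gamma
  vn <- .block_norms(gs, v)
  grad_n <- .block_norms(gs, grad)
  ifelse(nonzero, vn, pmax(0, grad_n - pen$weights))
}

#' Smallest penalty that zeroes all penalized groups
#'
#' With the zero start, the prox threshold dominates the gradient of the
#' loss at `gamma = 0` as soon as
#' `lambda >= max_g ||t(P_g) grad(loss)(0)||_2 / sqrt(|g|)` over penalized
#' groups, so the fitted model keeps every penalized block at zero.  If
#' unpenalized groups are present, the gradient is evaluated at their
#' (unregularized) partial optimum obtained by a preliminary fit with all
#' penalized blocks pinned at zero; with no unpenalized variables this is
#' simply the gradient at zero.
#'
#' @param ds a [logistic_data()] or [cox_data()] object.
#' @param gs a [group_structure()].
#' @return scalar `lambda_max`.
#' @export
lambda_max <- function(ds, gs) {
  stopifnot(inherits(ds, "pgd_data"), inherits(gs, "group_structure"))
  beta0 <- numeric(ds$p)
  if (any(!gs$penalized)) {
    # profile out the unpenalized block first (large lambda limit)
    pen_inf <- group_weights(gs, 0)
    gs_unpen_vars <- unlist(gs$groups[!gs$penalized], use.names = FALSE)
    Xu <- ds$X[, gs_unpen_vars, drop = FALSE]
    dsu <- if (inherits(ds, "logistic_data")) logistic_data(Xu, ds$y)
           else cox_data(Xu, ds$time, ds$status)
    gsu <- group_structure(
      data.frame(variable = seq_along(gs_unpen_vars), group = "u"),
      length(gs_unpen_vars))
    fit <- fit_pgd(dsu, gsu, group_weights(gsu, 0),
                   solver_options(tol = 1e-8))
    beta0[gs_unpen_vars] <- fit$beta
  }
  grad <- collapse_vector(gs, .loss_grad(ds, beta0)$grad)
  bn <- .block_norms(gs, grad)
  max(bn[gs$penalized] / sqrt(gs$sizes[gs$penalized]))
}
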