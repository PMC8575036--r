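#' Log-spaced penalty grid
#'
#' `n_lambda` values equally spaced in log10 between `lambda_max` and
#' `lambda_min`, in decreasing order.
#'
#' @param lambda_max largest penalty (first grid point).
#' @param lambda_min smallest penalty (last grid point); must be positive
#'   and below `lambda_max`.
#' @param n_lambda number of grid points (default 100).
#' @return decreasing numeric vector of length `n_lambda`.
#' @export
lambda_grid <- function(lambda_max, lambda_min, n_lambda = 100L) {
  if (!is.numeric(lambda_max) || !is.numeric(lambda_min) ||
      length(lambda_max) != 1L || length(lambda_min) != 1L ||
      !(lambda_max > lambda_min) || lambda_min <= 0) {
    stop("need lambda_max > lambda_min > 0", call. = FALSE)
  }
  if (!is.numeric(n_lambda) || length(n_lambda) != 1L || n_lambda < 2) {
    stop("`n_lambda` must be >= 2", call. = FALSE)
  }
  10^seq(log10(lambda_max), log10(lambda_min), length.out = n_lambda)
}

#' Warm-started regularization path
#'
#' Fits the model at every penalty in `lambdas` in decreasing order,
#' warm-starting each fit from the previous solution, and records per-step
#' sparsity (number of penalized groups with a nonzero latent block, and
#' number of variables with a nonzero collapsed coefficient).
#'
#' @param ds a [logistic_data()] or [cox_data()] object.
#' @param gs a [group_structure()].
#' @param lambdas decreasing positive penalty sequence (see
#'   [lambda_grid()]); an unsorted vector is sorted decreasingly.
#' @param opts [solver_options()] used for every fit; the default
#'   tolerance 5e-4 is the path/cross-validation tolerance.
#' @param unpenalized optional variable indices excluded from
#'   regularization (merged into `gs`).
#' @return an object of class `"og_path"`: `lambdas`, `fits` (list of
#'   [fit_pgd()] results), `n_groups_selected`, `n_nonzero`, `gs` (the
#'   group structure actually used).
#' @export
fit_path <- function(ds, gs, lambdas, opts = solver_options(tol = 5e-4),
                     unpenalized = integer()) {
  stopifnot(inherits(ds, "pgd_data"), inherits(gs, "group_structure"))
  if (!is.numeric(lambdas) || length(lambdas) < 1L || any(lambdas <= 0)) {
    stop("`lambdas` must be positive", call. = FALSE)
  }
  lambdas <- sort(unique(lambdas), decreasing = TRUE)
  pen1 <- group_weights(gs, lambdas[1L], unpenalized = unpenalized)
  gs <- pen1$gs
  M <- lipschitz_constant(ds, gs)   # shared by every fit on this dataset

  fits <- vector("list", length(lambdas))
  ngrp <- integer(length(lambdas))
  nvar <- integer(length(lambdas))
  gamma <- NULL
  for (i in seq_along(lambdas)) {
    pen <- if (i == 1L) pen1 else group_weights(gs, lambdas[i])
    fit <- fit_pgd(ds, gs, pen, opts, gamma0 = gamma, M = M)
    gamma <- fit$gamma
    bn <- .block_norms(gs, gamma)
    ngrp[i] <- sum(bn > 0 & gs$penalized)
    nvar[i] <- sum(fit$beta != 0)
    fits[[i]] <- fit
  }
  structure(list(lambdas = lambdas, fits = fits,
                 n_groups_selected = ngrp, n_nonzero = nvar,
                 gs = gs, M = M, cv_table = NULL, selected_lambda = NULL,
                 final_fit = NULL),
            class = "og_path")
}

#' @export
print.og_path <- function(x, ...) {
  cat(sprintf("Regularization path: %d lambdas in [%g, %g]\n",
              length(x$lambdas), min(x$lambdas), max(x$lambdas)))
  if (!is.null(x$selected_lambda)) {
    cat(sprintf("  selected lambda = %g (%s)\n", x$selected_lambda,
                attr(x$cv_table, "metric")))
  }
  invisible(x)
}

#' Stratified k-fold cross-validation over a penalty grid
#'
#' Assigns folds by a seeded permutation stratified by the class label
#' (logistic) or the event indicator (Cox), fits a warm-started path on
#' each training portion at the cross-validation tolerance, scores the
#' held-out portion with binomial deviance (logistic, lower is better) or
#' Harrell's C-index (Cox, higher is better), picks the penalty with the
#' best mean metric (ties go to the larger, sparser penalty), and refits
#' on the full data at that penalty at the tighter final tolerance.
#'
#' @inheritParams fit_path
#' @param k number of folds (default 10); every Cox training fold must
#'   retain at least one event.
#' @param metric `"deviance"` or `"cindex"`; default chosen by model.
#' @param seed integer seed for the fold permutation.
#' @param opts_cv solver options for the per-fold path fits.
#' @param opts_final solver options for the final full-data fit.
#' @return an `"og_path"` (full-data path) with `cv_table` (data frame:
#'   `lambda`, `metric_mean`, `metric_se`, `n_groups_selected`,
#'   `n_nonzero`), `selected_lambda` and `final_fit` filled in.
#' @export
cross_validate <- function(ds, gs, lambdas, k = 10L, metric = NULL,
                           seed = 1L,
                           opts_cv = solver_options(tol = 5e-4),
                           opts_final = solver_options(tol = 1e-5),
                           unpenalized = integer()) {
  stopifnot(inherits(ds, "pgd_data"))
  if (!is.numeric(k) || length(k) != 1L || k < 2 || k > ds$n) {
    stop("`k` must be between 2 and n", call. = FALSE)
  }
  k <- as.integer(k)
  is_logit <- inherits(ds, "logistic_data")
  metric <- metric %||% (if (is_logit) "deviance" else "cindex")
  metric <- match.arg(metric, c("deviance", "cindex"))
  if (metric == "cindex" && is_logit) {
    stop("the C-index metric applies to Cox models", call. = FALSE)
  }

  strata <- if (is_logit) ds$y else ds$status
  folds <- .make_folds(strata, k, seed)
  if (!is_logit) {
    ok <- vapply(seq_len(k), function(f) any(ds$status[folds != f] == 1),
                 logical(1))
    if (!all(ok)) {           # re-stratification attempt, then error
      folds <- .make_folds(strata, k, seed + 1L)
      ok <- vapply(seq_len(k), function(f) any(ds$status[folds != f] == 1),
                   logical(1))
      if (!all(ok)) {
        stop("could not assign folds so that every training fold retains an event",
             call. = FALSE)
      }
    }
  }

  path <- fit_path(ds, gs, lambdas, opts = opts_cv,
                   unpenalized = unpenalized)
  gs <- path$gs
  lambdas <- path$lambdas
  nl <- length(lambdas)

  scores <- matrix(NA_real_, nrow = k, ncol = nl)
  for (f in seq_len(k)) {
    train <- .subset_data(ds, folds != f)
    test_idx <- which(folds == f)
    test_X <- ds$X[test_idx, , drop = FALSE]
    fold_path <- fit_path(train, gs, lambdas, opts = opts_cv)
    for (i in seq_len(nl)) {
      eta <- as.vector(test_X %*% fold_path$fits[[i]]$beta)
      scores[f, i] <- if (is_logit) {
        binomial_deviance(ds$y[test_idx], plogis(eta))
      } else {
        harrell_c_index(ds$time[test_idx], ds$status[test_idx], eta)
      }
    }
  }

  mean_m <- colMeans(scores)
  se_m <- apply(scores, 2, sd) / sqrt(k)
  best <- if (metric == "deviance") {
    which(mean_m == min(mean_m))[1L]   # first = largest lambda on ties
  } else {
    which(mean_m == max(mean_m))[1L]
  }

  pen_best <- group_weights(gs, lambdas[best])
  final <- fit_pgd(ds, gs, pen_best, opts_final,
                   gamma0 = path$fits[[best]]$gamma, M = path$M)

  cv_table <- data.frame(lambda = lambdas,
                         metric_mean = mean_m,
                         metric_se = se_m,
                         n_groups_selected = path$n_groups_selected,
                         n_nonzero = path$n_nonzero)
  attr(cv_table, "metric") <- metric
  path$cv_table <- cv_table
  path$selected_lambda <- lambdas[best]
  path$final_fit <- final
  path$folds <- folds
  path
}

# Stratified fold assignment by seeded permutation; the fold counter
# continues across strata so small strata still spread over all folds.
.make_folds <- function(strata, k, seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
  folds <- integer(length(strata))
  counter <- 0L
  for (s in unique(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- (counter + seq_along(idx) - 1L) %% k + 1L
    counter <- counter + length(idx)
  }
  folds
}

#' Harrell's concordance index
#'
#' Fraction of comparable pairs whose predicted risk ordering agrees with
#' the observed survival ordering.  A pair `(i, j)` is comparable when
#' `time_i < time_j` and subject `i` had an event; it is concordant when
#' `risk_i > risk_j` (higher risk, earlier event), and risk-score ties
#' count 1/2.
#'
#' @param time observed times.
#' @param status event indicators (1 = event).
#' @param risk predicted risk scores (e.g. the linear predictor).
#' @return scalar in \[0, 1\].
#' @export
harrell_c_index <- function(time, status, risk) {
  n <- length(time)
  if (length(status) != n || length(risk) != n) {
    stop("`time`, `status` and `risk` must have equal length", call. = FALSE)
  }
  conc <- 0
  comp <- 0
  for (i in which(status == 1)) {
    later <- time > time[i]
    m <- sum(later)
    if (m == 0) next
    comp <- comp + m
    conc <- conc + sum(risk[i] > risk[later]) + 0.5 * sum(risk[i] == risk[later])
  }
  if (comp == 0) {
    stop("no comparable pairs; the C-index is undefined", call. = FALSE)
  }
  conc / comp
}

#' Binomial deviance
#'
#' `-2 * sum(y * log(p) + (1 - y) * log(1 - p))` with probabilities
#' clipped to `[1e-12, 1 - 1e-12]`.
#'
#' @param y binary labels.
#' @param prob predicted class-1 probabilities.
#' @return scalar deviance.
#' @export
binomial_deviance <- function(y, prob) {
  if (length(y) != length(prob)) {
    stop("`y` and `prob` must have equal length", call. = FALSE)
  }
  prob <- pmin(pmax(prob, 1e-12), 1 - 1e-12)
  -2 * sum(y * log(prob) + (1 - y) * log1p(-prob))
}
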