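#' Model data containers
#'
#' `logistic_data()` wraps a design matrix and binary labels;
#' `cox_data()` wraps a design matrix with right-censored survival
#' outcomes (observed time `y_i = min(t_i, c_i) > 0` and event indicator
#' `delta_i = 1{t_i <= c_i}`).  The matrix may be a base matrix or any
#' `Matrix` sparse matrix; it is stored as given and never duplicated.
#'
#' @param X numeric `n x p` design matrix (dense or sparse).
#' @param y binary labels in \{0, 1\}, length `n`.
#' @return an object of class `c("logistic_data", "pgd_data")` or
#'   `c("cox_data", "pgd_data")`.
#' @export
logistic_data <- function(X, y) {
  X <- .check_design(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) {
    stop("length of `y` must equal nrow(X)", call. = FALSE)
  }
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("labels must be 0/1 with no missing values", call. = FALSE)
  }
  structure(list(X = X, y = y, n = nrow(X), p = ncol(X)),
            class = c("logistic_data", "pgd_data"))
}

#' @rdname logistic_data
#' @param time observed times, strictly positive, length `n`.
#' @param status event indicators in \{0, 1\} (1 = event, 0 = censored);
#'   at least one event is required.
#' @export
cox_data <- function(X, time, status) {
  X <- .check_design(X)
  time <- as.numeric(time)
  status <- as.numeric(status)
  if (length(time) != nrow(X) || length(status) != nrow(X)) {
    stop("`time` and `status` must have length nrow(X)", call. = FALSE)
  }
  if (anyNA(time) || any(time <= 0)) {
    stop("survival times must be strictly positive", call. = FALSE)
  }
  if (anyNA(status) || !all(status %in% c(0, 1))) {
    stop("`status` must be 0/1 with no missing values", call. = FALSE)
  }
  if (!any(status == 1)) {
    stop("all observations are censored; at least one event is required",
         call. = FALSE)
  }
  ord <- order(time)  # ascending; risk sets use non-strict >= (Breslow ties)
  r <- rle(time[ord])
  ends <- cumsum(r$lengths)
  structure(list(X = X, time = time, status = status,
                 n = nrow(X), p = ncol(X),
                 ord = ord,
                 tie_first = rep.int(ends - r$lengths + 1L, r$lengths),
                 tie_last = rep.int(ends, r$lengths)),
            class = c("cox_data", "pgd_data"))
}

.check_design <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!(is.matrix(X) || is(X, "Matrix"))) {
    stop("`X` must be a matrix", call. = FALSE)
  }
  if (nrow(X) < 2L || ncol(X) < 1L) {
    stop("`X` must have n >= 2 rows and p >= 1 columns", call. = FALSE)
  }
  if (is.matrix(X) && anyNA(X)) stop("`X` contains missing values",
                                     call. = FALSE)
  X
}

# Subset samples (used by cross-validation folds).
.subset_data <- function(ds, idx) {
  if (inherits(ds, "logistic_data")) {
    logistic_data(ds$X[idx, , drop = FALSE], ds$y[idx])
  } else {
    cox_data(ds$X[idx, , drop = FALSE], ds$time[idx], ds$status[idx])
  }
}

#' Loss and gradient of the negative log-(partial-)likelihood
#'
#' `logistic_loss_grad()` evaluates the logistic negative log-likelihood
#' `-sum(y * eta - log(1 + exp(eta)))` with `eta = X beta`, using a
#' numerically stable log1p formulation, and its gradient
#' `t(X) %*% (plogis(eta) - y)`.
#'
#' `cox_loss_grad()` evaluates the negative log partial likelihood
#' `-sum(delta_i * (eta_i - log(sum_{l: y_l >= y_i} exp(eta_l))))` under
#' the Breslow convention for ties (non-strict risk sets with a shared
#' denominator), and its gradient, in `O(n log n + n p)` via cumulative
#' sums over the time-sorted sample; the `n x n` risk-set matrix is never
#' formed.
#'
#' @param ds a [logistic_data()] or [cox_data()] object.
#' @param beta numeric coefficient vector of length `ds$p`.
#' @return a list with elements `loss` (scalar) and `grad` (length-`p`
#'   vector); the gradient is of the minimized negative log-likelihood.
#' @export
logistic_loss_grad <- function(ds, beta) {
  stopifnot(inherits(ds, "logistic_data"))
  eta <- .linpred(ds$X, beta)
  # log(1 + exp(eta)) = max(eta, 0) + log1p(exp(-|eta|))
  loss <- sum(pmax(eta, 0) + log1p(exp(-abs(eta)))) - sum(ds$y * eta)
  grad <- .xtmul(ds$X, plogis(eta) - ds$y)
  list(loss = loss, grad = grad)
}

#' @rdname logistic_loss_grad
#' @export
cox_loss_grad <- function(ds, beta) {
  stopifnot(inherits(ds, "cox_data"))
  eta <- .linpred(ds$X, beta)
  ord <- ds$ord
  eta_s <- eta[ord]
  delta_s <- ds$status[ord]
  m <- max(eta_s)
  w <- exp(eta_s - m)                       # centered hazards, overflow-safe
  denom <- rev(cumsum(rev(w)))[ds$tie_first]  # risk-set sums, ties shared
  loss <- sum(delta_s * (log(denom) + m - eta_s))
  cum <- cumsum(delta_s / denom)[ds$tie_last] # sum over events with y_i <= y_j
  resid_s <- w * cum - delta_s
  resid <- numeric(ds$n)
  resid[ord] <- resid_s
  grad <- .xtmul(ds$X, resid)
  list(loss = loss, grad = grad)
}

.linpred <- function(X, beta) {
  if (length(beta) != ncol(X)) {
    stop(sprintf("`beta` has length %d; expected %d", length(beta), ncol(X)),
         call. = FALSE)
  }
  # exploit coefficient sparsity: only active columns contribute
  nz <- which(beta != 0)
  if (length(nz) == 0L) return(numeric(nrow(X)))
  if (is.matrix(X) && length(nz) < ncol(X) / 4L) {
    return(as.vector(X[, nz, drop = FALSE] %*% beta[nz]))
  }
  as.vector(X %*% beta)
}

# crossprod avoiding S4 dispatch (and a dense copy) for base matrices
.xtmul <- function(X, v) {
  if (is.matrix(X)) as.vector(crossprod(X, v))
  else as.vector(Matrix::crossprod(X, v))
}

# Generic dispatch used by the solver.
.loss_grad <- function(ds, beta) {
  if (inherits(ds, "logistic_data")) logistic_loss_grad(ds, beta)
  else cox_loss_grad(ds, beta)
}

#' Lipschitz constant of the latent gradient
#'
#' Returns `M = c * ||t(XA) %*% (XA)||_2` with `c = 1/4` for logistic and
#' `c = 2` for Cox models, where `A` is the latent expansion map.  The
#' spectral norm is estimated by power iteration applied through the
#' operators `X` and `A` (the `n x latent_dim` product is never
#' materialized), with a deterministic start vector.
#'
#' The reciprocal `1/M` is the default proximal-gradient step size; any
#' step in `[eps, 2/M - eps]` is admissible.
#'
#' @param ds a [logistic_data()] or [cox_data()] object.
#' @param gs a [group_structure()], or `NULL` for the identity map
#'   (no latent duplication).
#' @param tol relative convergence tolerance of the power iteration.
#' @param max_iter iteration cap; non-convergence is an error.
#' @return scalar `M`.
#' @export
lipschitz_constant <- function(ds, gs = NULL, tol = 1e-6, max_iter = 1000L) {
  stopifnot(inherits(ds, "pgd_data"))
  cfac <- if (inherits(ds, "logistic_data")) 0.25 else 2
  X <- ds$X
  A <- if (is.null(gs)) NULL else gs$A
  d <- if (is.null(A)) ncol(X) else ncol(A)

  apply_op <- function(v) {
    u <- if (is.null(A)) v else as.vector(A %*% v)
    t1 <- as.vector(X %*% u)
    t2 <- .xtmul(X, t1)
    if (is.null(A)) t2 else as.vector(Matrix::crossprod(A, t2))
  }

  v <- seq_len(d) / sqrt(sum(seq_len(d)^2))  # deterministic start
  lam <- 0
  for (k in seq_len(max_iter)) {
    w <- apply_op(v)
    nw <- sqrt(sum(w * w))
    if (nw == 0) return(0)   # zero design
    lam_new <- sum(v * w)    # Rayleigh quotient (operator is PSD)
    v <- w / nw
    if (k > 1 && abs(lam_new - lam) <= tol * abs(lam_new)) {
      return(cfac * lam_new)
    }
    lam <- lam_new
  }
  stop(sprintf(
    "power iteration did not reach relative tolerance %g in %d iterations (last estimate %g)",
    tol, max_iter, lam), call. = FALSE)
}
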