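test_that("block soft-thresholding has the closed form", {
  expect_equal(prox_block_l2(c(3, 4), 2.5), c(1.5, 2))
  expect_equal(prox_block_l2(c(0.3, 0.4), 0.5), c(0, 0))   # norm == t
  expect_equal(prox_block_l2(c(0.1, 0.1), 5), c(0, 0))
  z <- rnorm(6)
  expect_equal(prox_block_l2(z, 0), z)
  expect_error(prox_block_l2(z, -1), "nonnegative")
})

test_that("objective combines loss and blockwise penalty consistently", {
  ds <- logistic_data(matrix(rnorm(8), 4, 2), c(1, 0, 1, 0))
  gs <- group_structure(data.frame(variable = 1:2, group = "a"), 2)
  expect_equal(objective_value(ds, gs, group_weights(gs, 0.4), c(0, 0)),
               4 * log(2))
  set.seed(2)
  gamma <- rnorm(2)
  expect_equal(objective_value(ds, gs, group_weights(gs, 0), gamma),
               logistic_loss_grad(ds, expand_coefficients(gs, gamma))$loss)
  # blockwise evaluation equals a flat independent computation
  gso <- group_structure(
    data.frame(variable = c(1, 2, 2), group = c("a", "a", "b")), 2)
  pen <- group_weights(gso, 0.3)
  g2 <- rnorm(gso$latent_dim)
  flat <- logistic_loss_grad(ds, expand_coefficients(gso, g2))$loss +
    sum(vapply(seq_along(gso$groups), function(g)
      pen$weights[g] * sqrt(sum(g2[gso$block == g]^2)), numeric(1)))
  expect_equal(objective_value(ds, gso, pen, g2), flat)
})

test_that("penalties at or above lambda_max give the all-zero solution", {
  ds <- random_logistic(40, 6, 5)
  gs <- group_structure(
    data.frame(variable = 1:6, group = rep(c("a", "b"), each = 3)), 6)
  lmx <- lambda_max(ds, gs)
  fit <- fit_pgd(ds, gs, group_weights(gs, lmx * (1 + 1e-10)))
  expect_identical(unname(fit$beta), rep(0, 6))
  expect_equal(max(kkt_residual(ds, gs, group_weights(gs, lmx * 1.01),
                                fit$gamma)), 0)
  # just below lambda_max something enters
  fit2 <- fit_pgd(ds, gs, group_weights(gs, lmx * 0.95))
  expect_gt(sum(fit2$beta != 0), 0)
})

test_that("unpenalized fit matches the Newton (glm) oracle", {
  ds <- random_logistic(50, 3, 21)
  gs <- group_structure(data.frame(variable = 1:3, group = letters[1:3]), 3)
  fit <- fit_pgd(ds, gs, group_weights(gs, 0), solver_options(tol = 1e-9))
  or <- stats::glm.fit(as.matrix(ds$X), ds$y,
                       family = stats::binomial())$coefficients
  expect_equal(unname(fit$beta), unname(or), tolerance = 1e-4)
})

test_that("unpenalized cox fit matches the coxph oracle", {
  skip_if_not_installed("survival")
  ds <- random_cox(60, 3, 22)
  gs <- group_structure(data.frame(variable = 1:3, group = letters[1:3]), 3)
  fit <- fit_pgd(ds, gs, group_weights(gs, 0), solver_options(tol = 1e-10))
  or <- survival::coxph(survival::Surv(ds$time, ds$status) ~ as.matrix(ds$X),
                        ties = "breslow")
  expect_equal(unname(fit$beta), unname(coef(or)), tolerance = 1e-3)
})

test_that("objective trace descends monotonically at step 1/M", {
  for (s in 1:5) {
    ds <- if (s %% 2) random_logistic(30, 8, s) else random_cox(30, 8, s)
    gs <- group_structure(
      data.frame(variable = 1:8, group = rep(c("a", "b"), each = 4)), 8)
    fit <- fit_pgd(ds, gs, group_weights(gs, 0.5),
                   solver_options(tol = 1e-6, max_iter = 2000))
    expect_true(all(diff(fit$objective_trace) <= 1e-12))
  }
})

test_that("final objective matches the block-coordinate oracle without overlap", {
  ds <- random_logistic(100, 50, 31)
  gs <- group_structure(
    data.frame(variable = 1:50, group = rep(letters[1:5], each = 10)), 50)
  pen <- group_weights(gs, 0.3 * lambda_max(ds, gs))
  fit <- fit_pgd(ds, gs, pen, solver_options(tol = 1e-8))
  orc <- bcd_oracle(ds, gs, pen)
  f_pgd <- objective_value(ds, gs, pen, fit$gamma)
  expect_lt(abs(f_pgd - orc$objective) / abs(orc$objective), 1e-6)
})

test_that("all-singleton groups reduce to the plain lasso (glmnet oracle)", {
  skip_if_not_installed("glmnet")
  ds <- random_logistic(60, 10, 41)
  gs <- group_structure(
    data.frame(variable = 1:10, group = paste0("v", 1:10)), 10)
  lam <- 0.2 * lambda_max(ds, gs)
  pen <- group_weights(gs, lam)
  fit <- fit_pgd(ds, gs, pen, solver_options(tol = 1e-9))
  # glmnet minimizes -(1/n) loglik + lambda' * ||beta||_1
  gl <- glmnet::glmnet(as.matrix(ds$X), ds$y, family = "binomial",
                       lambda = lam / ds$n, standardize = FALSE,
                       intercept = FALSE, thresh = 1e-14)
  b_gl <- as.vector(gl$beta)
  f_ours <- objective_value(ds, gs, pen, fit$gamma)
  f_gl <- objective_value(ds, gs, pen, collapse_vector(gs, b_gl))
  expect_lt(abs(f_ours - f_gl) / abs(f_gl), 1e-6)
  expect_equal(unname(fit$beta), b_gl, tolerance = 1e-4)
})

test_that("fit is invariant to the order in which groups are listed", {
  ds <- random_logistic(50, 9, 51)
  m1 <- data.frame(variable = 1:9, group = rep(c("a", "b", "c"), each = 3))
  m2 <- m1[9:1, ]
  gs1 <- group_structure(m1, 9)
  gs2 <- group_structure(m2, 9)
  f1 <- fit_pgd(ds, gs1, group_weights(gs1, 1), solver_options(tol = 1e-8))
  f2 <- fit_pgd(ds, gs2, group_weights(gs2, 1), solver_options(tol = 1e-8))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-8)
})

test_that("overlap keeps the union-of-groups selection semantics", {
  # two groups sharing variable 3; zero one latent block by hand
  gs <- group_structure(
    data.frame(variable = c(1, 2, 3, 3, 4, 5), group = rep(c("a", "b"), 3)),
    5)
  gamma <- numeric(gs$latent_dim)
  gamma[gs$block == 1] <- c(1, 1, 0.5)      # group a = {1, 3, 4}
  beta <- expand_coefficients(gs, gamma)
  expect_equal(beta[3], 1)                  # shared variable still active
  expect_equal(beta[c(2, 5)], c(0, 0))      # group b fully zero
})

test_that("kkt residuals are near zero at converged solutions and shrink with tolerance", {
  ds <- random_logistic(80, 12, 61)
  gs <- group_structure(
    data.frame(variable = 1:12, group = rep(c("a", "b", "c"), each = 4)), 12)
  pen0 <- group_weights(gs, 0)
  f0 <- fit_pgd(ds, gs, pen0, solver_options(tol = 1e-10))
  expect_lt(max(kkt_residual(ds, gs, pen0, f0$gamma)), 1e-6)

  pen <- group_weights(gs, 0.3 * lambda_max(ds, gs))
  f_loose <- fit_pgd(ds, gs, pen, solver_options(tol = 5e-4))
  f_tight <- fit_pgd(ds, gs, pen, solver_options(tol = 1e-5))
  expect_lte(max(kkt_residual(ds, gs, pen, f_tight$gamma)),
             max(kkt_residual(ds, gs, pen, f_loose$gamma)))
})

test_that("solver guards: step size domain, max_iter warning, beta consistency", {
  ds <- random_logistic(30, 4, 71)
  gs <- group_structure(data.frame(variable = 1:4, group = "a"), 4)
  pen <- group_weights(gs, 0.5)
  M <- lipschitz_constant(ds, gs)
  expect_error(fit_pgd(ds, gs, pen, solver_options(step_size = 3 / M)),
               "admissible")
  expect_warning(
    f <- fit_pgd(ds, gs, pen, solver_options(tol = 1e-14, max_iter = 20)),
    "max_iter")
  expect_false(f$converged)
  expect_equal(f$n_iter, 20L)
  f2 <- fit_pgd(ds, gs, pen)
  expect_equal(f2$beta, expand_coefficients(gs, f2$gamma))
})
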