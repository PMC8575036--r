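test_that("lambda grids are equally log-spaced and decreasing", {
  expect_equal(lambda_grid(1e-4, 1e-6, 3), c(1e-4, 1e-5, 1e-6))
  g <- lambda_grid(1e-4, 1e-7, 100)
  expect_equal(g[1], 1e-4)
  expect_equal(g[100], 1e-7)
  r <- g[-1] / g[-100]
  expect_equal(max(r) - min(r), 0, tolerance = 1e-12)
  expect_equal(lambda_grid(2, 1, 2), c(2, 1))
  expect_error(lambda_grid(1e-6, 1e-4, 10), "lambda_max > lambda_min")
  expect_error(lambda_grid(1, 0, 10), "lambda_max > lambda_min")
})

test_that("warm-started paths start empty, densify, and match cold starts", {
  sim <- simulate_dataset(4, 6, 2, 10, 150, "logistic", seed = 3)
  ds <- sim$dataset; gs <- sim$gs
  lmx <- lambda_max(ds, gs)
  grid <- lambda_grid(lmx * 1.0001, 0.05 * lmx, 12)
  path <- fit_path(ds, gs, grid)
  expect_equal(path$n_nonzero[1], 0L)
  expect_equal(path$n_groups_selected[1], 0L)
  # nonzero counts mostly non-increasing in lambda (loose empirical check)
  d <- diff(path$n_nonzero)     # lambdas decreasing, counts should grow
  expect_gte(mean(d >= 0), 0.95)
  # a cold start at the smallest lambda reaches the same objective as a
  # continuation of the warm-started path, at the final-fit tolerance
  pen_last <- group_weights(gs, grid[12])
  cold <- fit_pgd(ds, gs, pen_last, solver_options(tol = 1e-5))
  warm <- fit_pgd(ds, gs, pen_last, solver_options(tol = 1e-5),
                  gamma0 = path$fits[[12]]$gamma)
  f_warm <- objective_value(ds, gs, pen_last, warm$gamma)
  f_cold <- objective_value(ds, gs, pen_last, cold$gamma)
  expect_lt(abs(f_warm - f_cold) / abs(f_cold), 1e-5)
})

test_that("leave-one-out deviances reproduce hand-computed values", {
  set.seed(4)
  X <- matrix(rnorm(6), 6, 1)
  y <- c(0, 1, 0, 1, 1, 0)
  ds <- logistic_data(X, y)
  gs <- group_structure(data.frame(variable = 1, group = "a"), 1)
  # at lambda >= lambda_max of every leave-one-out training subset, each
  # fold fits the zero model and predicts p = 1/2 for its held-out point:
  # deviance 2 log 2 per fold, standard error 0
  lmx_loo <- max(vapply(1:6, function(i)
    lambda_max(logistic_data(X[-i, , drop = FALSE], y[-i]), gs),
    numeric(1)))
  res <- cross_validate(ds, gs, c(4 * lmx_loo, 2 * lmx_loo), k = 6, seed = 1)
  expect_equal(res$cv_table$metric_mean, rep(2 * log(2), 2))
  expect_equal(res$cv_table$metric_se, rep(0, 2))
})

test_that("cross-validation is deterministic given a seed", {
  sim <- simulate_dataset(3, 5, 1, 10, 80, "logistic", seed = 12)
  lmx <- lambda_max(sim$dataset, sim$gs)
  grid <- lambda_grid(lmx, 0.1 * lmx, 5)
  r1 <- cross_validate(sim$dataset, sim$gs, grid, k = 4, seed = 99)
  r2 <- cross_validate(sim$dataset, sim$gs, grid, k = 4, seed = 99)
  expect_identical(r1$folds, r2$folds)
  expect_identical(r1$cv_table, r2$cv_table)
  expect_identical(r1$selected_lambda, r2$selected_lambda)
  r3 <- cross_validate(sim$dataset, sim$gs, grid, k = 4, seed = 100)
  expect_false(identical(r1$folds, r3$folds))
})

test_that("fold assignment is stratified", {
  y <- rep(c(0, 1), c(40, 10))
  folds <- overlasso:::.make_folds(y, 5, 7)
  for (f in 1:5) expect_equal(sum(y[folds == f]), 2)
})

test_that("pure-noise data select a model no denser than the smallest-lambda fit", {
  set.seed(13)
  X <- matrix(rnorm(200 * 100), 200)
  y <- rbinom(200, 1, 0.5)
  ds <- logistic_data(X, y)
  gs <- group_structure(
    data.frame(variable = 1:100, group = rep(paste0("g", 1:10), each = 10)),
    100)
  lmx <- lambda_max(ds, gs)
  res <- cross_validate(ds, gs, lambda_grid(lmx, 0.2 * lmx, 8), k = 5,
                        seed = 5)
  i_sel <- which(res$lambdas == res$selected_lambda)
  expect_lte(res$n_nonzero[i_sel], res$n_nonzero[length(res$lambdas)])
})

test_that("cox cross-validation selects by C-index and beats the null on signal", {
  wins <- 0L
  for (s in 1:4) {
    sim <- simulate_dataset(5, 10, 2, 10, 200, "cox", seed = s,
                            cox_mode = "proportional")
    ds <- sim$dataset; gs <- sim$gs
    lmx <- lambda_max(ds, gs)
    res <- cross_validate(ds, gs, lambda_grid(lmx, 0.05 * lmx, 8), k = 3,
                          seed = s)
    expect_equal(attr(res$cv_table, "metric"), "cindex")
    ctrain <- harrell_c_index(ds$time, ds$status,
                              as.vector(ds$X %*% res$final_fit$beta))
    if (ctrain > 0.5) wins <- wins + 1L
  }
  expect_gte(wins, 3L)
})

test_that("the C-index matches closed cases and the exhaustive-pair oracle", {
  expect_equal(harrell_c_index(c(1, 2, 3), c(1, 1, 1), c(3, 2, 1)), 1)
  expect_equal(harrell_c_index(c(1, 2, 3), c(1, 1, 1), c(1, 2, 3)), 0)
  expect_equal(harrell_c_index(c(1, 2, 3, 4), c(1, 1, 0, 1), c(4, 1, 3, 2)),
               brute_c_index(c(1, 2, 3, 4), c(1, 1, 0, 1), c(4, 1, 3, 2)))
  set.seed(6)
  tm <- rexp(30); st <- rbinom(30, 1, 0.6); rk <- rnorm(30)
  rk[1:5] <- rk[6:10]   # force risk-score ties
  expect_equal(harrell_c_index(tm, st, rk), brute_c_index(tm, st, rk))
  expect_error(harrell_c_index(c(2, 1), c(1, 0), c(1, 2)), "comparable")
})

test_that("the C-index agrees with the survival package", {
  skip_if_not_installed("survival")
  set.seed(8)
  # untied times: tied-time conventions differ between implementations
  tm <- rexp(40); st <- rbinom(40, 1, 0.7); rk <- rnorm(40)
  cc <- survival::concordance(survival::Surv(tm, st) ~ rk, reverse = TRUE)
  expect_equal(harrell_c_index(tm, st, rk), unname(cc$concordance))
})

test_that("binomial deviance matches its definition and the logistic loss", {
  expect_equal(binomial_deviance(c(0, 1, 1), c(0, 1, 1)), 0, tolerance = 1e-9)
  expect_equal(binomial_deviance(rep(1, 4), rep(0.5, 4)), 8 * log(2))
  ds <- random_logistic(25, 3, 91)
  set.seed(91)
  beta <- rnorm(3)
  prob <- plogis(as.vector(ds$X %*% beta))
  expect_equal(binomial_deviance(ds$y, prob),
               2 * logistic_loss_grad(ds, beta)$loss)
  expect_error(binomial_deviance(c(0, 1), 0.5), "length")
})
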