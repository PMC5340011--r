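# Elastic-net penalized binomial-trials GLM: likelihood, trial expansion,
# solver oracles, regularization path, cross-validated tuning.

test_that("negloglik matches its closed form and the perfect-fit limit", {
  X <- matrix(0, 1, 1)
  expect_equal(negloglik(0, 0, X, binomial_response(0L)), 5 * log(2))
  # y = m with pi -> 1: contribution -> 0 under clipping
  expect_lt(negloglik(30, 0, X, binomial_response(5L)), 1e-8)
  expect_error(negloglik(0, NaN, X, binomial_response(0L)))
})

test_that("expand_trials is the exact Bernoulli-equivalence oracle", {
  inst <- make_glm_instance(3, n = 12, p = 3)
  ex <- expand_trials(inst$X, inst$resp)
  expect_equal(nrow(ex$X), 12 * 5)
  one <- expand_trials(matrix(1.5, 1, 1), binomial_response(3L))
  expect_identical(one$y, c(1L, 1L, 1L, 0L, 0L))
  expect_true(all(one$X == 1.5))

  # binomial nll = Bernoulli nll on the expansion minus the constant,
  # at 20 random parameter points
  const <- sum(lchoose(5, inst$resp$y))
  for (k in 1:20) {
    par <- isisen:::local_seed(100 + k, rnorm(4, sd = 0.8))
    bern <- negloglik(par[1], par[-1], ex$X,
                      binomial_response(ex$y, 1L))
    binm <- negloglik(par[1], par[-1], inst$X, inst$resp)
    expect_equal(binm, bern - const, tolerance = 1e-10)
  }
})

test_that("unpenalized fit matches IRLS on the trial expansion", {
  # independent oracle: stats::glm on the expanded Bernoulli rows
  for (seed in 1:5) {
    inst <- make_glm_instance(seed, n = 50, p = 5)
    ex <- expand_trials(inst$X, inst$resp)
    oracle <- stats::glm.fit(cbind(1, ex$X), ex$y,
                             family = stats::binomial())
    fit <- fit_enet(inst$X, inst$resp, lambda = 0)
    expect_equal(unname(c(fit$intercept, fit$beta)),
                 unname(oracle$coefficients), tolerance = 1e-6)
  }
})

test_that("a fully penalized fit is the null model", {
  inst <- make_glm_instance(7)
  fit <- fit_enet(inst$X, inst$resp, lambda = 100)
  expect_true(all(fit$beta == 0))
  expect_equal(fit$intercept, qlogis(mean(inst$resp$y) / 5),
               tolerance = 1e-6)
})

test_that("duplicated columns receive equal coefficients when w < 1", {
  inst <- make_glm_instance(11, n = 60, p = 4)
  X2 <- cbind(inst$X, inst$X[, 1])
  fit <- fit_enet(X2, inst$resp, lambda = 0.05)
  expect_equal(unname(fit$beta[1]), unname(fit$beta[5]), tolerance = 1e-5)
  expect_gt(abs(fit$beta[1]), 0)
})

test_that("w = 1 gives lasso sparsity and w near 0 approaches ridge", {
  inst <- make_glm_instance(13, n = 40, p = 8)
  lasso <- fit_enet(inst$X, inst$resp, 0.08, enet_config(w = 1))
  ridge <- fit_enet(inst$X, inst$resp, 0.08, enet_config(w = 0.001))
  expect_gt(sum(lasso$beta == 0), 0)
  expect_true(all(ridge$beta != 0))
})

test_that("constant response warns and pins the intercept at the boundary", {
  X <- matrix(rnorm(20), 10, 2)
  expect_warning(f <- fit_enet(X, binomial_response(rep(0L, 10)), 0.1),
                 "constant")
  expect_lt(plogis(f$intercept), 1e-6)
})

test_that("lambda_path starts at the smallest all-zero penalty", {
  inst <- make_glm_instance(17, n = 40, p = 6)
  lam <- lambda_path(inst$X, inst$resp, n_lambda = 25)
  expect_length(lam, 25)
  expect_true(all(diff(lam) < 0))
  top <- fit_enet(inst$X, inst$resp, lam[1])
  expect_true(all(top$beta == 0))
  just_below <- fit_enet(inst$X, inst$resp, lam[1] * 0.9)
  expect_gt(sum(just_below$beta != 0), 0)

  # hand-computed lambda_max on a small instance
  X <- matrix(c(1, 2, 3, 4, 5, 2, 1, 2, 1, 2), 5, 2)
  y <- c(0L, 1L, 3L, 4L, 5L)
  resp <- binomial_response(y)
  std <- isisen:::standardize_columns(X)
  lmax <- max(abs(crossprod(std$X, y - mean(y)))) / (5 * 0.5)
  expect_equal(lambda_path(X, resp, w = 0.5, n_lambda = 3)[1], lmax)

  expect_error(lambda_path(X, binomial_response(rep(2L, 5))),
               "zero-variance")
  expect_warning(lambda_path(X, resp, w = 0), "ridge")
})

test_that("solution path is continuous in lambda", {
  inst <- make_glm_instance(19, n = 60, p = 6)
  lam <- lambda_path(inst$X, inst$resp, n_lambda = 40)
  path <- isisen:::enet_path_fit(inst$X, inst$resp, lam, enet_config())
  step <- vapply(seq_len(39), function(l) {
    sqrt(sum((path$beta[, l] - path$beta[, l + 1])^2))
  }, numeric(1))
  expect_lt(max(step), 0.5)
})

test_that("fit agrees with glmnet on Bernoulli data at matched penalties", {
  skip_if_not_installed("glmnet")
  inst <- make_glm_instance(23, n = 200, p = 6, m = 1,
                            beta = c(1, -1, 0.5, 0, 0, 0))
  for (lam in c(0.02, 0.005)) {
    g <- glmnet::glmnet(inst$X, inst$resp$y, family = "binomial",
                        alpha = 0.5, lambda = lam, standardize = TRUE,
                        thresh = 1e-12)
    f <- fit_enet(inst$X, inst$resp, lam)
    expect_equal(unname(f$beta), unname(as.numeric(g$beta)),
                 tolerance = 1e-4)
    expect_equal(f$intercept, unname(g$a0), tolerance = 1e-4)
  }
})

test_that("cv_lambda is deterministic and partitions evenly", {
  inst <- make_glm_instance(29, n = 10, p = 3)
  cv1 <- cv_lambda(inst$X, inst$resp, n_folds = 5, seed = 4)
  cv2 <- cv_lambda(inst$X, inst$resp, n_folds = 5, seed = 4)
  expect_identical(cv1$lambda_best, cv2$lambda_best)
  expect_identical(cv1$folds, cv2$folds)
  expect_true(all(table(cv1$folds) == 2))
})

test_that("cv_lambda stays near lambda_max on pure noise", {
  hits <- 0
  for (i in 1:50) {
    X <- isisen:::local_seed(i, matrix(rnorm(60 * 20), 60, 20))
    y <- isisen:::local_seed(1000 + i, rbinom(60, 5, 0.5))
    resp <- binomial_response(y)
    lam <- lambda_path(X, resp, n_lambda = 20)
    cv <- cv_lambda(X, resp, n_folds = 5, seed = i, lambda = lam)
    hits <- hits + (cv$lambda_best >= lam[2])
  }
  expect_gte(hits / 50, 0.8)
})

test_that("fit serialization keeps the nonzero coefficients", {
  inst <- make_glm_instance(31)
  fit <- fit_enet(inst$X, inst$resp, 0.05)
  f <- withr::local_tempfile(fileext = ".json")
  write_enet_fit(fit, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$lambda, 0.05)
  expect_equal(length(back$coefficients), sum(fit$beta != 0))
  expect_equal(back$intercept, fit$intercept, tolerance = 1e-12)
})

test_that("tidy and glance summarize a fit", {
  inst <- make_glm_instance(37)
  fit <- fit_enet(inst$X, inst$resp, 0.05)
  td <- tidy(fit)
  expect_true(all(td$estimate != 0))
  gl <- glance(fit)
  expect_identical(gl$df, nrow(td))
  expect_true(gl$converged)
  expect_gte(gl$deviance, 0)
})
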