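# Screening: submodel-size rule, marginal/residual rankings, ISIS loop.

test_that("default_d implements the outcome-type rules", {
  expect_identical(default_d(659, "count"), 50L)
  expect_identical(default_d(659, "binary"), 25L)
  expect_identical(default_d(659, "continuous"), 101L)
  expect_identical(default_d(659, "count", c = 2), 101L)
  expect_identical(default_d(3, "binary"), 1L)  # floored at 1
  expect_error(default_d(1, "count"), ">= 2")
})

test_that("marginal_ranking orders by |Pearson correlation| with ties by index", {
  resp <- binomial_response(c(0L, 1L, 2L, 3L, 4L, 5L, 0L, 5L))
  y <- resp$y
  X <- cbind(a = rnorm(8), b = as.numeric(y), c = as.numeric(y),
             d = rnorm(8))
  rk <- marginal_ranking(X, resp)
  expect_identical(rk$index[1:2], c(2L, 3L))  # tie broken by lower index
  expect_equal(rk$utility[1], 1)
  # zero-variance column ranked last
  X2 <- cbind(X, e = rep(1, 8))
  expect_identical(marginal_ranking(X2, resp)$index[5], 5L)
})

test_that("a planted linear signal is ranked first almost always", {
  hits <- 0
  for (i in 1:100) {
    dat <- isisen:::local_seed(i, {
      X <- matrix(rnorm(500 * 30), 500, 30)
      y <- rbinom(500, 5, plogis(1.2 * X[, 7]))
      list(X = X, y = y)
    })
    rk <- marginal_ranking(dat$X, binomial_response(dat$y))
    hits <- hits + (rk$index[1] == 7L)
  }
  expect_gte(hits / 100, 0.95)
})

test_that("sis_screen saturates, truncates and nests in d", {
  inst <- make_glm_instance(41, n = 30, p = 8)
  expect_setequal(sis_screen(inst$X, inst$resp, 20), 1:8)
  expect_length(sis_screen(inst$X, inst$resp, 1), 1)
  s3 <- sis_screen(inst$X, inst$resp, 3)
  s6 <- sis_screen(inst$X, inst$resp, 6)
  expect_true(all(s3 %in% s6))
})

test_that("residual ranking under a null fit equals the marginal ranking", {
  inst <- make_glm_instance(43, n = 40, p = 6)
  null_fit <- fit_enet(inst$X, inst$resp, lambda = 100)
  rr <- residual_ranking(inst$X, inst$resp, null_fit, exclude = c(2L, 5L))
  mr <- marginal_ranking(inst$X, inst$resp)
  expect_identical(rr$index, mr$index[!mr$index %in% c(2L, 5L)])
  expect_false(any(c(2L, 5L) %in% rr$index))
})

test_that("residual ranking rescues a marginally hidden joint signal", {
  # x2 has corr -0.9 with x1 and cancels marginally, but y follows x1 + x2
  succ <- 0
  for (i in 1:100) {
    n <- 500
    x1 <- isisen:::local_seed(i, rnorm(n))
    x2 <- -0.9 * x1 + sqrt(1 - 0.81) * isisen:::local_seed(200 + i, rnorm(n))
    Xn <- isisen:::local_seed(400 + i, matrix(rnorm(n * 48), n, 48))
    X <- cbind(x1, x2, Xn)
    y <- isisen:::local_seed(600 + i,
                             rbinom(n, 5, plogis(3 * (x1 + x2))))
    resp <- binomial_response(y)
    f1 <- fit_enet(X[, 1, drop = FALSE], resp, 0)
    full <- f1
    full$beta <- stats::setNames(numeric(50), isisen:::feature_names(X))
    full$beta[1] <- f1$beta
    rr <- residual_ranking(X, resp, full, exclude = 1L)
    succ <- succ + (2L %in% rr$index[1:5])
  }
  expect_gte(succ / 100, 0.9)
})

test_that("residual ranking warns and returns empty on a perfect fit", {
  X <- matrix(rnorm(20), 10, 2)
  resp <- binomial_response(rep(c(0L, 5L), 5))
  fit <- fit_enet(X, resp, 100)
  fit$intercept <- 0
  fit$beta[] <- 0
  # force exact residual zero by using a response the null fit reproduces
  resp0 <- binomial_response(rep(2L, 10))
  fit0 <- structure(list(intercept = qlogis(0.4), beta = c(0, 0), m = 5L),
                    class = "enet_fit")
  expect_warning(rr <- residual_ranking(X, resp0, fit0), "zero-variance")
  expect_identical(nrow(rr), 0L)
})

test_that("isis_select is deterministic and respects the d cap", {
  sim <- sim_mets_scenario(p = 300, seed = 51)
  cfg <- screening_config(d = 12)
  s1 <- isis_select(sim$X, sim$resp, cfg, seed = 2)
  s2 <- isis_select(sim$X, sim$resp, cfg, seed = 2)
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$trace$lambda, s2$trace$lambda)
  expect_true(all(vapply(s1$trace$active, length, integer(1)) <= 12))
  expect_true(all(vapply(s1$trace$candidates, length, integer(1)) <= 12))
  # selected features carry nonzero final coefficients
  expect_true(all(s1$fit$beta[s1$selected] != 0))
  expect_true(all(s1$fit$beta[-s1$selected] == 0))
})

test_that("without screening or refinement ISIS reduces to one elastic-net fit", {
  inst <- make_glm_instance(53, n = 60, p = 10,
                            beta = c(1.5, -1, rep(0, 8)))
  cfg <- screening_config(d = 10, max_isis_iter = 1, tune = "cv",
                          refine = "none")
  sel <- isis_select(inst$X, inst$resp, cfg, seed = 9)
  lam <- sel$trace$lambda[1]
  direct <- fit_enet(inst$X, inst$resp, lam)
  expect_equal(unname(sel$fit$beta), unname(direct$beta), tolerance = 1e-10)
  expect_identical(sel$selected, unname(which(direct$beta != 0)))
})

test_that("ISIS controls false positives on pure noise", {
  sizes <- vapply(1:20, function(i) {
    X <- isisen:::local_seed(3000 + i, matrix(rnorm(200 * 500), 200, 500))
    y <- isisen:::local_seed(4000 + i, rbinom(200, 5, 0.5))
    sel <- isis_select(X, binomial_response(y), screening_config(),
                       seed = i)
    length(sel$selected)
  }, integer(1))
  expect_lte(mean(sizes), 2)
})

test_that("ISIS recovers the planted signals in the benchmark scenario", {
  hits <- 0
  screened_all <- 0
  for (i in 1:20) {
    sim <- sim_mets_scenario(p = 2000, seed = 500 + i)
    sel <- isis_select(sim$X, sim$resp, screening_config(d = 50),
                       seed = 500 + i)
    truth <- sort(sim$scenario$signal_positions)
    hits <- hits + all(truth %in% sel$selected)
    cand <- sort(unique(unlist(sel$trace$candidates)))
    screened_all <- screened_all + all(truth %in% cand)
  }
  expect_gte(hits / 20, 0.9)
  # sure-screening sanity: candidates over iterations cover the truth
  expect_gte(screened_all / 20, 0.95)
})

test_that("trace serialization writes one JSON record per iteration", {
  sim <- sim_mets_scenario(p = 150, seed = 61)
  sel <- isis_select(sim$X, sim$resp, screening_config(d = 8), seed = 3)
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_isis_trace(sel, f)
  lines <- readLines(f)
  expect_length(lines, nrow(sel$trace))
  rec <- jsonlite::fromJSON(lines[1])
  expect_identical(rec$iteration, 1L)
  expect_true(all(c("candidates", "active", "lambda", "deviance")
                  %in% names(rec)))
})
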