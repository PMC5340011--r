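# Elastic-net penalized binomial-trials GLM.

standardize_columns <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  # population sd, as is conventional for penalized paths
  s <- sqrt(colMeans(X^2) - mu^2)
  s[s < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2L, mu, "-"), 2L, s, "/")
  list(X = Xs, center = mu, scale = s)
}

#' Elastic-net configuration
#'
#' @param w Lasso weight in \[0,1\]: the penalty is
#'   \eqn{\lambda (w \|\beta\|_1 + (1-w)/2 \|\beta\|_2^2)}. Default 0.5,
#'   i.e. half lasso and half ridge, the weighting used throughout for
#'   correlated methylation markers.
#' @param standardize Center and scale columns to unit variance before
#'   penalization (coefficients are always reported on the original scale).
#' @param max_iter Maximum IRLS iterations.
#' @param tol Convergence tolerance on the maximum absolute coefficient
#'   change.
#' @param prob_clip Clipping bound keeping fitted probabilities away from 0/1.
#' @return A list of class `enet_config`.
#' @export
enet_config <- function(w = 0.5, standardize = TRUE, max_iter = 1000L,
                        tol = 1e-7, prob_clip = 1e-9) {
  stopifnot(w >= 0, w <= 1, tol > 0, max_iter >= 1)
  structure(list(w = w, standardize = standardize,
                 max_iter = as.integer(max_iter), tol = tol,
                 prob_clip = prob_clip),
            class = "enet_config")
}

# Shared worker: fit a decreasing lambda path on (optionally standardized)
# data with warm starts; returns coefficients on the ORIGINAL scale.
enet_path_fit <- function(X, resp, lambda, cfg) {
  X <- as_design_matrix(X)
  resp <- as_binomial_response(resp)
  n <- nrow(X)
  stopifnot(length(resp$y) == n, n >= 2)
  if (anyNA(X)) stop("`X` must not contain missing values", call. = FALSE)
  std <- if (cfg$standardize) {
    standardize_columns(X)
  } else {
    list(X = X, center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  }
  constant <- all(resp$y == 0L) || all(resp$y == resp$m)
  if (constant) {
    warning("constant response: intercept fit at clipped boundary",
            call. = FALSE)
  }
  fit <- enet_path_cpp(std$X, as.numeric(resp$y), resp$m, cfg$w,
                       sort(lambda, decreasing = TRUE),
                       0, rep(0, ncol(X)),
                       cfg$max_iter, cfg$tol, cfg$prob_clip, 1000L)
  beta_std <- fit$beta
  beta <- beta_std / std$scale
  b0 <- drop(fit$b0) - drop(crossprod(beta_std, std$center / std$scale))
  list(lambda = sort(lambda, decreasing = TRUE),
       beta = beta, intercept = b0,
       n_iter = drop(fit$n_iter), converged = drop(fit$converged) == 1L)
}

#' Fit the elastic-net penalized binomial-trials GLM
#'
#' Models a count response \eqn{y_i \sim \mathrm{Binomial}(m, \pi_i)} with
#' \eqn{\mathrm{logit}(\pi_i) = \beta_0 + \beta^\top x_i} and minimizes
#' \deqn{\frac{1}{n}\,\mathrm{negloglik}(\beta_0, \beta) +
#'   \lambda\left(w\|\beta\|_1 + \frac{1-w}{2}\|\beta\|_2^2\right)}
#' by IRLS with a coordinate-descent inner loop; the intercept is
#' unpenalized. The ridge component shrinks correlated predictors together
#' (duplicated columns receive equal coefficients whenever `w < 1`), while
#' the lasso component keeps the solution sparse.
#'
#' @param X Numeric samples x features matrix (no missing values).
#' @param resp A [binomial_response()] or count vector (then `m = 5`).
#' @param lambda Penalty level \eqn{\ge 0}.
#' @param cfg An [enet_config()].
#' @return An object of class `enet_fit` with elements `intercept`, `beta`
#'   (dense named vector; zeros for unselected features), `lambda`, `w`,
#'   `deviance`, `n_iter`, `converged`.
#' @examples
#' sim <- sim_mets_scenario(p = 120, seed = 1)
#' fit <- fit_enet(sim$X[, 1:20], sim$resp, lambda = 0.05)
#' glance(fit)
#' @export
fit_enet <- function(X, resp, lambda, cfg = enet_config()) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda >= 0)
  X <- as_design_matrix(X)
  resp <- as_binomial_response(resp)
  path <- enet_path_fit(X, resp, lambda, cfg)
  beta <- drop(path$beta)
  names(beta) <- feature_names(X)
  if (!path$converged[1L]) {
    warning("IRLS did not converge in ", cfg$max_iter, " iterations",
            call. = FALSE)
  }
  new_enet_fit(path$intercept[1L], beta, lambda, cfg, X, resp,
               path$n_iter[1L], path$converged[1L])
}

new_enet_fit <- function(intercept, beta, lambda, cfg, X, resp,
                         n_iter, converged) {
  nz <- which(beta != 0)  # deviance from the active columns only
  structure(list(
    intercept = intercept,
    beta = beta,
    lambda = lambda,
    w = cfg$w,
    deviance = binomial_deviance(intercept, beta[nz],
                                 X[, nz, drop = FALSE], resp,
                                 cfg$prob_clip),
    n_iter = n_iter,
    converged = converged,
    m = resp$m,
    nobs = nrow(X)
  ), class = "enet_fit")
}

#' @export
print.enet_fit <- function(x, ...) {
  cat("<enet_fit> lambda =", signif(x$lambda, 4L), ", w =", x$w,
      ",", sum(x$beta != 0), "nonzero of", length(x$beta), "features\n")
  cat("deviance =", signif(x$deviance, 6L),
      ", converged =", x$converged, "\n")
  invisible(x)
}

#' Predict from an elastic-net binomial fit
#'
#' @param object An `enet_fit`.
#' @param newdata Samples x features matrix with the same columns as the
#'   training data.
#' @param type `"link"` (linear predictor), `"response"` (probability
#'   \eqn{\hat\pi}), or `"count"` (\eqn{m \hat\pi}).
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.enet_fit <- function(object, newdata,
                             type = c("response", "link", "count"), ...) {
  type <- match.arg(type)
  newdata <- as_design_matrix(newdata)
  nz <- which(object$beta != 0)
  eta <- drop(object$intercept +
                newdata[, nz, drop = FALSE] %*% object$beta[nz])
  switch(type,
         link = eta,
         response = sigmoid(eta),
         count = object$m * sigmoid(eta))
}

#' @rdname fit_enet
#' @param x An `enet_fit`.
#' @param ... Unused.
#' @export
tidy.enet_fit <- function(x, ...) {
  nz <- which(x$beta != 0)
  tibble::tibble(term = names(x$beta)[nz],
                 index = nz,
                 estimate = unname(x$beta[nz]))
}

#' @rdname fit_enet
#' @export
glance.enet_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, w = x$w, df = sum(x$beta != 0),
                 deviance = x$deviance, n_iter = x$n_iter,
                 converged = x$converged, nobs = x$nobs)
}

#' Serialize an elastic-net fit to JSON
#'
#' Writes the intercept, the nonzero coefficients keyed by feature ID, and
#' the fit metadata.
#'
#' @param fit An `enet_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enet_fit <- function(fit, path) {
  nz <- fit$beta[fit$beta != 0]
  jsonlite::write_json(list(
    intercept = fit$intercept,
    coefficients = as.list(nz),
    lambda = fit$lambda,
    w = fit$w,
    deviance = fit$deviance,
    converged = fit$converged
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Regularization path for the binomial elastic net
#'
#' \eqn{\lambda_{max} = \max_j |x_j^\top (y - \bar y)| / (n w)} on
#' standardized columns is the smallest penalty with an all-zero solution;
#' the path is a geometric grid of `n_lambda` values down to
#' `lambda_max * lambda_min_ratio`.
#'
#' @inheritParams fit_enet
#' @param w Lasso weight. Pure ridge (`w = 0`) has no finite all-zero
#'   penalty; the grid then falls back to the `w = 0.001` formula with a
#'   warning.
#' @param n_lambda Number of grid points.
#' @param lambda_min_ratio Smallest lambda as a fraction of the largest;
#'   default 0.01 when p > n, else 1e-4.
#' @return Decreasing numeric vector of length `n_lambda`.
#' @export
lambda_path <- function(X, resp, w = 0.5, n_lambda = 50L,
                        lambda_min_ratio = NULL) {
  X <- as_design_matrix(X)
  resp <- as_binomial_response(resp)
  y <- resp$y
  if (var(y) == 0) stop("zero-variance response", call. = FALSE)
  if (w == 0) {
    warning("w = 0 (pure ridge) has no finite lambda_max; using w = 0.001",
            call. = FALSE)
    w <- 0.001
  }
  lambda_min_ratio <- lambda_min_ratio %||%
    if (ncol(X) > nrow(X)) 0.01 else 1e-4
  std <- standardize_columns(X)
  n <- nrow(X)
  lambda_max <- max(abs(drop(crossprod(std$X, y - mean(y))))) / (n * w)
  exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
          length.out = n_lambda))
}

#' Cross-validated penalty selection
#'
#' Folds are a seeded permutation split; for each fold the full path is fit
#' on the training part with warm starts and the mean per-subject held-out
#' binomial deviance is recorded per lambda. The best lambda minimizes the
#' across-fold mean (ties go to the larger, sparser lambda).
#'
#' @inheritParams lambda_path
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed controlling the fold assignment.
#' @param lambda Optional lambda grid; defaults to [lambda_path()].
#' @param rule `"min"` returns the deviance-minimizing lambda; `"1se"` the
#'   largest lambda whose mean deviance is within one standard error of the
#'   minimum (the usual sparser choice for selection).
#' @param cfg An [enet_config()]; its `w` is overridden by `w`.
#' @return A list with `lambda_best` (per `rule`), `lambda_min`,
#'   `lambda_1se`, `cv` (tibble: lambda, mean deviance, sd), and `folds`
#'   (the fold assignment).
#' @export
cv_lambda <- function(X, resp, w = 0.5, n_folds = 10L, seed = 1L,
                      lambda = NULL, n_lambda = 50L,
                      lambda_min_ratio = NULL, rule = c("min", "1se"),
                      cfg = enet_config(w = w)) {
  rule <- match.arg(rule)
  X <- as_design_matrix(X)
  resp <- as_binomial_response(resp)
  n <- nrow(X)
  stopifnot(n_folds >= 2, n >= n_folds)
  cfg$w <- w
  lambda <- sort(lambda %||%
                   lambda_path(X, resp, w, n_lambda, lambda_min_ratio),
                 decreasing = TRUE)
  folds <- local_seed(seed, {
    sample(rep_len(seq_len(n_folds), n))
  })
  dev <- matrix(NA_real_, n_folds, length(lambda))
  cfg_fold <- cfg
  cfg_fold$tol <- max(cfg$tol, 1e-5)  # fold fits only rank lambdas
  for (f in seq_len(n_folds)) {
    test <- folds == f
    train_resp <- binomial_response(resp$y[!test], resp$m)
    if (var(train_resp$y) == 0) {
      warning("fold ", f, " training response is constant; ",
              "deviance computed with clipped probabilities", call. = FALSE)
    }
    path <- enet_path_fit(X[!test, , drop = FALSE], train_resp, lambda,
                          cfg_fold)
    Xt <- X[test, , drop = FALSE]
    yt <- binomial_response(resp$y[test], resp$m)
    sat <- saturated_negloglik(yt)
    dev[f, ] <- vapply(seq_along(lambda), function(l) {
      2 * (negloglik(path$intercept[l], path$beta[, l], Xt, yt,
                     cfg$prob_clip) - sat) / sum(test)
    }, numeric(1L))
  }
  cvm <- colMeans(dev)
  cvse <- apply(dev, 2L, sd) / sqrt(n_folds)
  best <- which(cvm <= min(cvm) + 1e-12)[1L]  # first = largest lambda
  one_se <- which(cvm <= cvm[best] + cvse[best] + 1e-12)[1L]
  list(lambda_best = if (rule == "min") lambda[best] else lambda[one_se],
       lambda_min = lambda[best],
       lambda_1se = lambda[one_se],
       cv = tibble::tibble(lambda = lambda, deviance = cvm,
                           deviance_se = cvse),
       folds = folds)
}
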