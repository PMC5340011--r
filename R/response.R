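#' Binomial-trials response
#'
#' Container for a per-subject count response \eqn{y_i \in \{0, \dots, m\}}
#' with a common trial count \eqn{m}. The metabolic-syndrome index counts how
#' many of five component conditions a subject satisfies, so the default is
#' \eqn{m = 5}.
#'
#' @param y Integer vector of counts.
#' @param m Trial count shared by all subjects (default 5).
#'
#' @return An object of class `binomial_response`: a list with elements `y`
#'   (integer vector) and `m` (integer scalar).
#' @examples
#' binomial_response(c(0, 3, 5, 2))
#' @export
binomial_response <- function(y, m = 5L) {
  if (is.list(y) && inherits(y, "binomial_response")) {
    return(y)
  }
  if (!is.numeric(y) || length(y) < 1L) {
    stop("`y` must be a non-empty numeric vector of counts", call. = FALSE)
  }
  if (any(!is.finite(y)) || any(y != round(y))) {
    stop("`y` must contain finite integer counts", call. = FALSE)
  }
  m <- as.integer(m)
  if (length(m) != 1L || is.na(m) || m < 1L) {
    stop("`m` must be a single integer >= 1", call. = FALSE)
  }
  if (any(y < 0L) || any(y > m)) {
    stop("counts must lie in [0, m]", call. = FALSE)
  }
  structure(list(y = as.integer(y), m = m), class = "binomial_response")
}

as_binomial_response <- function(resp, m = 5L) {
  if (inherits(resp, "binomial_response")) resp else binomial_response(resp, m)
}

#' @export
print.binomial_response <- function(x, ...) {
  cat("<binomial_response> n =", length(x$y), ", m =", x$m, "\n")
  cat("counts:", paste(utils::head(x$y, 10L), collapse = " "),
      if (length(x$y) > 10L) "..." else "", "\n")
  invisible(x)
}

#' @export
length.binomial_response <- function(x) length(x$y)

#' Negative binomial-trials log-likelihood
#'
#' Computes \eqn{-\sum_i [\log \binom{m}{y_i} + y_i \log \pi_i +
#' (m - y_i)\log(1-\pi_i)]} with \eqn{\pi_i = \mathrm{sigmoid}(\beta_0 +
#' \beta^\top x_i)}. Probabilities are clipped away from 0 and 1 so the value
#' stays finite under separation.
#'
#' @param intercept Scalar intercept \eqn{\beta_0}.
#' @param beta Coefficient vector of length `ncol(X)`.
#' @param X Numeric samples x features matrix.
#' @param resp A [binomial_response()] (or a count vector, taken with `m = 5`).
#' @param prob_clip Clipping bound for \eqn{\pi_i} (default `1e-9`).
#'
#' @return Non-negative scalar.
#' @examples
#' X <- matrix(0, 1, 1)
#' negloglik(0, 0, X, binomial_response(0L)) # 5 * log(2)
#' @export
negloglik <- function(intercept, beta, X, resp, prob_clip = 1e-9) {
  X <- as_design_matrix(X)
  resp <- as_binomial_response(resp)
  stopifnot(length(beta) == ncol(X), length(resp$y) == nrow(X))
  eta <- drop(intercept + X %*% beta)
  if (any(!is.finite(eta))) {
    stop("non-finite linear predictor", call. = FALSE)
  }
  p <- clip(sigmoid(eta), prob_clip, 1 - prob_clip)
  y <- resp$y
  m <- resp$m
  -sum(lchoose(m, y) + y * log(p) + (m - y) * log1p(-p))
}

#' Expand binomial-trials data to Bernoulli rows
#'
#' Each count row \eqn{(x_i, y_i)} becomes \eqn{m} Bernoulli rows: the same
#' covariates repeated with \eqn{y_i} ones and \eqn{m - y_i} zeros. For any
#' coefficients, the Bernoulli log-likelihood on the expansion equals the
#' binomial log-likelihood on the original data minus
#' \eqn{\sum_i \log\binom{m}{y_i}} — which makes the expansion an exact
#' oracle for the binomial fit via ordinary logistic regression.
#'
#' @inheritParams negloglik
#' @return A list with `X` (an `n*m` x p matrix) and `y` (binary vector).
#' @examples
#' ex <- expand_trials(matrix(1:2, 2, 1), binomial_response(c(3L, 0L)))
#' dim(ex$X) # 10 rows
#' @export
expand_trials <- function(X, resp) {
  X <- as_design_matrix(X)
  resp <- as_binomial_response(resp)
  stopifnot(length(resp$y) == nrow(X))
  m <- resp$m
  idx <- rep(seq_len(nrow(X)), each = m)
  ones <- sequence(rep(m, nrow(X))) <= rep(resp$y, each = m)
  list(X = X[idx, , drop = FALSE], y = as.integer(ones))
}

# Saturated negative log-likelihood (pi_hat = y/m), with 0 log 0 = 0.
saturated_negloglik <- function(resp) {
  resp <- as_binomial_response(resp)
  y <- resp$y
  m <- resp$m
  p <- y / m
  term <- function(k, pr) ifelse(k == 0, 0, k * log(pr))
  -sum(lchoose(m, y) + term(y, p) + term(m - y, 1 - p))
}

# Residual deviance: 2 * (negloglik - saturated negloglik).
binomial_deviance <- function(intercept, beta, X, resp, prob_clip = 1e-9) {
  2 * (negloglik(intercept, beta, X, resp, prob_clip) -
         saturated_negloglik(resp))
}
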