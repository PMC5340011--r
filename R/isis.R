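# (Iterative) sure independence screening around the penalized binomial fit.

#' Default screening submodel size
#'
#' The screening step retains \eqn{d} features before penalized selection.
#' The recommended sizes scale as \eqn{d = \lfloor cn/(4\log n)\rfloor} for a
#' binary outcome, \eqn{\lfloor cn/(2\log n)\rfloor} for a count outcome and
#' \eqn{\lfloor cn/\log n\rfloor} for a continuous one (natural log), floored
#' at 1.
#'
#' @param n Sample size (>= 2).
#' @param outcome_type `"binary"`, `"count"`, or `"continuous"`.
#' @param c Grid constant multiplying the rule (default 1).
#' @return Integer submodel size.
#' @examples
#' default_d(659, "count")  # 50
#' default_d(659, "binary") # 25
#' @export
default_d <- function(n, outcome_type = c("count", "binary", "continuous"),
                      c = 1) {
  outcome_type <- match.arg(outcome_type)
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    stop("`n` must be a single sample size >= 2", call. = FALSE)
  }
  div <- switch(outcome_type, binary = 4, count = 2, continuous = 1)
  max(1L, as.integer(floor(c * n / (div * log(n)))))
}

#' Screening configuration
#'
#' @param d Submodel size; `NULL` uses [default_d()] at fit time.
#' @param outcome_type Outcome type for the `d` rule (the 0-5 index is a
#'   count).
#' @param c Grid constant for [default_d()].
#' @param max_isis_iter Maximum screening iterations; 1 gives plain (non
#'   iterative) screening.
#' @param w Lasso weight for the elastic-net selection step.
#' @param cv_folds Cross-validation folds used to tune lambda at each refit.
#' @param n_lambda Lambda grid length at each refit (20; the grid only
#'   generates candidate supports, so it can be coarser than a standalone
#'   regularization path).
#' @param lambda_min_ratio Smallest scanned lambda as a fraction of
#'   lambda_max (0.05 by default: supports stabilize well above the dense
#'   end of the path, and the refinement step does the final selection).
#' @param tune How the penalty is tuned at each refit: `"bic"` (default;
#'   BIC over the penalized path, deterministic) or `"cv"`
#'   (cross-validated held-out deviance via [cv_lambda()]).
#' @param refine `"bic"` (default) prunes the elastic-net active set by
#'   Wald-guided backward elimination on refit BIC before it is reported;
#'   `"none"` reports the raw active set. The pruning counteracts the
#'   ridge component's grouping, which otherwise drags correlated
#'   neighbours of a selected feature into the active set wholesale.
#' @param ebic_gamma EBIC weight for the refinement penalty
#'   `log(n) + 2 * ebic_gamma * log(p)` (default 0.5); the `log(p)` term
#'   accounts for the selection having searched all `p` features.
#' @param lambda_rule For `tune = "cv"`: `"1se"` (default; the sparser
#'   one-standard-error choice) or `"min"` (the deviance minimizer).
#' @param utility Marginal utility for ranking: `"correlation"` (absolute
#'   Pearson correlation with the outcome, the default) or `"glm"`
#'   (per-feature binomial GLM deviance reduction; slower).
#' @param residual_type Residual used for iterative recruitment:
#'   `"response"` (\eqn{y - m\hat\pi}) or `"deviance"`.
#' @param enet An [enet_config()] for the selection step.
#' @return A list of class `screening_config`.
#' @export
screening_config <- function(d = NULL,
                             outcome_type = c("count", "binary", "continuous"),
                             c = 1, max_isis_iter = 5L, w = 0.5,
                             cv_folds = 5L, n_lambda = 20L,
                             lambda_min_ratio = 0.05,
                             tune = c("bic", "cv"),
                             refine = c("bic", "none"),
                             ebic_gamma = 0.5,
                             lambda_rule = c("1se", "min"),
                             utility = c("correlation", "glm"),
                             residual_type = c("response", "deviance"),
                             enet = enet_config(w = w)) {
  outcome_type <- match.arg(outcome_type)
  tune <- match.arg(tune)
  refine <- match.arg(refine)
  lambda_rule <- match.arg(lambda_rule)
  utility <- match.arg(utility)
  residual_type <- match.arg(residual_type)
  stopifnot(is.null(d) || d >= 1, max_isis_iter >= 1, cv_folds >= 2)
  enet$w <- w
  structure(list(d = d, outcome_type = outcome_type, c = c,
                 max_isis_iter = as.integer(max_isis_iter), w = w,
                 cv_folds = as.integer(cv_folds),
                 n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 tune = tune, refine = refine,
                 ebic_gamma = ebic_gamma,
                 lambda_rule = lambda_rule,
                 utility = utility, residual_type = residual_type,
                 enet = enet),
            class = "screening_config")
}

marginal_utility <- function(X, target, utility = "correlation",
                             resp = NULL) {
  if (utility == "correlation") {
    s <- sqrt(pmax(colMeans(X * X) - colMeans(X)^2, 0))
    u <- rep(-Inf, ncol(X))
    ok <- s > 1e-12 & sd(target) > 0
    if (any(ok)) {
      u[ok] <- abs(suppressWarnings(cor(X[, ok, drop = FALSE], target)))
    }
    u
  } else {
    # per-feature binomial GLM: deviance explained by each feature alone
    vapply(seq_len(ncol(X)), function(j) {
      if (sd(X[, j]) == 0) return(-Inf)
      f <- stats::glm(cbind(resp$y, resp$m - resp$y) ~ X[, j],
                      family = stats::binomial())
      f$null.deviance - f$deviance
    }, numeric(1L))
  }
}

#' Rank features by marginal utility
#'
#' Features are ordered by descending absolute Pearson correlation with the
#' count response (ties broken by ascending feature index; zero-variance
#' columns last).
#'
#' @param X Samples x features matrix.
#' @param resp A [binomial_response()] or count vector.
#' @param utility `"correlation"` or `"glm"` (see [screening_config()]).
#' @return A tibble with columns `rank`, `index`, `term`, `utility`,
#'   ordered by rank.
#' @export
marginal_ranking <- function(X, resp, utility = "correlation") {
  X <- as_design_matrix(X)
  resp <- as_binomial_response(resp)
  u <- marginal_utility(X, as.numeric(resp$y), utility, resp)
  ord <- order(-u, seq_along(u))
  tibble::tibble(rank = seq_along(ord), index = ord,
                 term = feature_names(X)[ord], utility = u[ord])
}

#' Sure independence screening
#'
#' Keeps the `min(d, p)` features with the highest marginal utility; the
#' screened set is nested in `d`.
#'
#' @inheritParams marginal_ranking
#' @param d Submodel size (>= 1).
#' @return Integer vector of feature indices (in ranking order).
#' @export
sis_screen <- function(X, resp, d, utility = "correlation") {
  stopifnot(d >= 1)
  rk <- marginal_ranking(X, resp, utility)
  rk$index[seq_len(min(d, nrow(rk)))]
}

#' Rank features by correlation with model residuals
#'
#' Used by the iterative step to rescue features that are marginally
#' uncorrelated with the outcome but jointly informative: after a fit, the
#' remaining features are ranked by absolute Pearson correlation with the
#' residual \eqn{r_i = y_i - m\hat\pi_i}.
#'
#' @inheritParams marginal_ranking
#' @param fit An `enet_fit` on the same data (full-length coefficient
#'   vector).
#' @param exclude Integer indices never returned (the current active set).
#' @param residual_type `"response"` or `"deviance"`.
#' @return A tibble like [marginal_ranking()], restricted to non-excluded
#'   features; empty (with a warning) if the residuals have zero variance.
#' @export
residual_ranking <- function(X, resp, fit, exclude = integer(),
                             residual_type = "response") {
  X <- as_design_matrix(X)
  resp <- as_binomial_response(resp)
  pihat <- predict(fit, X, type = "response")
  r <- if (residual_type == "response") {
    resp$y - resp$m * pihat
  } else {
    p_clip <- clip(pihat, 1e-9, 1 - 1e-9)
    dev_i <- -2 * (resp$y * log(p_clip) +
                     (resp$m - resp$y) * log1p(-p_clip)) +
      2 * (ifelse(resp$y == 0, 0, resp$y * log(resp$y / resp$m)) +
             ifelse(resp$y == resp$m, 0,
                    (resp$m - resp$y) * log1p(-resp$y / resp$m)))
    sign(resp$y - resp$m * pihat) * sqrt(pmax(dev_i, 0))
  }
  if (sd(r) == 0) {
    warning("zero-variance residuals (perfect fit); empty ranking",
            call. = FALSE)
    return(tibble::tibble(rank = integer(), index = integer(),
                          term = character(), utility = numeric()))
  }
  keep <- setdiff(seq_len(ncol(X)), exclude)
  u <- marginal_utility(X[, keep, drop = FALSE], r)
  ord <- order(-u, seq_along(u))
  tibble::tibble(rank = seq_along(ord), index = keep[ord],
                 term = feature_names(X)[keep][ord], utility = u[ord])
}

#' Iterative sure independence screening with elastic-net selection
#'
#' The two-step procedure: (1) screen the top `d` features by marginal
#' correlation and select within them by the tuned elastic-net binomial
#' fit, pruned by backward elimination on refit BIC (see
#' [screening_config()]); (2) iteratively recruit the `d - |S|` features
#' most correlated with the current residuals, refit on the union, and
#' repeat until the active set stabilizes or `max_isis_iter` is reached.
#' With `d >= p`, one iteration, `tune = "cv"` and `refine = "none"` this
#' is exactly the elastic-net-only fit on all features; the default
#' elastic-net-only comparator (`d >= p`, one iteration) keeps the same
#' tuning and pruning as ISIS so the two differ only in the screening
#' step.
#'
#' @inheritParams marginal_ranking
#' @param cfg A [screening_config()].
#' @param seed Integer seed (controls the lambda-tuning folds; derived
#'   per-iteration seeds keep the run deterministic).
#' @return An object of class `isis_fit`: `selected` (sorted indices),
#'   `terms`, `fit` (final `enet_fit` with full-length coefficients),
#'   `trace` (per-iteration tibble), `d`, `n_iter`, `stabilized`.
#' @examples
#' sim <- sim_mets_scenario(p = 200, seed = 7)
#' sel <- isis_select(sim$X, sim$resp, screening_config(d = 10), seed = 7)
#' sel$selected
#' @export
isis_select <- function(X, resp, cfg = screening_config(), seed = 1L) {
  X <- as_design_matrix(X)
  resp <- as_binomial_response(resp)
  n <- nrow(X)
  p <- ncol(X)
  if (n < 2 || p < 1) stop("empty data", call. = FALSE)
  d <- cfg$d %||% default_d(n, cfg$outcome_type, cfg$c)
  if (d < 1) stop("`d` must be >= 1", call. = FALSE)

  intercept_only <- function() {
    qlogis(clip(mean(resp$y) / resp$m, 1e-9, 1 - 1e-9))
  }

  fit_candidates <- function(candidates, iter) {
    Xc <- X[, candidates, drop = FALSE]
    if (cfg$tune == "bic") {
      tuned <- tune_path_bic(Xc, resp, cfg)
      lambda_sel <- tuned$lambda
      fit_c <- NULL
      active_c <- candidates[tuned$beta != 0]
    } else {
      lambda_sel <- cv_lambda(Xc, resp, w = cfg$w, n_folds = cfg$cv_folds,
                              seed = derive_seed(seed, iter),
                              n_lambda = cfg$n_lambda,
                              rule = cfg$lambda_rule,
                              cfg = cfg$enet)$lambda_best
      fit_c <- fit_enet(Xc, resp, lambda_sel, cfg$enet)
      active_c <- candidates[fit_c$beta != 0]
    }
    S <- active_c
    if (cfg$refine == "bic" && length(active_c) > 0L) {
      S <- backward_refine(X, resp, active_c, ebic_gamma = cfg$ebic_gamma)
    }
    beta_full <- stats::setNames(numeric(p), feature_names(X))
    if (cfg$refine == "none" && setequal(S, active_c)) {
      if (is.null(fit_c)) {
        fit_c <- fit_enet(Xc, resp, lambda_sel, cfg$enet)
      }
      beta_full[candidates] <- fit_c$beta
      intercept <- fit_c$intercept
      n_iter_c <- fit_c$n_iter
      conv_c <- fit_c$converged
    } else if (length(S) > 0L) {
      # refit the penalized model on the pruned support; drop any
      # coefficients the refit zeroes so selection and fit stay consistent
      fit_s <- fit_enet(X[, S, drop = FALSE], resp, lambda_sel, cfg$enet)
      beta_full[S] <- fit_s$beta
      S <- S[fit_s$beta != 0]
      intercept <- fit_s$intercept
      n_iter_c <- fit_s$n_iter
      conv_c <- fit_s$converged
    } else {
      intercept <- intercept_only()
      n_iter_c <- 0L
      conv_c <- TRUE
    }
    fit_full <- new_enet_fit(intercept, beta_full, lambda_sel, cfg$enet,
                             X, resp, n_iter_c, conv_c)
    list(fit = fit_full, lambda = lambda_sel, active = sort(S))
  }

  trace <- list()
  active <- integer()
  fit <- NULL
  stabilized <- FALSE
  iter <- 0L
  for (iter in seq_len(cfg$max_isis_iter)) {
    if (iter == 1L) {
      candidates <- sort(sis_screen(X, resp, d, cfg$utility))
    } else {
      n_recruit <- d - length(active)
      recruits <- if (n_recruit > 0L) {
        rk <- residual_ranking(X, resp, fit, exclude = active,
                               residual_type = cfg$residual_type)
        rk$index[seq_len(min(n_recruit, nrow(rk)))]
      } else {
        integer()
      }
      candidates <- sort(union(active, recruits))
    }
    res <- fit_candidates(candidates, iter)
    fit <- res$fit
    new_active <- res$active
    trace[[iter]] <- tibble::tibble(
      iteration = iter,
      candidates = list(candidates),
      active = list(new_active),
      lambda = res$lambda,
      deviance = fit$deviance
    )
    if (iter > 1L && setequal(new_active, active)) {
      active <- new_active
      stabilized <- TRUE
      break
    }
    active <- new_active
  }
  structure(list(selected = active,
                 terms = feature_names(X)[active],
                 fit = fit,
                 trace = dplyr::bind_rows(trace),
                 d = d, n_iter = iter, stabilized = stabilized),
            class = "isis_fit")
}

#' @export
print.isis_fit <- function(x, ...) {
  cat("<isis_fit> d =", x$d, ",", x$n_iter, "iteration(s),",
      length(x$selected), "feature(s) selected\n")
  if (length(x$selected)) {
    cat("selected:", paste(x$terms, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname isis_select
#' @param x An `isis_fit`.
#' @param ... Unused.
#' @export
tidy.isis_fit <- function(x, ...) {
  tibble::tibble(term = x$terms, index = x$selected,
                 estimate = unname(x$fit$beta[x$selected]))
}

#' @rdname isis_select
#' @export
glance.isis_fit <- function(x, ...) {
  tibble::tibble(d = x$d, n_selected = length(x$selected),
                 n_iter = x$n_iter, stabilized = x$stabilized,
                 lambda = x$fit$lambda, deviance = x$fit$deviance,
                 converged = x$fit$converged)
}

#' Serialize an ISIS trace as JSON lines
#'
#' One record per iteration: candidate set, active set, lambda, deviance.
#'
#' @param x An `isis_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isis_trace <- function(x, path) {
  lines <- vapply(seq_len(nrow(x$trace)), function(i) {
    jsonlite::toJSON(list(
      iteration = x$trace$iteration[i],
      candidates = x$trace$candidates[[i]],
      active = x$trace$active[[i]],
      lambda = x$trace$lambda[i],
      deviance = x$trace$deviance[i]
    ), auto_unbox = TRUE, digits = NA)
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
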