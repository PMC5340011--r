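# Support refinement by backward elimination on refit BIC.
#
# The elastic-net selection step inherits the ridge component's grouping:
# at any penalty on the path, correlated neighbours of a true feature enter
# together with it, so the path's active sets never visit the sparse truth.
# The unpenalized refit separates them cleanly (decoys add almost no
# deviance once the true feature is in the model), so a BIC comparison over
# refitted supports is selection-consistent where the penalized path is
# not. Backward elimination is guided by Wald z-statistics: one refit per
# step, dropping the least significant feature, and the BIC-minimizing
# support along the greedy sequence is returned.

# saturated negative log-likelihood without the binomial constant
sat_nll_nocon <- function(resp) {
  y <- resp$y
  m <- resp$m
  p <- y / m
  -(sum(ifelse(y == 0, 0, y * log(p))) +
      sum(ifelse(y == m, 0, (m - y) * log(1 - p))))
}

# Unpenalized binomial-trials GLM refit (Newton); global column indices.
glm_refit <- function(X, resp, support, prob_clip = 1e-9) {
  r <- glm_binom_cpp(X[, support, drop = FALSE], as.numeric(resp$y),
                     resp$m, 100L, 1e-8, prob_clip)
  r$deviance <- 2 * (r$nll - sat_nll_nocon(resp))
  r
}

# Backward elimination from `support`; returns the subset (possibly empty)
# minimizing deviance + penalty * |S| along the Wald-guided elimination
# sequence. The default penalty is the EBIC penalty log(n) + 2*gamma*log(p)
# with the full feature count p, which accounts for the selection having
# searched all p features (plain BIC under-penalizes after screening).
backward_refine <- function(X, resp, support, penalty = NULL,
                            ebic_gamma = 0.5) {
  penalty <- penalty %||%
    (log(nrow(X)) + 2 * ebic_gamma * log(ncol(X)))
  sat <- sat_nll_nocon(resp)
  p0 <- clip(mean(resp$y) / resp$m, 1e-9, 1 - 1e-9)
  nll0 <- -(sum(resp$y) * log(p0) + sum(resp$m - resp$y) * log(1 - p0))
  sets <- list(integer())
  bics <- 2 * (nll0 - sat)
  cur <- support
  while (length(cur) > 0L) {
    r <- glm_refit(X, resp, cur)
    sets[[length(sets) + 1L]] <- cur
    bics <- c(bics, r$deviance + penalty * length(cur))
    if (length(cur) == 1L) break
    z <- abs(r$coef[-1L]) / r$se[-1L]
    cur <- cur[-which.min(z)]
  }
  sort(sets[[which.min(bics)]])
}

# BIC over the penalized path: deviance + log(n) * df at each lambda,
# ties resolved toward the larger (sparser) penalty. Returns the chosen
# lambda together with the path coefficients at that lambda, so callers
# need not refit to recover the active set.
tune_path_bic <- function(X, resp, cfg) {
  lam <- lambda_path(X, resp, cfg$w, cfg$n_lambda,
                     cfg$lambda_min_ratio %||% 0.05)
  cfg_path <- cfg$enet
  cfg_path$tol <- max(cfg_path$tol, 1e-5)  # scan precision; pruning follows
  cfg_path$max_iter <- min(cfg_path$max_iter, 25L)
  path <- enet_path_fit(X, resp, lam, cfg_path)
  n <- nrow(X)
  sat <- saturated_negloglik(resp)
  bic <- vapply(seq_along(lam), function(l) {
    nz <- which(path$beta[, l] != 0)
    dev <- 2 * (negloglik(path$intercept[l], path$beta[nz, l],
                          X[, nz, drop = FALSE], resp,
                          cfg$enet$prob_clip) - sat)
    dev + log(n) * length(nz)
  }, numeric(1L))
  l <- which(bic <= min(bic) + 1e-9)[1L]
  list(lambda = path$lambda[l], beta = path$beta[, l],
       intercept = path$intercept[l])
}

bic_path_lambda <- function(X, resp, cfg) tune_path_bic(X, resp, cfg)$lambda
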