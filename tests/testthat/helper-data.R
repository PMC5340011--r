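# Small deterministic fixtures built in code.

# random binomial-trials regression instance
make_glm_instance <- function(seed, n = 50L, p = 5L, m = 5L,
                              beta = NULL, intercept = 0.2) {
  isisen:::local_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    beta <- beta %||% c(1, -0.5, rep(0, p - 2))[seq_len(p)]
    pi <- plogis(intercept + drop(X %*% beta))
    y <- rbinom(n, m, pi)
    list(X = X, resp = binomial_response(y, m), beta = beta,
         intercept = intercept)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# hand-built bootstrap_selection object for threshold tests
fake_selection <- function(counts, B) {
  p <- length(counts)
  structure(list(B = B, counts = stats::setNames(as.integer(counts),
                                                 paste0("f", seq_len(p))),
                 replicates = list(), terms = paste0("f", seq_len(p)),
                 seed = 0L),
            class = "bootstrap_selection")
}

# brute-force Mann-Whitney AUC by pair enumeration
auc_brute <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}
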