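# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library functions never perturb a
# user's stream.
local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Counter-based child seed: deterministic, order-independent, < 2^31.
derive_seed <- function(seed, counter) {
  (as.double(seed) * 48271 + as.double(counter) * 65537) %% 2147483629
}

sigmoid <- function(x) 1 / (1 + exp(-x))

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

as_design_matrix <- function(X) {
  if (is.data.frame(X)) {
    X <- as.matrix(X)
  }
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("`X` must be a numeric matrix or data frame of samples x features",
         call. = FALSE)
  }
  storage.mode(X) <- "double"
  X
}

feature_names <- function(X) {
  colnames(X) %||% paste0("V", seq_len(ncol(X)))
}
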