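#' K-nearest-neighbour imputation in probe space
#'
#' Missing methylation values are imputed from the `k` most similar probes
#' (CpG sites), not from similar samples: for a missing entry the imputed
#' value is the unweighted mean of the k nearest probes' values in that
#' sample. Probe-probe distance is Euclidean over the samples where both
#' probes are observed, rescaled by `sqrt(n / overlap)` so probes with few
#' shared observations are not spuriously close.
#'
#' A neighbour is usable for an entry only if it is itself observed in that
#' sample. If fewer than `k` usable neighbours exist the available ones are
#' used with a warning; if none exist, or a probe is entirely missing, an
#' error names the probe.
#'
#' @param mat A [methylation_matrix()] (or numeric samples x probes matrix).
#' @param k Number of neighbouring probes (default 10).
#' @return A matrix of the same class with no missing values; observed
#'   entries are unchanged.
#' @export
impute_knn <- function(mat, k = 10L) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L) {
    stop("`k` must be a single integer >= 1", call. = FALSE)
  }
  kind <- methylation_kind(mat)
  X <- unclass(as_design_matrix(mat))
  attr(X, "kind") <- NULL
  if (!anyNA(X)) {
    return(mat)
  }
  n <- nrow(X)
  probes <- colnames(X) %||% paste0("col", seq_len(ncol(X)))
  all_missing <- colSums(!is.na(X)) == 0L
  if (any(all_missing)) {
    stop("probe entirely missing: ", probes[all_missing][1L], call. = FALSE)
  }
  obs <- !is.na(X)
  X0 <- X
  X0[!obs] <- 0
  out <- X
  short_neighbours <- FALSE
  for (j in which(colSums(!obs) > 0L)) {
    # scaled Euclidean distance from probe j to every other probe
    dj <- X0 - X0[, j]
    both <- obs & obs[, j]
    ss <- colSums((dj * both)^2)
    overlap <- colSums(both)
    dist <- sqrt(ss * n / pmax(overlap, 1L))
    dist[overlap == 0L] <- Inf
    dist[j] <- Inf
    ord <- order(dist, seq_along(dist))
    for (i in which(!obs[, j])) {
      usable <- ord[obs[i, ord] & is.finite(dist[ord])]
      if (length(usable) == 0L) {
        stop("no usable neighbour for probe ", probes[j],
             " in sample ", i, call. = FALSE)
      }
      if (length(usable) < k) short_neighbours <- TRUE
      nb <- usable[seq_len(min(k, length(usable)))]
      out[i, j] <- mean(X[i, nb])
    }
  }
  if (short_neighbours) {
    warning("fewer than k usable neighbours for some entries; used all available",
            call. = FALSE)
  }
  if (inherits(mat, "methylation_matrix")) {
    methylation_matrix(out, kind = kind)
  } else {
    out
  }
}
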