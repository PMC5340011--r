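# Bolasso-style bootstrap stability selection.

#' Bootstrap stability selection
#'
#' Runs [isis_select()] on `B` nonparametric bootstrap resamples (rows of
#' `X` and `y` drawn jointly with replacement, size `n`) and tabulates how
#' often each feature enters the selected set. Per-replicate seeds are
#' derived from the master seed by a counter scheme, so the result does not
#' depend on execution order. A replicate whose resample is degenerate (for
#' example a constant response) is recorded as an empty selection with a
#' warning; `B` is unchanged.
#'
#' @inheritParams isis_select
#' @param B Number of bootstrap replicates (default 100).
#' @param seed Master seed.
#' @return An object of class `bootstrap_selection`: `B`, `counts` (named
#'   integer vector over all features), `replicates` (list of selected index
#'   vectors), `terms`.
#' @examples
#' sim <- sim_mets_scenario(p = 120, seed = 3)
#' bs <- bootstrap_select(sim$X, sim$resp, screening_config(d = 10),
#'                        B = 5, seed = 3)
#' frequency_table(bs, top_k = 5)
#' @export
bootstrap_select <- function(X, resp, cfg = screening_config(), B = 100L,
                             seed = 1L) {
  X <- as_design_matrix(X)
  resp <- as_binomial_response(resp)
  B <- as.integer(B)
  stopifnot(B >= 1L)
  n <- nrow(X)
  p <- ncol(X)
  counts <- stats::setNames(integer(p), feature_names(X))
  replicates <- vector("list", B)
  for (b in seq_len(B)) {
    rep_seed <- derive_seed(seed, b)
    idx <- local_seed(rep_seed, sample.int(n, n, replace = TRUE))
    sel <- tryCatch({
      rb <- binomial_response(resp$y[idx], resp$m)
      if (var(rb$y) == 0) stop("constant bootstrap response")
      isis_select(X[idx, , drop = FALSE], rb, cfg,
                  seed = derive_seed(rep_seed, 1L))$selected
    }, error = function(e) {
      warning("bootstrap replicate ", b, " failed (",
              conditionMessage(e), "); recorded as empty selection",
              call. = FALSE)
      integer()
    })
    replicates[[b]] <- sel
    counts[sel] <- counts[sel] + 1L
  }
  structure(list(B = B, counts = counts, replicates = replicates,
                 terms = feature_names(X), seed = seed),
            class = "bootstrap_selection")
}

#' @export
print.bootstrap_selection <- function(x, ...) {
  cat("<bootstrap_selection> B =", x$B, ",",
      sum(x$counts > 0L), "feature(s) ever selected\n")
  print(frequency_table(x, top_k = 10L))
  invisible(x)
}

#' Bootstrap selection frequency table
#'
#' @param sel A [bootstrap_select()] result.
#' @param top_k Number of rows to keep (features with zero count are
#'   dropped first).
#' @return A tibble with columns `term`, `index`, `count`, `proportion`,
#'   in descending count order (ties: ascending feature index).
#' @export
frequency_table <- function(sel, top_k = 20L) {
  stopifnot(top_k >= 1)
  nz <- unname(which(sel$counts > 0L))
  ord <- nz[order(-sel$counts[nz], nz)]
  ord <- ord[seq_len(min(top_k, length(ord)))]
  tibble::tibble(term = sel$terms[ord], index = ord,
                 count = unname(sel$counts[ord]),
                 proportion = unname(sel$counts[ord]) / sel$B)
}

#' @rdname frequency_table
#' @param x A `bootstrap_selection`.
#' @param ... Unused.
#' @export
tidy.bootstrap_selection <- function(x, ...) {
  frequency_table(x, top_k = max(1L, sum(x$counts > 0L)))
}

#' @rdname frequency_table
#' @export
glance.bootstrap_selection <- function(x, ...) {
  tibble::tibble(B = x$B, n_ever_selected = sum(x$counts > 0L),
                 mean_set_size = mean(lengths(x$replicates)),
                 max_count = if (any(x$counts > 0)) max(x$counts) else 0L)
}

#' Threshold a bootstrap selection into a final feature set
#'
#' Two stability criteria:
#' \describe{
#'   \item{`half`}{keep features selected in at least half of the `B`
#'     bootstrap replicates (`counts >= B/2`);}
#'   \item{`gap`}{sort the positive counts in decreasing order, find the
#'     single largest consecutive drop, and keep the head above it;}
#'   \item{`both`}{the intersection of the two, with both partitions
#'     reported.}
#' }
#'
#' @param sel A [bootstrap_select()] result.
#' @param rule `"half"`, `"gap"`, or `"both"`.
#' @return A list with `selected` (sorted indices), `terms`, `rule`, and a
#'   `diagnostics` tibble (per-rule sets and the gap location when used).
#' @export
threshold_select <- function(sel, rule = c("half", "gap", "both")) {
  rule <- match.arg(rule)
  if (all(sel$counts == 0L)) {
    warning("all bootstrap counts are zero; empty selection", call. = FALSE)
    return(list(selected = integer(), terms = character(), rule = rule,
                diagnostics = tibble::tibble()))
  }
  half_set <- function() sort(unname(which(sel$counts >= sel$B / 2)))
  gap_set <- function() {
    nz <- unname(which(sel$counts > 0L))
    ord <- nz[order(-sel$counts[nz], nz)]
    cs <- sel$counts[ord]
    if (length(cs) == 1L) return(sort(ord))
    drops <- cs[-length(cs)] - cs[-1L]
    if (max(drops) == 0L || sum(drops == max(drops)) > 1L) {
      warning("no unique largest frequency drop; gap rule selects nothing",
              call. = FALSE)
      return(integer())
    }
    sort(ord[seq_len(which.max(drops))])
  }
  h <- if (rule %in% c("half", "both")) half_set() else NULL
  g <- if (rule %in% c("gap", "both")) gap_set() else NULL
  selected <- switch(rule, half = h, gap = g, both = intersect(h, g))
  diagnostics <- tibble::tibble(
    rule = c(if (!is.null(h)) "half", if (!is.null(g)) "gap"),
    n_selected = c(if (!is.null(h)) length(h), if (!is.null(g)) length(g)),
    members = c(if (!is.null(h)) list(h), if (!is.null(g)) list(g))
  )
  list(selected = sort(selected), terms = sel$terms[sort(selected)],
       rule = rule, diagnostics = diagnostics)
}

#' Write a frequency table as TSV
#'
#' Columns `feature_id`, `probe_id`, `count`, `proportion`.
#'
#' @param sel A `bootstrap_selection`.
#' @param path Output path.
#' @param top_k Rows to keep.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(sel, path, top_k = 50L) {
  tab <- frequency_table(sel, top_k)
  out <- tibble::tibble(feature_id = tab$index, probe_id = tab$term,
                        count = tab$count, proportion = tab$proportion)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Plot bootstrap selection frequencies
#'
#' Bar chart of the most frequently selected features with the half-of-
#' bootstraps threshold drawn as a dashed line.
#'
#' @param object A `bootstrap_selection`.
#' @param top_k Features to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bootstrap_selection <- function(object, top_k = 20L, ...) {
  tab <- frequency_table(object, top_k)
  tab$term <- factor(tab$term, levels = rev(tab$term))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$term, y = .data$proportion)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "selection proportion",
                  title = paste0("Bootstrap selection frequencies (B = ",
                                 object$B, ")")) +
    ggplot2::theme_minimal()
}
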