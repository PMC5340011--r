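# Predictive evaluation: binary and Hand-Till multiclass AUC, k-fold CV.

#' Binary AUC (Mann-Whitney estimator)
#'
#' The probability that a randomly chosen positive scores higher than a
#' randomly chosen negative, with ties counted 1/2 — computed from mid-ranks
#' so it is exact under ties.
#'
#' @param scores Numeric score vector (higher = more positive).
#' @param labels Logical/0-1 vector; both classes must be present.
#' @return AUC in \[0, 1\].
#' @examples
#' binary_auc(c(0.9, 0.4, 0.35, 0.8), c(1, 0, 1, 0)) # 0.75
#' @export
binary_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Hand-Till multiclass AUC
#'
#' For an ordinal outcome scored by a single scalar (here the fitted
#' probability \eqn{\hat\pi}), the measure is
#' \deqn{M = \frac{2}{c(c-1)} \sum_{i < j} \hat A(i, j)}
#' over the \eqn{c} observed classes, where \eqn{\hat A(i,j)} is the
#' two-class AUC of the score separating class \eqn{j} (treated as positive
#' when \eqn{j > i}) from class \eqn{i}. Hand and Till define
#' \eqn{\hat A(i,j) = [A(i|j) + A(j|i)]/2} from per-class probability
#' columns; with one shared score those two terms coincide with the
#' two-class AUC, so the average reduces to it.
#'
#' @param scores Numeric scores.
#' @param y Class labels (integers, e.g. the 0-5 index); at least two
#'   distinct classes.
#' @return M in \[0, 1\].
#' @export
hand_till_auc <- function(scores, y) {
  stopifnot(length(scores) == length(y), !anyNA(scores), !anyNA(y))
  classes <- sort(unique(y))
  if (length(classes) < 2L) {
    stop("at least two distinct classes required", call. = FALSE)
  }
  pairs <- utils::combn(classes, 2L)
  a <- vapply(seq_len(ncol(pairs)), function(k) {
    lo <- pairs[1L, k]
    hi <- pairs[2L, k]
    keep <- y %in% c(lo, hi)
    binary_auc(scores[keep], y[keep] == hi)
  }, numeric(1L))
  mean(a)
}

#' Cross-validated selection-and-prediction evaluation
#'
#' Seeded unstratified k-fold split; within each fold, [isis_select()] runs
#' on the training folds only (lambda tuned inside, so no leakage), held-out
#' subjects are scored by the fitted \eqn{\hat\pi}, and both the Hand-Till
#' multiclass AUC on the 0-5 index and the binary AUC on the index >= 3
#' dichotomy are computed. A test fold with a single class gets `NA` for
#' that AUC (with a warning) and is excluded from the mean.
#'
#' @inheritParams isis_select
#' @param k Number of folds (default 5).
#' @return An object of class `cv_evaluation` with `folds` (per-fold
#'   tibble: n_selected, auc_binary, auc_multiclass) and `summary` (means
#'   and sds).
#' @export
cv_evaluate <- function(X, resp, cfg = screening_config(), k = 5L,
                        seed = 1L) {
  X <- as_design_matrix(X)
  resp <- as_binomial_response(resp)
  k <- as.integer(k)
  n <- nrow(X)
  stopifnot(k >= 2L, n >= k)
  fold_id <- local_seed(seed, sample(rep_len(seq_len(k), n)))
  rows <- purrr::map(seq_len(k), function(f) {
    test <- fold_id == f
    sel <- isis_select(X[!test, , drop = FALSE],
                       binomial_response(resp$y[!test], resp$m),
                       cfg, seed = derive_seed(seed, 1000L + f))
    scores <- predict(sel$fit, X[test, , drop = FALSE], type = "response")
    ytest <- resp$y[test]
    auc_mc <- if (length(unique(ytest)) >= 2L) {
      hand_till_auc(scores, ytest)
    } else {
      warning("fold ", f, " has a single index class; multiclass AUC is NA",
              call. = FALSE)
      NA_real_
    }
    ybin <- mets_binary(ytest)
    auc_bin <- if (length(unique(ybin)) >= 2L) {
      binary_auc(scores, ybin)
    } else {
      warning("fold ", f, " has a single binary class; binary AUC is NA",
              call. = FALSE)
      NA_real_
    }
    tibble::tibble(fold = f, n_test = sum(test),
                   n_selected = length(sel$selected),
                   auc_binary = auc_bin, auc_multiclass = auc_mc)
  })
  folds <- dplyr::bind_rows(rows)
  summary <- tibble::tibble(
    k = k,
    mean_n_selected = mean(folds$n_selected),
    sd_n_selected = sd(folds$n_selected),
    mean_auc_binary = mean(folds$auc_binary, na.rm = TRUE),
    mean_auc_multiclass = mean(folds$auc_multiclass, na.rm = TRUE)
  )
  structure(list(folds = folds, summary = summary, seed = seed),
            class = "cv_evaluation")
}

#' @export
print.cv_evaluation <- function(x, ...) {
  cat("<cv_evaluation> ", nrow(x$folds), "-fold cross-validation\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname cv_evaluate
#' @param x A `cv_evaluation`.
#' @param ... Unused.
#' @export
tidy.cv_evaluation <- function(x, ...) x$folds

#' @rdname cv_evaluate
#' @export
glance.cv_evaluation <- function(x, ...) x$summary

#' Plot per-fold cross-validated AUCs
#'
#' @param object A `cv_evaluation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_evaluation <- function(object, ...) {
  long <- tidyr::pivot_longer(object$folds,
                              c("auc_binary", "auc_multiclass"),
                              names_to = "measure", values_to = "auc")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$fold), y = .data$auc,
                                     fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "fold", y = "AUC") +
    ggplot2::theme_minimal()
}

#' Write a cross-validation report
#'
#' JSON plus TSV with the per-configuration summary rows (number of selected
#' variables with sd, average binary AUC, average multiclass AUC).
#'
#' @param reports Named list of `cv_evaluation` objects (one per
#'   configuration, e.g. elastic-net-only and ISIS at two submodel sizes).
#' @param path_json,path_tsv Output paths (either may be `NULL`).
#' @return Invisibly, the combined summary tibble.
#' @export
write_cv_report <- function(reports, path_json = NULL, path_tsv = NULL) {
  stopifnot(length(names(reports)) == length(reports))
  tab <- dplyr::bind_rows(
    purrr::imap(reports, function(r, nm) {
      dplyr::mutate(r$summary, configuration = nm, .before = 1L)
    })
  )
  if (!is.null(path_json)) {
    jsonlite::write_json(
      purrr::map(reports, function(r) {
        list(summary = as.list(r$summary), folds = r$folds)
      }),
      path_json, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  if (!is.null(path_tsv)) {
    readr::write_tsv(tab, path_tsv, progress = FALSE)
  }
  invisible(tab)
}
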