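#' Methylation matrix container
#'
#' A samples x probes numeric matrix with unique sample and probe identifiers
#' and a value kind: `"beta"` (proportions in \[0,1\]) or `"m"` (logit scale).
#'
#' @param values Numeric matrix, samples in rows, probes in columns. Row and
#'   column names are used as identifiers; defaults are generated if absent.
#' @param kind `"beta"` or `"m"`.
#' @return An object of class `methylation_matrix` (a numeric matrix with a
#'   `kind` attribute).
#' @examples
#' methylation_matrix(matrix(runif(6), 3, 2), kind = "beta")
#' @export
methylation_matrix <- function(values, kind = c("beta", "m")) {
  kind <- match.arg(kind)
  values <- as_design_matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("sample", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("cg", sprintf("%08d", seq_len(ncol(values))))
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate sample IDs", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate probe IDs", call. = FALSE)
  }
  if (kind == "beta") {
    v <- values[!is.na(values)]
    if (length(v) && (any(v < 0) || any(v > 1))) {
      stop("Beta values must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(values, kind = kind, class = c("methylation_matrix", "matrix",
                                           "array"))
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat("<methylation_matrix> ", nrow(x), " samples x ", ncol(x), " probes (",
      attr(x, "kind"), " values), ", sum(is.na(x)), " missing\n", sep = "")
  invisible(x)
}

methylation_kind <- function(x) attr(x, "kind") %||% "m"

#' Convert a methylation matrix between Beta and M scales
#'
#' @param mat A [methylation_matrix()].
#' @param eps Clip bound used by [beta_to_m()].
#' @return A `methylation_matrix` on the other scale.
#' @export
convert_methylation <- function(mat, eps = 1e-6) {
  kind <- methylation_kind(mat)
  vals <- unclass(mat)
  attr(vals, "kind") <- NULL
  if (kind == "beta") {
    methylation_matrix(beta_to_m(vals, eps), kind = "m")
  } else {
    methylation_matrix(m_to_beta(vals), kind = "beta")
  }
}

#' Read a methylation matrix from TSV/CSV
#'
#' The file must have a header row and row labels in the first column. Empty
#' cells and `"NA"` are parsed as missing. Whatever the on-disk orientation,
#' the returned matrix is samples x probes.
#'
#' @param path File path; delimiter inferred from the extension (`.csv` is
#'   comma, anything else tab) unless `delim` is given.
#' @param orientation `"samples_by_probes"` (default) or `"probes_by_samples"`.
#' @param kind Value kind stored in the result, `"beta"` or `"m"`.
#' @param delim Optional explicit field delimiter.
#' @return A [methylation_matrix()].
#' @export
read_methylation_matrix <- function(path,
                                    orientation = c("samples_by_probes",
                                                    "probes_by_samples"),
                                    kind = c("beta", "m"),
                                    delim = NULL) {
  orientation <- match.arg(orientation)
  kind <- match.arg(kind)
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, col_names = TRUE,
                          col_types = readr::cols(.default = "c"),
                          na = c("", "NA"), progress = FALSE,
                          show_col_types = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0L) {
    stop("parse error at line ", probs$row[1L] + 1L, ": ",
         probs$expected[1L], call. = FALSE)
  }
  if (ncol(df) < 2L) {
    stop("expected row labels plus at least one data column", call. = FALSE)
  }
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate row IDs: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  num <- suppressWarnings(
    vapply(df[-1L], function(col) as.numeric(col), numeric(nrow(df)))
  )
  num <- matrix(num, nrow = nrow(df))
  introduced <- !is.na(as.matrix(df[-1L])) & is.na(num)
  if (any(introduced)) {
    bad <- which(introduced, arr.ind = TRUE)[1L, ]
    stop("non-numeric cell at line ", bad[["row"]] + 1L, ", column ",
         names(df)[-1L][bad[["col"]]], call. = FALSE)
  }
  rownames(num) <- ids
  colnames(num) <- names(df)[-1L]
  if (anyDuplicated(colnames(num))) {
    stop("duplicate column IDs", call. = FALSE)
  }
  if (orientation == "probes_by_samples") {
    num <- t(num)
  }
  methylation_matrix(num, kind = kind)
}

#' Write a methylation matrix as samples x probes TSV
#'
#' Values are written with 6 significant digits; missing entries as `NA`.
#'
#' @param mat A [methylation_matrix()] (or plain matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_methylation_matrix <- function(mat, path) {
  vals <- signif(unclass(mat), 6L)
  df <- tibble::as_tibble(as.data.frame(vals), rownames = "sample_id")
  readr::write_tsv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' CSV with one row per subject and named columns for the five
#' metabolic-syndrome component measurements (`waist_cm`, `glucose_mgdl`,
#' `hdl_mgdl`, `sbp_mmhg`, `dbp_mmhg`, `tg_mgdl`) and the four medication
#' flags (`med_diabetes`, `med_cholesterol`, `med_htn`, `med_tg`).
#'
#' @param path CSV path.
#' @return A tibble with the columns above (flags as logical).
#' @export
read_phenotypes <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        na = c("", "NA"))
  needed <- c(mets_measure_cols, mets_flag_cols)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("phenotype table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- dplyr::mutate(df, dplyr::across(dplyr::all_of(mets_flag_cols),
                                        as.logical))
  bad <- vapply(df[mets_measure_cols],
                function(col) any(!is.na(col) & col < 0), logical(1L))
  if (any(bad)) {
    stop("negative measurement in column ",
         mets_measure_cols[bad][1L], call. = FALSE)
  }
  df
}
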