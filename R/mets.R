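mets_measure_cols <- c("waist_cm", "glucose_mgdl", "hdl_mgdl",
                       "sbp_mmhg", "dbp_mmhg", "tg_mgdl")
mets_flag_cols <- c("med_diabetes", "med_cholesterol", "med_htn", "med_tg")

#' Metabolic-syndrome index (0-5)
#'
#' Counts how many of the five metabolic-syndrome component conditions each
#' subject satisfies:
#' \itemize{
#'   \item abdominal obesity: waist circumference > 102 cm;
#'   \item high fasting glucose: >= 100 mg/dl, or on diabetes medication;
#'   \item reduced HDL cholesterol: < 40 mg/dl, or on cholesterol medication;
#'   \item hypertension: SBP > 130 mmHg or DBP > 85 mmHg, or on
#'     antihypertensive medication;
#'   \item hypertriglyceridemia: >= 150 mg/dl, or on triglyceride medication.
#' }
#' Boundary semantics follow these inequalities literally: a waist of exactly
#' 102 cm does not count, a glucose of exactly 100 mg/dl does.
#'
#' Subjects with any missing component are an error: studies using this index
#' exclude such subjects rather than impute the phenotype.
#'
#' @param pheno Data frame with the measurement and medication-flag columns
#'   named as in [read_phenotypes()]. Flag columns may be omitted (taken as
#'   `FALSE`).
#' @return `pheno` as a tibble with an integer `mets_index` column appended.
#' @examples
#' rec <- tibble::tibble(waist_cm = 110, glucose_mgdl = 120, hdl_mgdl = 35,
#'                       sbp_mmhg = 140, dbp_mmhg = 90, tg_mgdl = 200)
#' mets_index(rec)$mets_index # 5
#' @export
mets_index <- function(pheno) {
  pheno <- tibble::as_tibble(pheno)
  missing_cols <- setdiff(mets_measure_cols, names(pheno))
  if (length(missing_cols)) {
    stop("missing measurement columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (fc in mets_flag_cols) {
    if (!fc %in% names(pheno)) pheno[[fc]] <- FALSE
  }
  comp <- pheno[c(mets_measure_cols, mets_flag_cols)]
  incomplete <- !stats::complete.cases(comp)
  if (any(incomplete)) {
    stop("missing metabolic-syndrome component for subject(s) ",
         paste(utils::head(which(incomplete), 5L), collapse = ", "),
         "; exclude them before scoring", call. = FALSE)
  }
  neg <- vapply(comp[mets_measure_cols], function(col) any(col < 0),
                logical(1L))
  if (any(neg)) {
    stop("negative measurement in column ", mets_measure_cols[neg][1L],
         call. = FALSE)
  }
  idx <- (comp$waist_cm > 102) +
    (comp$glucose_mgdl >= 100 | comp$med_diabetes) +
    (comp$hdl_mgdl < 40 | comp$med_cholesterol) +
    (comp$sbp_mmhg > 130 | comp$dbp_mmhg > 85 | comp$med_htn) +
    (comp$tg_mgdl >= 150 | comp$med_tg)
  dplyr::mutate(pheno, mets_index = as.integer(idx))
}

#' Dichotomize the metabolic-syndrome index
#'
#' Standard metabolic syndrome: at least three of the five conditions.
#'
#' @param index Integer vector with values in 0..5.
#' @return Integer vector of 0/1.
#' @examples
#' mets_binary(c(2, 3, 5)) # 0 1 1
#' @export
mets_binary <- function(index) {
  if (any(is.na(index)) || any(index < 0 | index > 5 | index != round(index))) {
    stop("`index` must contain integers in 0..5", call. = FALSE)
  }
  as.integer(index >= 3)
}
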