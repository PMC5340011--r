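# Beta/M transforms, KNN imputation, MetS index, matrix IO.

test_that("beta_to_m matches the logit-base-2 transform", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  eps <- 1e-6
  expect_equal(beta_to_m(0, eps = eps), log2(eps / (1 - eps)))
  expect_equal(beta_to_m(1, eps = eps), log2((1 - eps) / eps))
  expect_error(beta_to_m(1.2), "\\[0, 1\\]")
  expect_error(beta_to_m(0.5, eps = 0.6), "eps")
  # strictly increasing on the unclipped domain
  b <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(beta_to_m(b)) > 0))
})

test_that("m_to_beta inverts beta_to_m within 1e-12", {
  expect_equal(m_to_beta(0), 0.5)
  expect_equal(m_to_beta(2), 0.8)
  b <- seq(0.001, 0.999, length.out = 101)
  expect_equal(m_to_beta(beta_to_m(b)), b, tolerance = 1e-12)
  expect_error(m_to_beta(Inf), "finite")
})

test_that("convert_methylation round-trips a matrix between scales", {
  m <- methylation_matrix(matrix(runif(12), 3, 4), kind = "beta")
  m2 <- convert_methylation(convert_methylation(m))
  expect_equal(unclass(m2), unclass(m), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(attr(convert_methylation(m), "kind"), "m")
})

test_that("mets_index implements the five component conditions", {
  rec <- function(waist, glu, hdl, sbp, dbp, tg, ...) {
    tibble::tibble(waist_cm = waist, glucose_mgdl = glu, hdl_mgdl = hdl,
                   sbp_mmhg = sbp, dbp_mmhg = dbp, tg_mgdl = tg, ...)
  }
  expect_identical(mets_index(rec(110, 120, 35, 140, 90, 200))$mets_index, 5L)
  expect_identical(mets_index(rec(90, 99, 45, 120, 80, 100))$mets_index, 0L)
  # boundary semantics: strict > for waist and BP, >= for glucose and TG,
  # < for HDL -- the exact-boundary record satisfies only two conditions
  expect_identical(mets_index(rec(102, 100, 40, 130, 85, 150))$mets_index, 2L)
  # medication flags count as satisfying their condition
  expect_identical(
    mets_index(rec(90, 99, 45, 120, 80, 100, med_htn = TRUE))$mets_index, 1L)
  expect_error(mets_index(rec(NA, 99, 45, 120, 80, 100)), "missing")
  expect_error(mets_index(rec(-1, 99, 45, 120, 80, 100)), "negative")
})

test_that("mets_index is monotone in each component condition", {
  base <- tibble::tibble(waist_cm = 90, glucose_mgdl = 90, hdl_mgdl = 50,
                         sbp_mmhg = 120, dbp_mmhg = 80, tg_mgdl = 100)
  worse <- list(waist_cm = 110, glucose_mgdl = 120, hdl_mgdl = 30,
                sbp_mmhg = 140, tg_mgdl = 200)
  i0 <- mets_index(base)$mets_index
  for (nm in names(worse)) {
    b <- base
    b[[nm]] <- worse[[nm]]
    expect_gte(mets_index(b)$mets_index, i0)
  }
})

test_that("mets_binary dichotomizes at three conditions", {
  expect_identical(mets_binary(c(0L, 2L, 3L, 5L)), c(0L, 0L, 1L, 1L))
  expect_error(mets_binary(6L), "0\\.\\.5")
  expect_error(mets_binary(-1L), "0\\.\\.5")
})

test_that("impute_knn leaves complete matrices untouched", {
  m <- methylation_matrix(matrix(runif(40), 5, 8), kind = "beta")
  expect_identical(impute_knn(m, k = 3), m)
})

test_that("impute_knn fills from nearest probes", {
  # probe B duplicates probe A; with k = 1, A's hole is filled from B
  v <- cbind(A = c(NA, 0.2, 0.4, 0.6), B = c(0.8, 0.2, 0.4, 0.6),
             C = c(0.1, 0.9, 0.1, 0.9))
  out <- impute_knn(methylation_matrix(v, kind = "beta"), k = 1)
  expect_equal(out[1, "A"], 0.8, ignore_attr = TRUE)
  expect_equal(out[-1, ], v[-1, ], ignore_attr = TRUE)

  # two equidistant neighbours holding 0.2 and 0.4 average to 0.3
  v2 <- cbind(A = c(NA, 0.5, 0.5), B = c(0.2, 0.6, 0.4), C = c(0.4, 0.4, 0.6))
  out2 <- impute_knn(methylation_matrix(v2, kind = "beta"), k = 2)
  expect_equal(out2[1, "A"], 0.3, ignore_attr = TRUE)
})

test_that("impute_knn errors on an all-missing probe and warns when short", {
  v <- cbind(A = c(NA, NA, NA), B = c(0.2, 0.6, 0.4))
  expect_error(impute_knn(methylation_matrix(v, kind = "beta")), "A")
  v2 <- cbind(A = c(NA, 0.5, 0.5), B = c(0.2, 0.6, 0.4))
  expect_warning(impute_knn(methylation_matrix(v2, kind = "beta"), k = 5),
                 "fewer than k")
})

test_that("matrix reader handles orientation, NA cells and bad input", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "m.tsv")
  writeLines(c("sample_id\tcg1\tcg2",
               "s1\t0.1\t0.9",
               "s2\tNA\t0.5",
               "s3\t0.3\t"), f)
  m <- read_methylation_matrix(f, kind = "beta")
  expect_equal(dim(m), c(3L, 2L))
  expect_true(is.na(m[2, 1]) && is.na(m[3, 2]))
  expect_equal(m[1, 2], 0.9, ignore_attr = TRUE)

  mt <- read_methylation_matrix(f, orientation = "probes_by_samples",
                                kind = "beta")
  expect_equal(dim(mt), c(2L, 3L))
  expect_equal(unclass(mt), t(unclass(m)), ignore_attr = TRUE)

  fdup <- file.path(dir, "dup.tsv")
  writeLines(c("id\tcg1", "s1\t0.1", "s1\t0.2"), fdup)
  expect_error(read_methylation_matrix(fdup), "duplicate")

  fbad <- file.path(dir, "bad.tsv")
  writeLines(c("id\tcg1", "s1\t0.1", "s2\toops"), fbad)
  expect_error(read_methylation_matrix(fbad), "line 3")
})

test_that("matrix writer round-trips through the reader", {
  dir <- withr::local_tempdir()
  m <- methylation_matrix(matrix(runif(20), 4, 5), kind = "beta")
  m[2, 3] <- NA
  f <- file.path(dir, "rt.tsv")
  write_methylation_matrix(m, f)
  back <- read_methylation_matrix(f, kind = "beta")
  expect_equal(unclass(back), unclass(m), tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("phenotype reader validates columns and flags", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "ph.csv")
  writeLines(c(
    "waist_cm,glucose_mgdl,hdl_mgdl,sbp_mmhg,dbp_mmhg,tg_mgdl,med_diabetes,med_cholesterol,med_htn,med_tg",
    "95,101,42,125,80,160,FALSE,FALSE,TRUE,FALSE"), f)
  ph <- read_phenotypes(f)
  expect_true(is.logical(ph$med_htn))
  expect_identical(mets_index(ph)$mets_index, 3L)

  f2 <- file.path(dir, "ph2.csv")
  writeLines(c("waist_cm,glucose_mgdl", "95,101"), f2)
  expect_error(read_phenotypes(f2), "lacks columns")
})
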