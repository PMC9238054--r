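test_that("lsfg_scan enforces its invariants", {
  m <- matrix(c(1, 2, 3, NaN), 2)
  sc <- lsfg_scan(m, patient_id = "P1", eye = "OD")
  expect_identical(sc$valid, matrix(c(TRUE, TRUE, TRUE, FALSE), 2))
  expect_true(all(is.finite(sc$mbr[sc$valid])))
  expect_error(lsfg_scan(matrix(-1, 2, 2)), class = "lsfg_negative_mbr")
  expect_error(lsfg_scan(1:4), class = "lsfg_bad_scan")
  expect_error(lsfg_scan(m, scan_index = 4), class = "lsfg_bad_scan")
  px <- as_tibble(sc)
  expect_equal(nrow(px), 4)
  expect_equal(px$mbr[px$valid], c(1, 2, 3))
})

test_that("CSV dialect round-trips bitwise and maps NaN to invalid", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("1,2\n3,NaN", f)
  sc <- read_scan(f, patient_id = "P1")
  expect_equal(sc$mbr[1, ], c(1, 2))
  expect_equal(sc$mbr[2, 1], 3)
  expect_identical(sc$valid, matrix(c(TRUE, TRUE, TRUE, FALSE), 2, byrow = TRUE))

  set.seed(5)
  m <- matrix(runif(30 * 20, 0, 40), 30, 20)
  m[sample(600, 13)] <- NaN
  sc2 <- mat_scan(m)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_scan(sc2, f2)
  back <- read_scan(f2)
  expect_identical(back$mbr[back$valid], sc2$mbr[sc2$valid]) # bitwise
  expect_identical(back$valid, sc2$valid)

  # all-valid scan writes no NaN
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_scan(mat_scan(matrix(1:6 / 2, 2, 3)), f3)
  expect_false(any(grepl("NaN", readLines(f3))))
})

test_that("read_scan rejects bad inputs with distinct errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("1,2\n3,-1.0", f)
  expect_error(read_scan(f), class = "lsfg_negative_mbr")
  expect_error(read_scan("no/such/file.csv"), class = "lsfg_io_error")
  f2 <- withr::local_tempfile(fileext = ".xyz")
  writeLines("1,2", f2)
  expect_error(read_scan(f2), class = "lsfg_io_error")
  expect_error(write_scan(mat_scan(matrix(1, 2, 2)), f2, dialect = "hdf5"),
               class = "lsfg_io_error")
})

test_that("TIFF dialect round-trips to single-float precision", {
  set.seed(6)
  m <- matrix(runif(40 * 25, 0, 45), 40, 25)
  m[sample(1000, 9)] <- NaN
  sc <- mat_scan(m)
  f <- withr::local_tempfile(fileext = ".tif")
  write_scan(sc, f)
  back <- read_scan(f)
  expect_identical(back$valid, sc$valid)
  # scaled 32-bit storage: relative error bounded by float epsilon on the
  # full-scale value
  expect_lt(max(abs(back$mbr[back$valid] - sc$mbr[sc$valid])), 100 * 2^-22)
})

test_that("cohorts round-trip through write_cohort/read_cohort", {
  coh <- small_cohort(n = 2, seed = 11)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(file.path(dir, "cohort.csv"))
  expect_equal(nrow(back$scans), nrow(coh$scans))
  expect_equal(back$seed, coh$seed)
  expect_setequal(back$patients$patient_id, coh$patients$patient_id)
  # scan payloads identical on valid pixels (CSV dialect is lossless)
  key <- function(s) paste(s$patient_id, s$eye, s$scan_index)
  orig <- setNames(coh$scans$scan, vapply(coh$scans$scan, key, ""))
  for (sc in back$scans$scan) {
    o <- orig[[key(sc)]]
    expect_identical(sc$mbr[sc$valid], o$mbr[o$valid])
    expect_identical(sc$irradiated, o$irradiated)
  }
  # covariates survive
  expect_equal(dplyr::arrange(back$patients, patient_id)$sbp,
               dplyr::arrange(coh$patients, patient_id)$sbp)
})

test_that("read_cohort validates the paired-eye structure", {
  coh <- small_cohort(n = 2, seed = 3)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  meta <- readr::read_csv(file.path(dir, "cohort.csv"), show_col_types = FALSE)

  # a missing scan file
  bad <- meta
  bad$scan_path_2[1] <- "missing.csv"
  readr::write_csv(bad, file.path(dir, "bad1.csv"))
  expect_error(read_cohort(file.path(dir, "bad1.csv"), scan_dir = dir),
               class = "lsfg_cohort_error", regexp = bad$patient_id[1])

  # both eyes irradiated
  bad2 <- meta
  bad2$irradiated <- TRUE
  readr::write_csv(bad2, file.path(dir, "bad2.csv"))
  expect_error(read_cohort(file.path(dir, "bad2.csv"), scan_dir = dir),
               class = "lsfg_cohort_error", regexp = "irradiated")

  # an eye with only 2 scans
  bad3 <- meta
  bad3$scan_path_3[2] <- NA
  readr::write_csv(bad3, file.path(dir, "bad3.csv"))
  expect_error(read_cohort(file.path(dir, "bad3.csv"), scan_dir = dir),
               class = "lsfg_cohort_error")

  # a required covariate missing
  bad4 <- meta
  bad4$sbp[1] <- NA
  readr::write_csv(bad4, file.path(dir, "bad4.csv"))
  expect_error(read_cohort(file.path(dir, "bad4.csv"), scan_dir = dir),
               class = "lsfg_cohort_error", regexp = "sbp")

  # dose/distance may be missing
  ok <- meta
  ok$dose_to_disc <- NA
  readr::write_csv(ok, file.path(dir, "ok.csv"))
  expect_no_error(read_cohort(file.path(dir, "ok.csv"), scan_dir = dir))
})
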