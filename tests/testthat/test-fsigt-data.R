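test_that("unit conversions use the standard clinical factors and invert exactly", {
  expect_equal(convert_units(90, "glucose", "mg/dl", "mmol/l"), 5)
  expect_equal(convert_units(94.5, "glucose", "mg/dl", "mmol/l"), 5.25)
  expect_equal(convert_units(7.5, "insulin", "mU/l", "pmol/l"), 45)
  expect_equal(convert_units(45, "insulin", "pmol/l", "mU/l"), 7.5)
  for (x in c(0.3, 5.25, 94.5, 180)) {
    expect_identical(
      convert_units(convert_units(x, "glucose", "mmol/l", "mg/dl"),
                    "glucose", "mg/dl", "mmol/l"), x)
    expect_identical(
      convert_units(convert_units(x, "insulin", "pmol/l", "mU/l"),
                    "insulin", "mU/l", "pmol/l"), x)
  }
  expect_error(convert_units(1, "glucose", "stone", "mmol/l"), "supported")
})

test_that("CSV round-trip preserves a canonical series and applies declared units", {
  s <- nf_subject$series
  path <- withr::local_tempfile(fileext = ".csv")
  write_fsigt_csv(s, path)
  r <- read_fsigt_csv(path, subject_id = attr(s, "subject_id"))
  expect_equal(r$time_min, s$time_min)
  expect_equal(r$glucose_mmol_l, s$glucose_mmol_l, tolerance = 1e-6)
  expect_equal(r$insulin_pmol_l, s$insulin_pmol_l, tolerance = 1e-6)
  expect_equal(r$ffa_umol_l, s$ffa_umol_l, tolerance = 1e-6)

  # declared mg/dl glucose is divided by 18.0 on read
  d <- utils::read.csv(path)
  d$glucose <- d$glucose * 18.0
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(d, path2, row.names = FALSE)
  r2 <- read_fsigt_csv(path2, units = c(glucose = "mg/dl"))
  expect_equal(r2$glucose_mmol_l, s$glucose_mmol_l, tolerance = 1e-6)

  # missing declared column is named in the error
  d3 <- d
  names(d3)[names(d3) == "ffa"] <- "nefa"
  utils::write.csv(d3, path2, row.names = FALSE)
  expect_error(read_fsigt_csv(path2), "ffa")
  r3 <- read_fsigt_csv(path2, units = c(glucose = "mg/dl"),
                       columns = c(ffa = "nefa"))
  expect_equal(r3$ffa_umol_l, s$ffa_umol_l, tolerance = 1e-6)
})

test_that("series validation rejects malformed inputs with informative errors", {
  tm <- c(-15, -10, -5, -1, 2, 3, 4, 5, 6)
  ok <- function(times = tm, ffa = rep(300, length(times)))
    fsigt_series("x", times, rep(5, length(times)), rep(45, length(times)), ffa)
  expect_s3_class(ok(), "fsigt_series")
  expect_error(ok(times = c(-15, -5, -5, -1, 2, 3, 4, 5, 6)), "duplicate.*-5")
  expect_error(ok(ffa = c(rep(300, 8), -1)), "ffa at row")
  expect_error(ok(ffa = c(rep(300, 8), NA)), "ffa at row")
  expect_error(ok(times = tm + 16), "basal")
  expect_error(ok(times = c(-15, -10, -5, -1, 2, 3, 4, 5, 6) - 3), "five post-bolus")
})

test_that("basal state is the mean of pre-bolus samples, order-invariant", {
  s <- toy_series(ffa = c(320, 330, 322, 332, rep(300, 6)),
                  glucose = c(5.2, 5.3, 5.2, 5.3, rep(5, 6)),
                  insulin = c(44, 46, 44, 46, rep(45, 6)))
  b <- basal_state(s)
  expect_equal(b$ffa_b, 326)
  expect_equal(b$g_b, 5.25)
  expect_equal(b$i_b, 45)

  # permuting which basal time carries which value leaves the means alone
  s2 <- toy_series(ffa = c(332, 322, 330, 320, rep(300, 6)),
                   glucose = c(5.3, 5.2, 5.3, 5.2, rep(5, 6)),
                   insulin = c(46, 44, 46, 44, rep(45, 6)))
  expect_equal(basal_state(s2), b)

  # a single basal sample is its own mean
  s3 <- fsigt_series("x", c(-1, 2, 3, 4, 5, 6), rep(5, 6), rep(45, 6),
                     c(311, rep(300, 5)))
  expect_equal(basal_state(s3)$ffa_b, 311)
})

test_that("cohort manifests round-trip through the generator's output directory", {
  dir <- withr::local_tempdir()
  cfg <- nf_config(n = 2)
  cohort <- generate_cohort(cfg, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "truth.csv")))
  back <- read_fsigt_cohort(file.path(dir, "manifest.csv"))
  expect_named(back, names(cohort))
  expect_equal(back[[1]]$ffa_umol_l, cohort[[1]]$series$ffa_umol_l,
               tolerance = 1e-6)
  expect_equal(attr(back[[2]], "body_weight"),
               attr(cohort[[2]]$series, "body_weight"), tolerance = 1e-6)
})
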