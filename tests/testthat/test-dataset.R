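test_that("grid construction follows the inclusive length formula", {
  g <- make_grid(400, 1800, 4)
  expect_length(g$values, 351)
  expect_equal(g$values[1], 400)
  expect_equal(g$values[351], 1800)

  expect_equal(make_grid(400, 404, 4)$values, c(400, 404))
  expect_error(make_grid(400, 1801, 4), "remainder 1")

  # property: length = (stop - start)/step + 1 for random valid triples
  withr::with_seed(11, {
    for (i in 1:25) {
      start <- sample(300:900, 1)
      step <- sample(c(1, 2, 4, 5, 10), 1)
      k <- sample(2:400, 1)
      g <- make_grid(start, start + step * (k - 1), step)
      expect_length(g$values, k)
      expect_equal(diff(g$values), rep(step, k - 1))
    }
  })
})

test_that("spectra + reference CSVs round-trip through the reader", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_csvs(dir)
  ds <- read_spectra_csv(paths$spectra, paths$references)
  expect_s3_class(ds, "spectral_dataset")
  expect_equal(nrow(ds$reflectance), 3)
  expect_length(ds$grid$values, 5)
  expect_named(ds$targets, c("tvbn", "L"))

  # write-then-read reproduces reflectance and targets
  out_sp <- file.path(dir, "out_sp.csv")
  out_ref <- file.path(dir, "out_ref.csv")
  write_spectra_csv(ds, out_sp, out_ref)
  ds2 <- read_spectra_csv(out_sp, out_ref)
  expect_equal(ds2$reflectance, ds$reflectance, tolerance = 1e-9)
  expect_equal(ds2$targets, ds$targets)
})

test_that("malformed spectra inputs are rejected with specific messages", {
  dir <- withr::local_tempdir()
  # non-uniform header spacing
  writeLines(c("sample_id,400,404,412", "S1,0.1,0.2,0.3", "S2,0.2,0.3,0.4"),
             file.path(dir, "bad1.csv"))
  writeLines(c("sample_id,tvbn", "S1,10", "S2,12"),
             file.path(dir, "refs.csv"))
  expect_error(
    read_spectra_csv(file.path(dir, "bad1.csv"), file.path(dir, "refs.csv")),
    "non-uniform"
  )
  # non-numeric header cell
  writeLines(c("sample_id,400,foo,408", "S1,0.1,0.2,0.3", "S2,0.2,0.3,0.4"),
             file.path(dir, "bad2.csv"))
  expect_error(
    read_spectra_csv(file.path(dir, "bad2.csv"), file.path(dir, "refs.csv")),
    "foo"
  )
  # duplicate sample id
  writeLines(c("sample_id,400,404,408", "S1,0.1,0.2,0.3", "S1,0.2,0.3,0.4"),
             file.path(dir, "bad3.csv"))
  expect_error(
    read_spectra_csv(file.path(dir, "bad3.csv"), file.path(dir, "refs.csv")),
    "S1"
  )
  # id present in only one file
  writeLines(c("sample_id,400,404,408", "S1,0.1,0.2,0.3", "S3,0.2,0.3,0.4"),
             file.path(dir, "bad4.csv"))
  expect_error(
    read_spectra_csv(file.path(dir, "bad4.csv"), file.path(dir, "refs.csv")),
    "mismatch"
  )
})

test_that("mask CSVs round-trip losslessly and validate lengths", {
  g <- make_grid(400, 408, 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_mask(c(TRUE, TRUE, TRUE), g, path)
  df <- utils::read.csv(path)
  expect_equal(df$selected, c(1, 1, 1))
  expect_equal(df$wavelength_nm, c(400, 404, 408))

  g2 <- make_grid(400, 1800, 4)
  withr::with_seed(5, {
    for (i in 1:5) {
      m <- runif(351) > 0.5
      write_mask(m, g2, path)
      expect_identical(read_mask(path, g2), m)
    }
  })
  expect_error(write_mask(rep(TRUE, 350), g2, path), "350")
})

test_that("dataset validation catches structural problems", {
  g <- make_grid(400, 408, 4)
  refl <- matrix(0.5, 2, 3)
  expect_error(
    spectral_dataset(g, refl, data.frame(tvbn = c(1, 2, 3)), c("a", "b")),
    "row count"
  )
  expect_error(
    spectral_dataset(g, refl, data.frame(tvbn = c(-1, 2)), c("a", "b")),
    "positive"
  )
  expect_error(
    spectral_dataset(g, matrix(c(0.5, NA, 1, 1, 1, 1), 2),
                     data.frame(tvbn = c(1, 2)), c("a", "b")),
    "missing"
  )
  # per-indicator missingness is allowed and reported on extraction
  ds <- spectral_dataset(g, refl, data.frame(tvbn = c(1, NA), L = c(40, 41)),
                         c("a", "b"))
  expect_message(iv <- indicator_values(ds, "tvbn"), "dropping 1")
  expect_equal(iv$rows, 1L)
  expect_error(indicator_values(ds, "nope"), "nope")
})
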