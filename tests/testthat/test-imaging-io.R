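test_that("CSV slice fixtures round-trip through read_volume", {
  dir <- withr::local_tempdir()
  set.seed(3)
  grids <- lapply(1:3, function(k) matrix(round(runif(64, -1000, -600)), 8, 8))
  for (k in 1:3)
    write_grid_csv(grids[[k]], file.path(dir, sprintf("slice_%02d.csv", k)))
  vol <- read_volume(dir, pixel_spacing = c(0.7, 0.7))
  expect_length(vol, 3)
  for (k in 1:3) {
    expect_identical(dim(vol[[k]]$values), c(8L, 8L))
    expect_equal(vol[[k]]$values, grids[[k]])
    expect_identical(vol[[k]]$slice_index, k)
  }
})

test_that("NIfTI volumes round-trip and header rescale is applied on read", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  set.seed(4)
  arr <- array(round(runif(8 * 8 * 3, -1000, -600)), dim = c(8, 8, 3))
  RNifti::writeNifti(RNifti::asNifti(arr), f)
  vol <- read_volume(f)
  expect_length(vol, 3)
  expect_equal(vol[[2]]$values, arr[, , 2])
  expect_equal(vol[[1]]$pixel_spacing, c(1, 1))

  # handcrafted file: stored int16 value 24 with scl_inter -1024 reads as -1000 HU
  f2 <- withr::local_tempfile(fileext = ".nii")
  write_scaled_nifti(f2, array(24L, dim = c(4, 4, 2)), slope = 1, inter = -1024)
  vol2 <- read_volume(f2)
  expect_true(all(vol2[[1]]$values == -1000))

  # same grid encoded as CSV and as NIfTI yields identical values
  csvf <- withr::local_tempfile(fileext = ".csv")
  write_grid_csv(matrix(-1000, 4, 4), csvf)
  expect_equal(read_volume(csvf)[[1]]$values, vol2[[1]]$values)
})

test_that("unreadable or unsupported inputs raise format errors", {
  expect_error(read_volume("no_such_file.nii"), class = "heqct_format_error")
  expect_error(read_volume("whatever.dcm", format_hint = "dicom"),
               class = "heqct_format_error")
  bad <- withr::local_tempfile(fileext = ".nii")
  writeLines("not a nifti", bad)
  expect_error(suppressWarnings(read_volume(bad)), class = "heqct_format_error")
})

test_that("slice validation rejects implausible attenuation and empty grids", {
  expect_error(hu_slice(matrix(-2000, 2, 2)), class = "heqct_validation_error")
  expect_error(hu_slice(matrix(5000, 2, 2)), class = "heqct_validation_error")
  expect_error(hu_slice(matrix(numeric(0), 0, 0)), class = "heqct_validation_error")
  expect_error(hu_slice(matrix(c(0, NA), 1, 2)), class = "heqct_validation_error")
  expect_silent(hu_slice(matrix(c(-1100, 3100), 1, 2)))
})

test_that("masks map nonzero to inside and enforce geometry", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_grid_csv(matrix(1, 8, 8), f)
  mk <- read_mask(f)
  expect_identical(sum(mk[[1]]$values), 64L)

  sl <- hu_slice(matrix(-700, 4, 4))
  expect_error(lung_mask(matrix(1, 8, 8), slice = sl),
               class = "heqct_geometry_error")
  vol3 <- lapply(1:3, function(k) hu_slice(matrix(-700, 8, 8)))
  expect_error(read_mask(f, volume = vol3[1:2]), class = "heqct_geometry_error")
})

test_that("phantom masks round-trip bit-exactly through NIfTI", {
  ph <- generate_phantom(phantom_spec(n_components = 2, n_enclosed = 1, seed = 12))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  arr <- simplify2array(lapply(ph$masks, function(m) m$values * 1L))
  RNifti::writeNifti(RNifti::asNifti(arr), f)
  back <- read_mask(f, volume = ph$volume)
  for (k in seq_along(back))
    expect_identical(back[[k]]$values, ph$masks[[k]]$values)
})

test_that("cohort tables read, validate, and round-trip value-for-value", {
  df <- toy_cohort_df(6)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  co <- read_cohort(f)
  expect_s3_class(co, "cohort_table")
  expect_identical(nrow(co), 6L)
  expect_true(all(co$modelling_complete))

  # round trip preserves every canonical column
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f2)
  co2 <- read_cohort(f2)
  for (col in setdiff(names(df), "modelling_complete"))
    expect_equal(co2[[col]], co[[col]], info = col)

  # column_map renames arbitrary source headers
  df3 <- df
  names(df3)[names(df3) == "age"] <- "Age (years)"
  names(df3)[names(df3) == "b1_880"] <- "b1 at -880 HU"
  f3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df3, f3, row.names = FALSE)
  co3 <- read_cohort(f3, column_map = c(age = "Age (years)",
                                        b1_880 = "b1 at -880 HU"))
  expect_equal(co3$age, co$age)
  expect_equal(co3$b1_880, co$b1_880)
  expect_error(read_cohort(f3, column_map = c(age = "No Such Header")),
               class = "heqct_schema_error")
})

test_that("cohort schema and invariant violations are explicit", {
  df <- toy_cohort_df(4)
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[setdiff(names(df), c("b1_880", "laa_950"))], f, row.names = FALSE)
  err <- expect_error(read_cohort(f), class = "heqct_schema_error")
  expect_match(conditionMessage(err), "laa_950")
  expect_match(conditionMessage(err), "b1_880")

  df2 <- toy_cohort_df(4); df2$laa_880[2] <- 101
  expect_error(as_cohort(df2), class = "heqct_validation_error")
  df3 <- toy_cohort_df(4); df3$b1_880[1] <- -3
  expect_error(as_cohort(df3), class = "heqct_validation_error")
  df4 <- toy_cohort_df(4); df4$patient_id[2] <- df4$patient_id[1]
  expect_error(as_cohort(df4), class = "heqct_validation_error")

  # missing Brinkman index flags the row instead of dropping it
  df5 <- toy_cohort_df(4); df5$brinkman_index[3] <- NA
  co5 <- as_cohort(df5)
  expect_identical(nrow(co5), 4L)
  expect_identical(co5$modelling_complete, c(TRUE, TRUE, FALSE, TRUE))
})
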