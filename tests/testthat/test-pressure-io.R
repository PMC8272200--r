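test_that("frame and sequence constructors enforce their invariants", {
  expect_error(pressure_frame(matrix(-1, 4, 4)), "negative")
  expect_error(pressure_frame(matrix(NA_real_, 4, 4)), "NA")
  expect_error(pressure_frame(matrix(1500, 4, 4)), "sensor_max")
  expect_error(pressure_sequence(list()), "non-empty")
  expect_error(pressure_sequence(list(pressure_frame(matrix(0, 4, 4)),
                                      pressure_frame(matrix(0, 5, 4)))),
               "shape")
  s <- pressure_sequence(lapply(1:3, function(i) pressure_frame(matrix(i, 4, 4))),
                         sampling_hz = 2)
  expect_equal(vapply(s$frames, `[[`, numeric(1), "timestamp"), c(0, 0.5, 1))
  expect_equal(length(s), 3L)
})

test_that("a stacked file of zeros reads as zero frames with 1 Hz timestamps", {
  f <- tempfile(fileext = ".txt")
  writeLines(paste(rep("0", 32), collapse = " ")[rep(1, 64 * 2)], f)
  writeLines(rep(paste(rep("0", 32), collapse = " "), 128), f)
  s <- read_sequence(f, grid_shape = c(64, 32))
  expect_length(s$frames, 2)
  expect_true(all(s$frames[[1]]$values == 0))
  expect_equal(s$frames[[2]]$timestamp, 1)
})

test_that("write/read round-trips are bit-exact, with metadata preserved", {
  for (seed in 1:3) {
    sc <- generate_scene(scene_spec("supine", seed = seed))
    seqin <- pressure_sequence(list(sc$frame, sc$frame), sampling_hz = 1,
                               subject_id = "S01", pose_id = "supine")
    f <- tempfile(fileext = ".txt")
    write_sequence(seqin, f)
    back <- read_sequence(f)
    expect_identical(back$frames[[1]]$values, seqin$frames[[1]]$values)
    expect_identical(back$frames[[2]]$values, seqin$frames[[2]]$values)
    expect_equal(back$subject_id, "S01")
    expect_equal(back$pose_id, "supine")
    expect_equal(back$sampling_hz, 1)
  }
})

test_that("reader rejects malformed input rather than clamping", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("1 2 3", "4 x 6", "7 8 9"), f)
  expect_error(read_sequence(f, grid_shape = c(3, 3)), "line 2")

  writeLines(as.character(1:10), f)
  expect_error(read_sequence(f, grid_shape = c(3, 3)), "multiple")

  writeLines(c("1 2 3", "4 -5 6", "7 8 9"), f)
  expect_error(read_sequence(f, grid_shape = c(3, 3)), "negative")

  expect_error(read_sequence(file.path(tempdir(), "nope.txt")), "exist")
  expect_error(write_sequence(list(), tempfile()), "pressure_sequence")
})

test_that("directory-of-frames dialect and the row flip flag work", {
  d <- file.path(tempdir(), "framesdir")
  dir.create(d, showWarnings = FALSE)
  m1 <- matrix(runif(12, 0, 10), 3, 4)
  m2 <- matrix(runif(12, 0, 10), 3, 4)
  for (i in 1:2) {
    con <- file.path(d, sprintf("frame%02d.txt", i))
    m <- if (i == 1) m1 else m2
    writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ",")), con)
  }
  s <- read_sequence(d, grid_shape = c(3, 4))
  expect_length(s$frames, 2)
  expect_equal(s$frames[[1]]$values, m1, tolerance = 1e-15)
  expect_equal(s$frames[[2]]$values, m2, tolerance = 1e-15)

  flipped <- read_sequence(d, grid_shape = c(3, 4), flip_rows = TRUE)
  expect_equal(flipped$frames[[1]]$values, m1[3:1, ], tolerance = 1e-15)
})
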