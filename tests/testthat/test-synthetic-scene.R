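test_that("scene specs validate landmarks and objects", {
  lms <- presscope:::default_landmarks("supine", c(64L, 32L))
  bad <- lms; bad$row[1] <- 99
  expect_error(scene_spec(landmarks = bad), "inside the grid")
  bad <- lms; bad$peak[1] <- 0
  expect_error(scene_spec(landmarks = bad), "peaks")
  bad <- lms; bad$spread[1] <- 0.2
  expect_error(scene_spec(landmarks = bad), "spread")
  expect_error(object_spec(rows = 1:2, cols = 1:10), "4 x 4")
  expect_error(scene_spec(objects = list(object_spec(1:10, 1:10, relief = 500))),
               "relief")
})

test_that("generated scenes are deterministic, valid and built as specified", {
  sp <- scene_spec("supine", seed = 77)
  a <- generate_scene(sp); b <- generate_scene(sp)
  expect_identical(a$frame$values, b$frame$values)
  expect_silent(validate_frame(a$frame))

  # empty spec -> all-zero frame
  empty <- scene_spec(landmarks = presscope:::default_landmarks("supine", c(64L, 32L))[0, ],
                      noise_sd = 0)
  expect_true(all(generate_scene(empty)$frame$values == 0))

  # noise-free supine: the maximum sits at the sacrum, the largest peak
  sp0 <- scene_spec("supine", noise_sd = 0)
  sc0 <- generate_scene(sp0)
  peak_at <- which(sc0$frame$values == max(sc0$frame$values), arr.ind = TRUE)
  sac <- sp0$landmarks[sp0$landmarks$name == "sacrum", ]
  expect_equal(unname(peak_at[1, ]), c(sac$row, sac$col))

  # masks: the wedge-under-body overlap is flagged
  sc <- wedge_scene(1)
  expect_identical(sc$truth$overlap, sc$truth$body_mask & sc$truth$object_mask)
})

test_that("object plateaus are flatter than body regions of equal area", {
  sc <- generate_scene(scene_spec("supine", objects = list(bench_wedge()),
                                  seed = 2, noise_sd = 0))
  v <- sc$frame$values
  obj_core <- sc$truth$object_field > 0.9 * 50
  n <- sum(obj_core)
  body_vals <- sort(v[sc$truth$body_mask], decreasing = TRUE)[seq_len(n)]
  expect_lt(var(v[obj_core]), var(body_vals))
})

test_that("sequences carry static truth, drift and the sampling contract", {
  sp <- scene_spec("supine", seed = 3, noise_sd = 0)
  gen <- generate_sequence(sp, n_frames = 5, drift_sd = 0)
  expect_equal(vapply(gen$sequence$frames, `[[`, numeric(1), "timestamp"), 0:4)
  expect_identical(gen$sequence$frames[[1]]$values, gen$sequence$frames[[5]]$values)
  expect_error(generate_sequence(sp, n_frames = 0), "n_frames")

  # law of large numbers: per-landmark mean over frames approaches the
  # noise-free value within 3 sd / sqrt(n)
  spn <- scene_spec("supine", seed = 11, noise_sd = 5)
  n <- 60
  gen <- generate_sequence(spn, n_frames = n)
  clean <- gen$truth$body_field
  lms <- gen$truth$landmarks
  for (i in seq_len(nrow(lms))) {
    at <- c(lms$row[i], lms$col[i])
    series <- vapply(gen$sequence$frames, function(f) f$values[at[1], at[2]],
                     numeric(1))
    expect_lt(abs(mean(series) - clean[at[1], at[2]]), 3 * 5 / sqrt(n))
  }
})

test_that("labelled datasets are balanced, reproducible and jitter-controlled", {
  ds <- labelled_dataset(10, seed = 9, n_subjects = 5)
  expect_length(ds, 30)
  expect_equal(as.integer(table(vapply(ds, `[[`, character(1), "label"))),
               rep(10L, 3))
  ds2 <- labelled_dataset(10, seed = 9, n_subjects = 5)
  expect_identical(lapply(ds, function(s) s$frame$values),
                   lapply(ds2, function(s) s$frame$values))

  # zero jitter and zero noise -> identical same-class frames
  dz <- labelled_dataset(4, jitter = list(subject_shift_row = 0,
                                          subject_shift_col = 0,
                                          frame_shift = 0, peak_frac = 0),
                         seed = 2, n_subjects = 2, noise_sd = 0)
  sup <- Filter(function(s) s$label == "supine", dz)
  expect_identical(sup[[1]]$frame$values, sup[[4]]$frame$values)
  expect_error(labelled_dataset(0), "n_per_posture")
})
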