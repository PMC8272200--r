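test_that("gradient field uses central differences with one-sided edges", {
  m <- outer(1:10, 1:8, function(r, c) 2 * c)  # ramp across columns
  g <- gradient_field(m)
  expect_true(all(abs(g$d_col - 2) < 1e-12))
  expect_true(all(abs(g$d_row) < 1e-12))
  g0 <- gradient_field(matrix(5, 6, 6))
  expect_true(all(g0$d_row == 0) && all(g0$d_col == 0))
  expect_error(gradient_field(matrix(1, 2, 5)), "3 x 3")

  # both components vanish at a blob peak
  b <- presscope:::blob_field(c(40L, 30L), 20, 16, 400, 3)
  g <- gradient_field(b)
  expect_lt(abs(g$d_row[20, 16]), 1e-8)
  expect_lt(abs(g$d_col[20, 16]), 1e-8)
})

test_that("zero-crossing maxima find blob peaks and ignore flat frames", {
  b <- presscope:::blob_field(c(40L, 30L), 20, 16, 400, 3)
  mx <- find_maxima(gradient_field(b), b, min_height = 50)
  expect_equal(nrow(mx), 1L)
  expect_equal(unname(mx[1, ]), c(20L, 16L))
  # exhaustive neighbourhood oracle: the peak dominates its 8-neighbours
  expect_true(all(b[20, 16] >= b[19:21, 15:17]))

  expect_equal(nrow(find_maxima(gradient_field(matrix(7, 20, 20)),
                                matrix(7, 20, 20))), 0L)

  # min_height filters low maxima out
  expect_equal(nrow(find_maxima(gradient_field(b), b, min_height = 500)), 0L)
})

test_that("supine phantom yields one maximum within 2 sensels of each landmark", {
  sc <- body_scene(13)
  enh <- enhance_chain(sc$frame)
  mx <- find_maxima(gradient_field(enh), enh, min_height = 20)
  lms <- sc$truth$landmarks
  for (i in seq_len(nrow(lms))) {
    d <- sqrt((mx[, 1] - lms$row[i])^2 + (mx[, 2] - lms$col[i])^2)
    expect_lte(min(d), 2)
  }
})

test_that("region growing recovers half-maximum discs and merges overlaps", {
  b <- presscope:::blob_field(c(40L, 30L), 20, 16, 400, 3)
  regs <- grow_regions(b, cbind(row = 20L, col = 16L), rel_level = 0.5)
  expect_length(regs, 1)
  analytic <- pi * 2 * log(2) * 3^2    # area of the half-max disc
  expect_lt(abs(nrow(regs[[1]]$pixels) - analytic) / analytic, 0.2)
  expect_equal(regs[[1]]$mean_pressure, mean(b[regs[[1]]$pixels]))

  # two far-apart blobs stay disjoint; raising rel_level shrinks regions
  b2 <- b + presscope:::blob_field(c(40L, 30L), 34, 8, 300, 2)
  seeds <- cbind(row = c(20L, 34L), col = c(16L, 8L))
  regs2 <- grow_regions(b2, seeds, rel_level = 0.5)
  expect_length(regs2, 2)
  tight <- grow_regions(b2, seeds, rel_level = 0.9)
  expect_true(all(vapply(seq_len(2), function(i)
    nrow(tight[[i]]$pixels) < nrow(regs2[[i]]$pixels), logical(1))))

  # overlapping half-max regions are merged with pooled seeds
  b3 <- presscope:::blob_field(c(40L, 30L), 20, 14, 400, 4) +
    presscope:::blob_field(c(40L, 30L), 20, 18, 400, 4)
  merged <- grow_regions(b3, cbind(row = c(20L, 20L), col = c(14L, 18L)))
  expect_length(merged, 1)
  expect_error(grow_regions(b, cbind(row = 99L, col = 1L)), "outside")
  expect_error(grow_regions(b, cbind(row = 2L, col = 2L), rel_level = 1.2),
               "rel_level")
})

test_that("filtering drops small regions and implausible rows", {
  raw <- matrix(10, 64, 32)
  tiny <- presscope:::new_region(cbind(row = c(10L, 10L), col = c(5L, 6L)), raw)
  big <- presscope:::new_region(as.matrix(expand.grid(row = 30:37, col = 10:17)),
                                raw)
  colnames(big$pixels) <- c("row", "col")
  out <- filter_regions(list(tiny, big), min_area = 4)
  expect_length(out, 1)
  expect_equal(nrow(out[[1]]$pixels), 64)  # an 8x8 square survives opening intact

  # a large region in an implausible row band is removed when posture given
  mid <- presscope:::new_region(as.matrix(expand.grid(row = 46:53, col = 10:17)),
                                raw)
  colnames(mid$pixels) <- c("row", "col")
  expect_length(filter_regions(list(mid), min_area = 4, posture = "supine"), 0)
  expect_length(filter_regions(list(mid), min_area = 4), 1)
})

test_that("spatial labelling follows the lying-body template", {
  for (seed in c(5, 23)) {
    sc <- body_scene(seed)
    regs <- presscope:::detect_regions(sc$frame, "supine")
    labs <- sort(vapply(regs, `[[`, character(1), "label"))
    expect_setequal(labs, c("head", "left_shoulder", "right_shoulder",
                            "sacrum", "left_foot", "right_foot"))
    # labels are mutually exclusive over pixels
    all_pix <- do.call(rbind, lapply(regs, function(r)
      cbind(r$pixels, id = match(r$label, labs))))
    expect_equal(anyDuplicated(all_pix[, 1:2]), 0)
  }

  sc <- body_scene(7, "right_lateral")
  labs <- vapply(presscope:::detect_regions(sc$frame, "right_lateral"),
                 `[[`, character(1), "label")
  expect_setequal(labs, c("head", "right_shoulder", "sacrum", "right_foot"))

  # a single detected region is labelled head by the topmost rule
  b <- presscope:::blob_field(c(64L, 32L), 10, 16, 300, 3)
  one <- grow_regions(b, cbind(row = 10L, col = 16L))
  lab1 <- label_regions(one, "supine")
  expect_equal(lab1[[1]]$label, "head")
  expect_length(label_regions(list(), "supine"), 0)
})

test_that("mean pressures come from the raw frame, exactly", {
  sc <- body_scene(31)
  regs <- presscope:::detect_regions(sc$frame, "supine")
  for (r in regs) {
    expect_equal(r$mean_pressure, mean(sc$frame$values[r$pixels]))
  }
})

test_that("detection is equivariant under in-grid translation", {
  lms <- presscope:::default_landmarks("supine", c(64L, 32L))
  sc1 <- generate_scene(scene_spec("supine", landmarks = lms, seed = 3))
  lms2 <- lms; lms2$row <- lms$row + 2; lms2$col <- lms$col + 3
  sc2 <- generate_scene(scene_spec("supine", landmarks = lms2, seed = 3))
  r1 <- presscope:::detect_regions(sc1$frame, "supine")
  r2 <- presscope:::detect_regions(sc2$frame, "supine")
  c1 <- vapply(r1, function(r) r$centroid, numeric(2))
  c2 <- vapply(r2, function(r) r$centroid, numeric(2))
  l1 <- vapply(r1, `[[`, character(1), "label")
  l2 <- vapply(r2, `[[`, character(1), "label")
  for (lab in intersect(l1, l2)) {
    shift <- c2[, l2 == lab] - c1[, l1 == lab]
    expect_lt(abs(shift[1] - 2), 1 + 1e-9)
    expect_lt(abs(shift[2] - 3), 1 + 1e-9)
  }
})
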