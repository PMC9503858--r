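test_that("threshold index follows its normalized definition", {
  expect_equal(threshold_index(100, 100), 0)
  expect_equal(threshold_index(0, 100), 1)
  expect_equal(threshold_index(25, 100), 0.75)
  expect_error(threshold_index(5, 0), "c_max")
  expect_error(threshold_index(-1, 10), "c_thr")
  expect_error(threshold_index(11, 10), "c_thr")
})

test_that("uptake-foci counting matches the flood-fill oracle", {
  expect_equal(count_uptake_foci(matrix(c(5, 0, 5), 1, 3), 1), 2L)
  expect_equal(count_uptake_foci(matrix(0, 3, 3), 0), 0L)
  expect_equal(count_uptake_foci(matrix(5, 3, 3), 1), 1L)

  set.seed(11)
  for (i in 1:12) {
    m <- matrix(rpois(16 * 16, 1.2), 16, 16)
    for (conn in c(4, 8)) for (thr in c(0, 1, 2)) {
      expect_equal(count_uptake_foci(m, thr, conn),
                   flood_fill_count(m > thr, conn),
                   info = sprintf("draw %d conn %d thr %d", i, conn, thr))
    }
  }
})

test_that("8-connected counts never exceed 4-connected counts", {
  set.seed(3)
  for (i in 1:10) {
    m <- matrix(rpois(100, 0.8), 10, 10)
    expect_lte(count_uptake_foci(m, 0, 8), count_uptake_foci(m, 0, 4))
  }
  # diagonal pair: the canonical case where they differ
  d <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(count_uptake_foci(d, 0, 8), 1L)
  expect_equal(count_uptake_foci(d, 0, 4), 2L)
})

test_that("nNUF sweep is normalized and brute-force consistent", {
  m <- two_focus_fixture()
  curve <- nuf_curve(m, n_steps = 19)
  expect_equal(max(curve$nNUF), 1)
  expect_equal(nrow(curve), 19)
  expect_true(all(diff(curve$ThI) > 0))
  # between the two blob levels (7 and 9) exactly the brighter blob shows;
  # below 7 both show; brute-force every sweep point
  for (i in seq_len(nrow(curve)))
    expect_equal(curve$NUF[i], flood_fill_count(m > curve$Cthr[i], 8))
  expect_true(all(curve$NUF[curve$Cthr < 7 & curve$Cthr > 0] == 2))
  expect_true(all(curve$NUF <= 2))
  expect_error(nuf_curve(matrix(0, 2, 2)), "all-zero")
  expect_error(nuf_curve(m, n_steps = 1), "n_steps")
})

test_that("single-focus images never sweep past one focus", {
  m <- matrix(0, 6, 6); m[3:4, 3:4] <- c(5, 6, 7, 8)
  curve <- nuf_curve(m, n_steps = 25)
  expect_true(all(curve$NUF %in% c(0L, 1L)))
})

test_that("cutoff selection returns the smallest qualifying ThI", {
  curve <- structure(data.frame(ThI = c(0.1, 0.2, 0.3),
                                Cthr = c(90, 80, 70), NUF = c(1L, 3L, 5L),
                                nNUF = c(0.2, 0.6, 1.0)),
                     class = c("nuf_curve", "data.frame"))
  expect_equal(select_segmentation_threshold(curve, 0.5)$chosen_ThI, 0.2)
  expect_equal(select_segmentation_threshold(curve, 1.0)$chosen_ThI, 0.3)
  expect_equal(select_segmentation_threshold(curve, 1e-9)$chosen_ThI, 0.1)
  expect_error(select_segmentation_threshold(curve, 0), "nnuf_cutoff")
  expect_error(select_segmentation_threshold(curve[0, ], 0.5), "non-empty")
})

test_that("plateau selection centres the widest stable NUF run", {
  m <- two_focus_fixture()
  curve <- nuf_curve(m, n_steps = 100)
  thr <- select_plateau_threshold(curve)
  # the widest constant run is NUF = 2, spanning thresholds within (0, 7)
  expect_equal(thr$NUF_plateau, 2L)
  expect_gt(thr$chosen_Cthr, 0)
  expect_lt(thr$chosen_Cthr, 7)
  seg <- segment_compartments(m, thr$chosen_Cthr,
                              body = matrix(TRUE, 6, 6))
  expect_equal(length(seg$foci), 2L)
  expect_equal(seg$counts_high, sum(m))
})

test_that("compartment masks partition the body and sum its counts", {
  m <- matrix(0, 8, 8)
  m[2:7, 2:7] <- 10              # body
  m[3:4, 3:4] <- 50              # one 2x2 focus
  body <- m > 0
  seg <- segment_compartments(m, 20, body, acquisition_duration_s = 100)
  expect_equal(seg$counts_high, 200)
  expect_equal(seg$counts_low, sum(m) - 200)
  expect_equal(seg$cps_high, 2)
  expect_true(all(seg$high_mask + seg$low_mask == body))
  expect_false(any(seg$high_mask & seg$low_mask))
  expect_equal(length(seg$foci), 1L)
  expect_equal(counts_ratio(seg), 200 / (sum(m) - 200))

  # nothing overcomes a threshold at or above the maximum
  seg2 <- segment_compartments(m, max(m), body)
  expect_equal(sum(seg2$high_mask), 0)
  expect_equal(seg2$counts_low, sum(m))
  # threshold 0: every positive in-body pixel is high
  seg3 <- segment_compartments(m, 0, body)
  expect_equal(sum(seg3$high_mask), sum(m > 0))
  # high pixels outside the body mask are rejected
  expect_error(segment_compartments(m, 20, matrix(FALSE, 8, 8)),
               "outside the body mask")
})

test_that("body mask fills holes and keeps the largest component", {
  m <- matrix(0, 10, 10)
  m[2:8, 2:8] <- 40
  m[4:5, 4:5] <- 0               # interior cold hole: must be filled
  m[10, 10] <- 5                 # small detached speck: must be dropped
  bm <- body_mask(m, body_fraction = 0.01)
  expect_true(all(bm[2:8, 2:8]))
  expect_false(bm[10, 10])
  expect_equal(sum(bm), 49)

  u <- matrix(7, 4, 4)
  expect_true(all(body_mask(u, 0.5)))   # uniform image: full frame
  expect_error(body_mask(matrix(0, 2, 2)), "all-zero")
  expect_error(body_mask(m, 1), "body_fraction")
})

test_that("mask run-length CSV and nNUF CSV round-trip", {
  dir <- withr::local_tempdir()
  set.seed(5)
  mask <- matrix(runif(35) > 0.5, 7, 5)
  f <- file.path(dir, "m.csv")
  write_mask_rle(mask, f)
  expect_identical(read_mask_rle(f), mask)

  curve <- nuf_curve(two_focus_fixture(), n_steps = 10)
  g <- file.path(dir, "c.csv")
  write_nuf_curve(curve, g)
  back <- read.csv(g)
  expect_equal(back$nNUF, curve$nNUF)
  expect_equal(back$NUF, curve$NUF)
})
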