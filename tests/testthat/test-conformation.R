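test_that("frame distances are Euclidean and respect missing landmarks", {
  fr <- dimer_frames(0L, 0, head1 = c(0, 0), head2 = c(3, 4),
                     hinge = c(0, 2.4))
  expect_equal(head_head_distance(fr), 5)
  g <- head_hinge_distances(fr)
  expect_equal(unname(g[1, ]), c(2.4, sqrt(9 + (4 - 2.4)^2)))

  # permuting the heads swaps the head-hinge pair
  fr2 <- dimer_frames(0L, 0, head1 = c(3, 4), head2 = c(0, 0),
                      hinge = c(0, 2.4))
  expect_equal(unname(head_hinge_distances(fr2)[1, ]), rev(unname(g[1, ])))

  fr$head2_x_nm <- NA
  expect_true(is.na(head_head_distance(fr)))
  expect_error(head_head_distance(data.frame(a = 1)), "required columns")
})

test_that("geometry and classification are invariant under rigid motions", {
  set.seed(14)
  fr <- dimer_frames(0:19, (0:19) * 0.1,
                     head1 = matrix(rnorm(40, 0, 15), ncol = 2),
                     head2 = matrix(rnorm(40, 0, 15), ncol = 2),
                     hinge = matrix(rnorm(40, 0, 5), ncol = 2))
  for (k in 1:5) {
    moved <- apply_rigid_motion(fr, angle = runif(1, 0, 2 * pi),
                                shift = rnorm(2, 0, 50),
                                reflect = k %% 2 == 0)
    expect_equal(head_head_distance(moved), head_head_distance(fr),
                 tolerance = 1e-9)
    expect_equal(head_hinge_distances(moved), head_hinge_distances(fr),
                 tolerance = 1e-9)
    expect_identical(classify_frames(moved), classify_frames(fr))
  }
})

test_that("classification reproduces the state definitions", {
  t <- thresholds()
  lab <- function(g1, g2, hh)
    as.character(classify_frame(frame_with_distances(g1, g2, hh), t))
  expect_identical(lab(25, 25, 2.5), "O")   # heads engaged with each other
  expect_identical(lab(2.4, 2.4, 4), "B")   # both heads at the hinge
  expect_identical(lab(2.0, 25, 26), "P")   # one head at the hinge
  expect_identical(lab(25, 2.0, 26), "P")
  expect_identical(lab(25, 25, 30), "V")    # open
  # ties at a threshold count as engaged
  expect_identical(lab(7, 7, 13), "B")
  tie_o <- dimer_frames(0L, 0, head1 = c(20, 0), head2 = c(20, 7),
                        hinge = c(0, 0))  # hh exactly at the threshold
  expect_identical(as.character(classify_frame(tie_o, t)), "O")
  # both heads hinge-engaged and mutually close: butterfly wins
  expect_identical(lab(2.4, 2.4, 1.0), "B")
  # missing landmarks are UNCLASSIFIED, not an error
  expect_identical(lab(NA, NA, NA), "UNCLASSIFIED")
})

test_that("classes are exhaustive and mutually exclusive", {
  set.seed(99)
  fr <- dimer_frames(seq_len(500), seq_len(500) * 0.1,
                     head1 = matrix(rnorm(1000, 0, 12), ncol = 2),
                     head2 = matrix(rnorm(1000, 0, 12), ncol = 2),
                     hinge = matrix(rnorm(1000, 0, 6), ncol = 2))
  for (t in list(thresholds(), thresholds(3, 10), thresholds(12, 2))) {
    lab <- classify_frames(fr, t)
    expect_false(any(is.na(lab)))
    expect_true(all(lab %in% c("V", "O", "B", "P")))
  }
})

test_that("hinge angle measures the chord angle at the hinge", {
  t <- thresholds()
  along_x <- straight_arm(23, 0)
  along_y <- straight_arm(23, pi / 2)
  expect_equal(hinge_angle(along_x, along_y, t), 90)
  expect_equal(hinge_angle(along_x, straight_arm(23, pi), t), 180)
  expect_equal(hinge_angle(along_x, straight_arm(23, 0), t), 0)
  # symmetric under swapping arms; always within [0, 180]
  set.seed(5)
  for (k in 1:10) {
    a1 <- straight_arm(23, runif(1, 0, 2 * pi))
    a2 <- straight_arm(23, runif(1, 0, 2 * pi))
    ang <- hinge_angle(a1, a2, t)
    expect_equal(ang, hinge_angle(a2, a1, t), tolerance = 1e-9)
    expect_true(ang >= 0 && ang <= 180)
  }
  expect_error(hinge_angle(NULL, along_y, t), "both arm traces")
  expect_error(hinge_angle(straight_arm(2, 0), along_y, t), "arc length")
})

test_that("windowed Gaussian fitting recovers and translates peaks", {
  x <- sample_engaged_distance(5000, 2.5, 1.3, seed = 61)
  pk <- gaussian_peak(x, c(0, 10), 0.5)
  expect_equal(unname(pk["mean"]), 2.5, tolerance = 0.1 / 2.5)
  # translation equivariance
  pk10 <- gaussian_peak(x + 10, c(10, 20), 0.5)
  expect_equal(unname(pk10["mean"] - pk["mean"]), 10, tolerance = 0.05)
  expect_equal(unname(pk10["sd"]), unname(pk["sd"]), tolerance = 0.05)
  # degenerate sample: sigma collapses below the bin width
  pk0 <- gaussian_peak(rep(3.1, 30), c(0, 10), 0.5)
  expect_lt(unname(pk0["sd"]), 0.5)
  expect_equal(unname(pk0["mean"]), 3.1, tolerance = 0.5)
  expect_error(gaussian_peak(c(1, 2, 3), c(0, 10)), "too few")
})

test_that("class frequencies sum to one over classified frames", {
  f <- class_frequencies(c("V", "V", "O", "B"))
  expect_equal(unname(f), c(0.5, 0.25, 0.25, 0), ignore_attr = TRUE)
  expect_equal(sum(f), 1)
  f2 <- class_frequencies(c("V", "UNCLASSIFIED", "O", "UNCLASSIFIED"))
  expect_equal(attr(f2, "unclassified_fraction"), 0.5)
  expect_equal(attr(f2, "n_classified"), 2L)
  expect_error(class_frequencies(rep("UNCLASSIFIED", 4)), "no classified")
})

test_that("movie annotation subsamples, counts transitions, breaks on gaps", {
  # build a movie whose classified sequence is O O B B V
  seqs <- list(c(25, 25, 2.5), c(25, 25, 2.5), c(2.4, 2.4, 4),
               c(2.4, 2.4, 4), c(25, 25, 30))
  fr <- do.call(rbind, lapply(seq_along(seqs), function(i)
    frame_with_distances(seqs[[i]][1], seqs[[i]][2], seqs[[i]][3],
                         frame_id = i - 1L, time_s = (i - 1) * 0.1)))
  ann <- annotate_movie(fr)
  expect_identical(as.character(ann$labels$label), c("O", "O", "B", "B", "V"))
  tc <- ann$transition_counts
  expect_equal(tc["O", "O"], 1L)
  expect_equal(tc["O", "B"], 1L)
  expect_equal(tc["B", "B"], 1L)
  expect_equal(tc["B", "V"], 1L)
  expect_equal(sum(tc), 4L)

  # an unclassifiable frame breaks the transition chain
  fr_gap <- fr[c(1, 2, 3), ]
  fr_gap[2, c("head1_x_nm", "head1_y_nm")] <- NA
  ann_gap <- annotate_movie(fr_gap)
  expect_equal(sum(ann_gap$transition_counts), 0L)

  # subsampling analyzes frames 0, k, 2k, ...
  fr50 <- do.call(rbind, lapply(0:49, function(i)
    frame_with_distances(25, 25, 30, frame_id = i, time_s = i * 0.1)))
  ann5 <- annotate_movie(fr50, subsample_every = 5)
  expect_equal(length(ann5$analyzed_frame_ids), 10L)
  expect_equal(ann5$analyzed_frame_ids, seq(0, 45, by = 5))
  expect_error(annotate_movie(fr50[0, ]), "empty")
})
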