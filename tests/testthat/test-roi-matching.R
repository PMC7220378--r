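test_that("rigid translation is recovered by zero-mean cross-correlation", {
  scene <- gen_roi_scene(10, field_px = c(96L, 96L), shift_px = c(0L, 0L),
                         seed = 1)
  expect_equal(unname(estimate_translation(scene$image_a, scene$image_a, 6)),
               c(0, 0))

  scene2 <- gen_roi_scene(10, field_px = c(96L, 96L), shift_px = c(5L, -3L),
                          seed = 2)
  expect_equal(unname(estimate_translation(scene2$image_a, scene2$image_b, 8)),
               c(5, -3))

  expect_error(estimate_translation(matrix(0, 8, 8), matrix(0, 8, 8), 2),
               "flat")
})

test_that("translation recovery tolerates 10% additive noise in >= 95% of runs", {
  scene <- gen_roi_scene(8, field_px = c(64L, 64L), shift_px = c(3L, 2L),
                         seed = 5)
  a0 <- (scene$image_a > 0) * 1
  b0 <- (scene$image_b > 0) * 1
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    a <- a0 + matrix(rnorm(length(a0), 0, 0.1), nrow(a0))
    b <- b0 + matrix(rnorm(length(b0), 0, 0.1), nrow(b0))
    sh <- estimate_translation(a, b, max_shift = 5, binarize = FALSE)
    hits <- hits + all(sh == c(3, 2))
  }
  expect_gte(hits, 95)
})

test_that("overlap ratio is intersection over union with the inclusive 0.3 rule", {
  m <- matrix(FALSE, 20, 20)
  a <- m; a[1:10, 1:10] <- TRUE
  expect_equal(overlap_ratio(a, a), 1.0)

  # two 10x10 squares sharing a 5x10 strip: 50 / 150
  b <- m; b[1:10, 6:15] <- TRUE
  expect_equal(overlap_ratio(a, b), 50 / 150)

  # disjoint and empty
  c0 <- m; c0[12:19, 12:19] <- TRUE
  expect_equal(overlap_ratio(a, c0), 0)
  expect_warning(expect_equal(overlap_ratio(a, m), 0), "empty")

  # boundary case: areas 65/65, overlap 30 -> 30/100 = 0.30 exactly, MATCHES
  la <- matrix(0L, 20, 20); lb <- matrix(0L, 20, 20)
  la[1:5, 1:13] <- 1L            # area 65
  lb[1:5, 8:20] <- 1L            # area 65, overlap columns 8:13 -> 30 px
  expect_equal(overlap_ratio(la > 0, lb > 0), 0.30)
  res <- match_rois(la, lb, shift = c(0L, 0L))
  expect_equal(nrow(res$pairs), 1)
  expect_true(res$pairs$matched[1])
})

test_that("ROI matching recovers generator ground truth one-to-one", {
  scene <- gen_roi_scene(12, field_px = c(160L, 160L), roi_px = c(8L, 8L),
                         shift_px = c(4L, -2L),
                         perturb_px = rep(c(0L, 2L, 6L), 4), seed = 7)
  # designed ratios: 1, (8-2)*8/(128-48)=0.6, (8-6)*8/(128-16)=0.143
  res <- match_rois(scene$image_a, scene$image_b, scene$shift_px)
  got <- res$pairs[res$pairs$matched, ]
  truth <- scene$truth[scene$truth$should_match, ]
  expect_setequal(got$label_a, truth$label)
  expect_equal(got$label_a, got$label_b)
  expect_equal(sort(unique(round(got$ratio, 6))), c(0.6, 1))
  # unmatched ROIs listed
  expect_setequal(res$unmatched_a, scene$truth$label[!scene$truth$should_match])

  # all-disjoint sets give zero pairs
  la <- matrix(0L, 10, 10); la[1:3, 1:3] <- 1L
  lb <- matrix(0L, 10, 10); lb[7:9, 7:9] <- 2L
  r0 <- match_rois(la, lb, c(0L, 0L))
  expect_equal(nrow(r0$pairs[r0$pairs$matched, ]), 0)

  # symmetry: match(B, A) with inverted shift transposes the pairing
  rev <- match_rois(scene$image_b, scene$image_a, -scene$shift_px)
  revm <- rev$pairs[rev$pairs$matched, ]
  expect_equal(revm[order(revm$label_b), c("label_b", "label_a")],
               got[order(got$label_a), c("label_a", "label_b")],
               ignore_attr = TRUE)
})

test_that("pairing is stable under ROI relabeling", {
  scene <- gen_roi_scene(6, field_px = c(64L, 64L), shift_px = c(2L, 1L),
                         seed = 9)
  res1 <- match_rois(scene$image_a, scene$image_b, scene$shift_px)
  perm <- c(4L, 6L, 1L, 3L, 5L, 2L)
  b2 <- scene$image_b
  b2[scene$image_b > 0] <- perm[scene$image_b[scene$image_b > 0]]
  res2 <- match_rois(scene$image_a, b2, scene$shift_px)
  m1 <- res1$pairs[res1$pairs$matched, ]
  m2 <- res2$pairs[res2$pairs$matched, ]
  expect_equal(m2$label_b[order(m2$label_a)],
               perm[m1$label_b[order(m1$label_a)]])
})
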