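test_that("degenerate images segment to nothing (or error when empty)", {
  expect_equal(nrow(segment_cells(matrix(100, 50, 50))), 0L)
  expect_error(segment_cells(matrix(numeric(0L), 0, 0)), "empty")
  expect_error(segment_cells(array(1, c(2, 2, 2))), "2D")
})

test_that("objects below the minimum area are removed", {
  img <- matrix(200, 120, 120)
  img[50:63, 50:63] <- 50                  # 14 x 14 = 196 px < 300
  expect_equal(nrow(segment_cells(img)), 0L)
  img[40:70, 40:70] <- 50                  # 31 x 31 = 961 px
  res <- segment_cells(img)
  expect_equal(nrow(res), 1L)
  expect_gte(res$area, 300L)
  # half-open 0-based rectangle of rows/cols 40..70 (1-based)
  expect_equal(c(res$row_min, res$row_max), c(39L, 70L))
})

test_that("well-separated synthetic cells are recovered with tight boxes", {
  cfg <- image_sim_config(rows = 420L, cols = 420L, n_planes = 3L,
                          n_cells = 3L, radius_range = c(20, 20), seed = 8)
  sim <- generate_image_pair(cfg)
  res <- segment_cells(sim$brightfield[, , sim$focal_plane])
  expect_equal(nrow(res), 3L)
  # match regions to ground truth by center distance; the true extent is
  # the cell radius plus its boundary ring
  for (i in seq_len(nrow(sim$cells))) {
    ctr_r <- (res$row_min + res$row_max) / 2
    ctr_c <- (res$col_min + res$col_max) / 2
    d <- sqrt((ctr_r - sim$cells$row[i])^2 + (ctr_c - sim$cells$col[i])^2)
    j <- which.min(d)
    expect_lt(d[j], 3)
    true_half <- sim$cells$radius[i] + cfg$ring_width
    expect_lt(abs((res$row_max[j] - res$row_min[j]) / 2 - true_half), 3)
    expect_lt(abs((res$col_max[j] - res$col_min[j]) / 2 - true_half), 3)
  }
})

test_that("Otsu segmentation is invariant under a global additive offset", {
  sim <- generate_image_pair(small_sim_config(seed = 12, n_cells = 4L))
  slice <- sim$brightfield[, , 2]
  expect_equal(segment_cells(slice), segment_cells(slice + 17.3))
})

test_that("regions never outnumber raw binarization components", {
  sim <- generate_image_pair(small_sim_config(seed = 31, n_cells = 5L))
  slice <- sim$brightfield[, , 2]
  res <- segment_cells(slice)
  rng <- range(slice)
  th <- rng[1] + EBImage::otsu(EBImage::Image((slice - rng[1]) /
                                              (rng[2] - rng[1]))) *
    (rng[2] - rng[1])
  raw_components <- max(EBImage::bwlabel(slice < th))
  expect_lte(nrow(res), raw_components)
})

test_that("fixed thresholds and polarity inversion are available", {
  img <- matrix(0, 100, 100)
  img[30:60, 30:60] <- 100                 # bright object on dark background
  res <- segment_cells(img, segmentation_params(threshold = "fixed",
                                                threshold_value = 50,
                                                dark_cells = FALSE))
  expect_equal(nrow(res), 1L)
  expect_error(segmentation_params(threshold = "fixed"), "threshold_value")
})

test_that("slice selection honours overrides and finds the sharp plane", {
  single <- array(matrix(rnorm(100), 10), c(10, 10, 1))
  expect_equal(select_brightfield_slice(single), 1L)
  ten <- array(rnorm(1000), c(10, 10, 10))
  expect_equal(select_brightfield_slice(ten, override = 3), 3L)
  expect_error(select_brightfield_slice(ten, override = 11), "outside")

  # plane 2 sharp, the others blurred copies: the focus score must peak at 2
  cfg <- image_sim_config(rows = 300L, cols = 300L, n_planes = 3L,
                          n_cells = 4L, seed = 77)
  sim <- generate_image_pair(cfg)         # focal plane = 2 for 3 planes
  expect_equal(sim$focal_plane, 2L)
  expect_equal(select_brightfield_slice(sim$brightfield), 2L)

  # explicit construction: 5 planes of increasing blur away from plane 2
  sharp <- sim$brightfield[, , 2]
  stack5 <- array(0, c(dim(sharp), 5))
  for (p in 1:5) {
    stack5[, , p] <- if (p == 2) sharp else
      as.matrix(EBImage::gblur(sharp, sigma = 1.5 * abs(p - 2)))
  }
  expect_equal(select_brightfield_slice(stack5), 2L)
})
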