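test_that("maximum projection matches trivial cases and the loop oracle", {
  one <- array(matrix(1:12, 3), c(3, 4, 1))
  expect_equal(max_projection(one), matrix(1:12, 3))
  two <- array(c(rep(10, 6), rep(20, 6)), c(2, 3, 2))
  expect_equal(max_projection(two), matrix(20, 2, 3))
  set.seed(6)
  rnd <- array(rnorm(6 * 7 * 5), c(6, 7, 5))
  expect_equal(max_projection(rnd), loop_max_projection(rnd))
  expect_error(max_projection(array(1, c(0, 3, 1))), "empty")
})

test_that("false-positive rules remove the documented region types", {
  proj <- matrix(100, 400, 400) + outer(1:400, 1:400, function(i, j) (i + j) %% 31)
  regs <- data.frame(label = 1:3,
                     area = c(7200, 2500, 2500),
                     row_min = c(100L, 100L, 200L),
                     col_min = c(100L, 200L, 100L),
                     row_max = c(220L, 150L, 250L),
                     col_max = c(160L, 250L, 150L))
  fp <- filter_false_positives(regs, proj)
  expect_true(fp$flags$oversize[1])           # 120 x 60 rectangle
  expect_false(any(fp$flags$oversize[2:3]))
  expect_equal(fp$kept$label, c(2L, 3L))      # 50 x 50, interior, textured

  proj2 <- proj
  proj2[120, 220] <- 255                      # saturate one pixel of region 2
  fp2 <- filter_false_positives(regs, proj2)
  expect_true(fp2$flags$saturated[2])
  expect_equal(fp2$kept$label, 3L)

  flat <- matrix(100, 400, 400)
  fp3 <- filter_false_positives(regs[3, ], flat)
  expect_true(fp3$flags$low_sd)               # sd 0 < 5

  near_edge <- data.frame(label = 1L, area = 2500,
                          row_min = 5L, col_min = 100L,
                          row_max = 55L, col_max = 150L)
  fp4 <- filter_false_positives(near_edge, proj)
  expect_true(fp4$flags$border)               # within 5% of the top edge

  small <- data.frame(label = 1L, area = 900, row_min = 100L, col_min = 100L,
                      row_max = 130L, col_max = 130L)
  expect_true(filter_false_positives(small, proj)$flags$undersize)

  outside <- data.frame(label = 1L, area = 100, row_min = 390L,
                        col_min = 390L, row_max = 410L, col_max = 410L)
  expect_error(filter_false_positives(outside, proj), "outside")
})

test_that("false-positive filtering is idempotent", {
  sim <- generate_image_pair(small_sim_config(seed = 14, n_cells = 5L))
  regs <- segment_cells(sim$brightfield[, , 2])
  proj <- max_projection(sim$gfp)
  fp1 <- filter_false_positives(regs, proj)
  fp2 <- filter_false_positives(fp1$kept, proj)
  expect_equal(fp2$kept, fp1$kept)
  expect_true(all(fp2$flags$kept))
})

test_that("cytosolic intensity matches enumerated quantile values", {
  const <- matrix(50, 5, 10)
  expect_equal(cytosolic_intensity(const),
               c(raw = 50, background = 50, corrected = 0))
  crop <- matrix(0:99, 10, 10)
  ci <- cytosolic_intensity(crop)
  expect_equal(ci[["raw"]], 24.75)            # linear-interpolation quantile
  expect_equal(ci[["background"]], 4.5)       # mean of 0..9
  expect_equal(ci[["corrected"]], 20.25)
  expect_error(cytosolic_intensity(numeric(0L)), "empty")
})

test_that("corrected intensity is offset-invariant and gain-linear", {
  set.seed(3)
  crop <- matrix(runif(400, 10, 200), 20, 20)
  base <- cytosolic_intensity(crop)
  shifted <- cytosolic_intensity(crop + 100)
  expect_equal(shifted[["corrected"]], base[["corrected"]])
  scaled <- cytosolic_intensity(crop * 3)
  expect_equal(scaled[["corrected"]], 3 * base[["corrected"]])
})

test_that("strain quantification recovers a two-fold cytosolic difference", {
  qa <- quantify_strain(list(generate_image_pair(
    small_sim_config(seed = 51, n_cells = 8L, gfp_level = 30))), "low")
  qb <- quantify_strain(list(generate_image_pair(
    small_sim_config(seed = 52, n_cells = 8L, gfp_level = 60))), "high")
  expect_gte(qa$summary$n, 6L)
  expect_gte(qb$summary$n, 6L)
  ratio <- qb$summary$median_corrected / qa$summary$median_corrected
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("centering modes behave as documented", {
  sim <- generate_image_pair(small_sim_config(seed = 53, n_cells = 6L))
  sub <- quantify_strain(list(sim), "s",
                         q_params = quant_params(centering = "subtract-median"))
  expect_equal(median(sub$measurements$centered), 0)
  div <- quantify_strain(list(sim), "s",
                         q_params = quant_params(centering = "divide-median"))
  expect_equal(median(div$measurements$centered), 1)
  none <- quantify_strain(list(sim), "s",
                          q_params = quant_params(centering = "none"))
  expect_equal(none$measurements$centered, none$measurements$corrected)
})

test_that("a fully flagged strain reports n = 0 with a note", {
  sim <- generate_image_pair(small_sim_config(seed = 54, n_cells = 3L))
  res <- quantify_strain(list(sim), "s",
                         fp_params = filter_params(min_axis = 90L,
                                                   max_axis = 95L))
  expect_equal(res$summary$n, 0L)
  expect_equal(res$summary$note, "no cells")
  expect_equal(nrow(res$measurements), 0L)
})

test_that("mismatched channel shapes are rejected", {
  sim <- generate_image_pair(small_sim_config(seed = 55, n_cells = 2L))
  bad <- list(brightfield = sim$brightfield,
              gfp = sim$gfp[1:100, 1:100, , drop = FALSE])
  expect_error(quantify_strain(list(bad), "s"), "shape")
})
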