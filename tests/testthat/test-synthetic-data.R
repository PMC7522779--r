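test_that("image generation is deterministic under a fixed seed", {
  cfg <- small_sim_config(seed = 42, n_cells = 4L)
  a <- generate_image_pair(cfg)
  b <- generate_image_pair(cfg)
  expect_identical(a$brightfield, b$brightfield)
  expect_identical(a$gfp, b$gfp)
  expect_identical(a$cells, b$cells)
})

test_that("a zero-cell field is noise only with empty ground truth", {
  sim <- generate_image_pair(small_sim_config(seed = 5, n_cells = 0L))
  expect_equal(nrow(sim$cells), 0L)
  # pure noise: no pixel anywhere near a cytosolic signal level
  expect_lt(max(sim$gfp), 40)
  expect_equal(dim(sim$brightfield), dim(sim$gfp))
})

test_that("generated stacks respect the saturation cap and cell count", {
  cfg <- small_sim_config(seed = 9, n_cells = 5L, focus_amplitude = 400)
  sim <- generate_image_pair(cfg)
  expect_lte(max(sim$gfp), cfg$saturation)
  expect_lte(max(sim$brightfield), cfg$saturation)
  expect_gte(min(sim$gfp), 0)
  expect_equal(nrow(sim$cells), 5L)
  expect_equal(sim$cells$id, 1:5)
  # interiors lie within the field
  expect_true(all(sim$cells$row - sim$cells$radius > 0))
  expect_true(all(sim$cells$row + sim$cells$radius < cfg$rows))
})

test_that("invalid image configurations are rejected", {
  expect_error(image_sim_config(rows = 0), "positive")
  expect_error(image_sim_config(n_cells = -1), "cell count")
  expect_error(image_sim_config(saturation = 100, bf_background = 200))
})

test_that("TIFF round-trip preserves stack shape and 8-bit content", {
  sim <- generate_image_pair(small_sim_config(seed = 3, n_cells = 2L))
  dir <- withr::local_tempdir()
  paths <- write_image_pair(sim, dir, prefix = "t")
  back <- read_stack_tiff(paths[["brightfield"]])
  expect_equal(dim(back), dim(sim$brightfield))
  # 8-bit storage quantizes to 255 levels
  expect_lt(max(abs(back - sim$brightfield)), 255 / 255 + 1e-9 + 0.5)
  truth <- read.csv(paths[["truth"]])
  expect_equal(truth$id, sim$cells$id)
})

test_that("evidence generation covers true sites per protease as configured", {
  cfg <- evidence_sim_config(protein_length = 200L,
                             true_sites = c(10L, 50L, 90L),
                             detect_prob = 1, n_spurious = 0L, seed = 1)
  ev <- generate_evidence_table(cfg)
  expect_equal(nrow(ev), 9L)               # 3 sites x 3 proteases
  expect_true(all(ev$true_site))
  expect_equal(sort(unique(as.integer(ev$positions))), c(10L, 50L, 90L))

  none <- generate_evidence_table(
    evidence_sim_config(protein_length = 200L, true_sites = c(10L, 50L),
                        detect_prob = 0, n_spurious = 0L, seed = 1))
  expect_equal(nrow(none), 0L)
})

test_that("evidence generation is reproducible and validates sites", {
  cfg <- evidence_sim_config(protein_length = 150L, true_sites = c(7L, 80L),
                             n_spurious = 4L, seed = 13)
  expect_identical(generate_evidence_table(cfg), generate_evidence_table(cfg))
  expect_error(evidence_sim_config(protein_length = 100L, true_sites = 150L),
               "within the protein")
})

test_that("simulated true sites pass and spurious sites fail the filter", {
  true16 <- c(6L, 15L, 65L, 76L, 214L, 252L, 254L, 263L, 266L, 268L, 280L,
              288L, 307L, 310L, 313L, 327L)
  cfg <- evidence_sim_config(protein_length = 341L, true_sites = true16,
                             n_spurious = 10L, seed = 99)
  tab <- filter_and_assemble_sites(generate_evidence_table(cfg))
  expect_equal(tab$position, true16)
  # under partial detection the filter still recovers exactly what was seen
  cfg2 <- evidence_sim_config(protein_length = 341L, true_sites = true16,
                              detect_prob = c(0.6, 0.6, 0.9),
                              n_spurious = 10L, seed = 100)
  ev2 <- generate_evidence_table(cfg2)
  tab2 <- filter_and_assemble_sites(ev2)
  expect_equal(tab2$position,
               sort(unique(as.integer(ev2$positions[ev2$true_site]))))
})

test_that("iBAQ table generation is positive, reproducible, bait-checked", {
  tab <- generate_ibaq_table(20L, "PEX14", 3L, seed = 4)
  expect_equal(dim(tab), c(20L, 3L))
  expect_true(all(tab > 0))
  expect_identical(tab, generate_ibaq_table(20L, "PEX14", 3L, seed = 4))
  expect_error(generate_ibaq_table(5L, "PEX14", 2L, seed = 1,
                                   protein_ids = c("A", "B", "C", "D", "E")),
               "bait")
})
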