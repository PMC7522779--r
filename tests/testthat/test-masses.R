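test_that("peptide masses and m/z match hand-computed monoisotopic values", {
  # 6 x Gly (57.02146) + water + proton at z = 1
  expect_equal(peptide_mz("GGGGGG", 0, 1), 361.1466, tolerance = 1e-6)
  # phosphopeptide precursor, z = 2, theoretical monoisotopic value
  expect_equal(peptide_mz("AREQTIDSNASIPEWQK", 1, 2), 1026.973,
               tolerance = 1e-5)
  expect_equal(peptide_mass("GGGGGG"), 361.1466 - 1.007276, tolerance = 1e-4)
})

test_that("peptide mass is additive under concatenation (minus one water)", {
  set.seed(11)
  for (i in 1:25) {
    a <- random_protein(sample(3:20, 1))
    b <- random_protein(sample(3:20, 1))
    expect_equal(peptide_mass(paste0(a, b)),
                 peptide_mass(a) + peptide_mass(b) - 18.010565,
                 tolerance = 1e-9)
  }
})

test_that("m/z decreases with charge and neutral mass is recoverable", {
  for (z in 1:4) {
    mz <- peptide_mz("AREQTIDSNASIPEWQK", 1, z)
    if (z > 1) expect_lt(mz, peptide_mz("AREQTIDSNASIPEWQK", 1, z - 1))
    expect_equal(mz * z - z * 1.007276,
                 peptide_mass("AREQTIDSNASIPEWQK", 1), tolerance = 1e-6)
  }
})

test_that("invalid m/z requests are rejected", {
  expect_error(peptide_mz("GGGGGG", 0, 0), "charge")
  expect_error(peptide_mz("GAGA", 1, 1), "exceeds")
  expect_error(peptide_mass("GBZ"), "unknown residue")
})

test_that("multistage-activation neutral-loss offsets match H3PO4 / z", {
  expect_equal(msa_neutral_loss_offsets(1)$rounded, 98)
  expect_equal(msa_neutral_loss_offsets(2)$rounded, 49)
  expect_equal(msa_neutral_loss_offsets(3)$rounded, 32.7)
  for (z in 1:3) {
    expect_equal(msa_neutral_loss_offsets(z)$offset, 97.9769 / z,
                 tolerance = 1e-12)
  }
  expect_error(msa_neutral_loss_offsets(4), "charge")
  expect_error(msa_neutral_loss_offsets(0), "charge")
})

test_that("b/y fragment ions match standard formulas", {
  fr <- fragment_ions("GK")
  b1 <- fr$mz[fr$type == "b" & fr$index == 1 & !fr$neutral_loss]
  y1 <- fr$mz[fr$type == "y" & fr$index == 1 & !fr$neutral_loss]
  expect_equal(b1, 58.0287, tolerance = 1e-4)
  expect_equal(y1, 147.1128, tolerance = 1e-4)
})

test_that("neutral-loss variants appear only for site-containing fragments", {
  fr <- fragment_ions("ASKG", phospho_positions = 2L, max_charge = 2L)
  # b1 = A only: no site, no loss variant
  expect_false(any(fr$neutral_loss[fr$type == "b" & fr$index == 1]))
  # y1 = G, y2 = KG: no site either
  expect_false(any(fr$neutral_loss[fr$type == "y" & fr$index <= 2]))
  # b2 = AS(p): loss variant present, shifted by 97.9769 / z
  for (z in 1:2) {
    sel <- fr$type == "b" & fr$index == 2 & fr$charge == z
    expect_equal(fr$mz[sel & !fr$neutral_loss] - fr$mz[sel & fr$neutral_loss],
                 97.9769 / z, tolerance = 1e-9)
  }
  # unmodified peptide emits no loss variants at all
  expect_false(any(fragment_ions("ASKG")$neutral_loss))
  expect_error(fragment_ions("GK", phospho_positions = 5L), "position")
})

test_that("b/y complementarity holds with and without phosphorylation", {
  for (phos in list(integer(0L), 3L)) {
    pep <- "SAMPLER"
    fr <- fragment_ions(pep, phospho_positions = phos)
    fr <- fr[!fr$neutral_loss & fr$charge == 1, ]
    n <- nchar(pep)
    precursor <- peptide_mass(pep, length(phos))
    for (i in seq_len(n - 1L)) {
      b <- fr$mz[fr$type == "b" & fr$index == i]
      y <- fr$mz[fr$type == "y" & fr$index == n - i]
      expect_equal(b + y, precursor + 2 * 1.007276, tolerance = 1e-9)
    }
  }
})
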