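test_that("residue masses agree with an independent reference table", {
  for (code in names(REF_RESIDUE_MASS))
    expect_equal(residue_mass(code), REF_RESIDUE_MASS[[code]],
                 tolerance = 1e-7, label = code)
  expect_equal(residue_mass("J"), 113.08406, tolerance = 1e-5)
  expect_identical(residue_mass("I"), residue_mass("L"))
  expect_error(residue_mass("B"), "unknown residue")
  expect_error(residue_mass("GA"), "unknown residue")
})

test_that("formula masses are computed to sub-mDa accuracy", {
  expect_equal(formula_mass("H2O"), 18.01056, tolerance = 1e-5)
  expect_equal(formula_mass("C10H10NO2", charge = 1), 176.0706,
               tolerance = 1e-4)
  expect_equal(formula_mass("CO2") + formula_mass("H2O"), 62.0004,
               tolerance = 1e-4)
  # signed formulas: loss of water
  expect_equal(formula_mass("H-2O-1"), -18.01056, tolerance = 1e-5)
  # a cation m/z is lighter than the neutral by one electron mass
  expect_lt(formula_mass("C6H12N", 1), formula_mass("C6H12N"))
  expect_error(formula_mass("notaformula"), "unparseable|unsupported")
  expect_error(formula_mass("C2x3"), "unparseable|unsupported")
  expect_error(formula_mass("H2O", charge = -1), "charge")
})

test_that("peptide neutral masses are additive with terminal contributions", {
  expect_equal(peptide_neutral_mass(parse_peptide("AG")), 146.0691,
               tolerance = 1e-4)
  expect_equal(peptide_neutral_mass(parse_peptide("Bz-ARF-NH2")), 495.2594,
               tolerance = 1e-4)
  expect_error(peptide(character(0)), "at least one residue")
  # additivity vs the independent reference table, random peptides
  set.seed(11)
  for (k in 1:25) {
    seqs <- random_peptide_string(sample(2:12, 1))
    expect_equal(peptide_neutral_mass(parse_peptide(seqs)),
                 sum(REF_RESIDUE_MASS[strsplit(seqs, "")[[1]]]) + REF_WATER,
                 tolerance = 1e-4, label = seqs)
  }
  # amidation replaces the water terminus with NH3
  expect_equal(peptide_neutral_mass(parse_peptide("ARF-NH2")) -
                 peptide_neutral_mass(parse_peptide("ARF")),
               REF_NH3 - REF_WATER, tolerance = 1e-5)
})

test_that("precursor m/z reproduces the reported worked-example values", {
  expect_equal(precursor_mz(parse_peptide("KVIKMV"), 1), 717.4697,
               tolerance = 0.001)
  expect_equal(precursor_mz(parse_peptide("Bz-ARFG"), 1), 554.2719,
               tolerance = 0.001)
  expect_equal(precursor_mz(parse_peptide("Bz-ARF-NH2"), 1), 496.2648,
               tolerance = 0.002)
  expect_error(precursor_mz(parse_peptide("AG"), 0), "positive integer")
})

test_that("charge scaling follows (mz1 + (z-1) proton)/z", {
  set.seed(12)
  for (k in 1:10) {
    p <- parse_peptide(random_peptide_string(sample(2:10, 1)))
    expect_equal(precursor_mz(p, 2),
                 (precursor_mz(p, 1) + 1.00728) / 2, tolerance = 1e-5)
  }
})

test_that("fragment conventions match the b/y/a/c/z/w/d definitions", {
  p <- parse_peptide("Bz-ARF-NH2")
  expect_equal(fragment_mz(p, ion("b", 1)), 176.0705, tolerance = 5e-4)
  expect_equal(fragment_mz(p, ion("y", 1)), 165.1020, tolerance = 5e-4)
  # the final b ion of an amidated peptide sits one NH3 below [M+H]+
  expect_equal(precursor_mz(p, 1) - fragment_mz(p, ion("b", 3)),
               17.026, tolerance = 1e-3)
  q <- parse_peptide("KVIKMV")
  expect_equal(fragment_mz(q, ion("z", 4)), 474.2870, tolerance = 1e-4)
  expect_equal(fragment_mz(q, ion("w", 4, side_chain_loss = 29.03913)),
               445.2479, tolerance = 1e-4)
  expect_equal(fragment_mz(q, ion("w", 4, side_chain_loss = 43.05478)),
               431.2323, tolerance = 1e-4)
  expect_error(fragment_mz(q, ion("b", 99)), "out of range")
  expect_error(ion("w", 4), "side_chain_loss")
})

test_that("series spacings are exact", {
  p <- parse_peptide("KVIKMV")
  for (i in 1:5) {
    expect_equal(fragment_mz(p, ion("b", i)) - fragment_mz(p, ion("a", i)),
                 27.99491, tolerance = 1e-5)
    expect_equal(fragment_mz(p, ion("c", i)) - fragment_mz(p, ion("b", i)),
                 17.02655, tolerance = 1e-5)
    expect_equal(fragment_mz(p, ion("y", i)) - fragment_mz(p, ion("z", i)),
                 16.01872, tolerance = 1e-5)
  }
})

test_that("b/y complementarity holds for random unmodified peptides", {
  set.seed(13)
  for (k in 1:15) {
    p <- parse_peptide(random_peptide_string(sample(2:12, 1)))
    n <- length(p$residues)
    mh <- precursor_mz(p, 1)
    for (i in seq_len(n - 1))
      expect_equal(fragment_mz(p, ion("b", i)) +
                     fragment_mz(p, ion("y", n - i)) - mh - 1.0072765,
                   0, tolerance = 1e-6)
  }
})

test_that("the I/L immonium ion and its NH3 loss carry the 86/69 signature", {
  imm <- fragment_mz(parse_peptide("IG"), ion("immonium", 1))
  expect_equal(round(imm), 86)
  expect_equal(imm, 86.0964, tolerance = 2e-4)
  expect_equal(round(imm - 17.02655), 69)
})

test_that("neutral losses subtract before charge scaling", {
  p <- parse_peptide("KVIKMV")
  full <- fragment_mz(p, ion("precursor", charge = 2))
  lost <- fragment_mz(p, ion("precursor", charge = 2,
                             neutral_losses = 43.98983))
  expect_equal(full - lost, 43.98983 / 2, tolerance = 1e-6)
})

test_that("mass_delta_match ranks explanations by absolute error", {
  hits <- mass_delta_match(113.084, 0.02)
  expect_identical(hits$explanation[1], "J")
  hits <- mass_delta_match(226.059, 0.02)
  expect_true("pyroglutamate-ED" %in% hits$explanation)
  # 128.076 sits between Gln (128.05858) and Lys (128.09496); both are
  # inside a 0.02 Da window, Gln closer
  hits <- mass_delta_match(128.076, 0.02)
  expect_identical(hits$explanation[1:2], c("Q", "K"))
  expect_identical(nrow(mass_delta_match(7.77, 0.001)), 0L)
  expect_error(mass_delta_match(113, tol = 0), "tol")
})
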