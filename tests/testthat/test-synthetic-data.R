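test_that("a clean unmodified dipeptide spectrum is exactly its y1 ladder", {
  s <- simulate_ms2("AG", clean_params())
  # b1 is suppressed for non-acylated N-termini, leaving y1 alone
  expect_equal(s$peaks$mz, 76.0393, tolerance = 1e-4)
  expect_identical(s$charge, 1L)
})

test_that("clean simulated peak sets equal the theoretical ion set", {
  p <- parse_peptide("KVAGF")
  s <- simulate_ms2(p, clean_params())
  theo <- fragment_table(p, charges = 1L)
  theo <- theo[!(theo$series == "b" & theo$index == 1L), ]
  expect_equal(sort(s$peaks$mz), sort(theo$mz), tolerance = 1e-6)
  # an N-acylated peptide additionally shows its b1 ion
  s2 <- simulate_ms2("Bz-ARFG", clean_params())
  expect_true(any(abs(s2$peaks$mz - 176.0706) < 1e-4))
})

test_that("simulation is deterministic given the seed", {
  params <- sim_params(mass_error_sd = 5, ion_detection_prob = 0.8,
                       noise_peaks = 10, seed = 99)
  s1 <- simulate_ms2("KVIKMV", params)
  s2 <- simulate_ms2("KVIKMV", params)
  expect_identical(s1$peaks, s2$peaks)
  b1 <- generate_benchmark_set(5, params = sim_params(seed = 42))
  b2 <- generate_benchmark_set(5, params = sim_params(seed = 42))
  expect_identical(lapply(b1, `[[`, "sequence"),
                   lapply(b2, `[[`, "sequence"))
  expect_identical(b1[[3]]$spectra$ms2$peaks, b2[[3]]$spectra$ms2$peaks)
})

test_that("detection probability zero yields an empty peak list", {
  s <- simulate_ms2("KVIKMV", sim_params(ion_detection_prob = 0,
                                         noise_peaks = 0))
  expect_identical(nrow(s$peaks), 0L)
  expect_error(simulate_ms2("A", clean_params()), "length >= 2")
})

test_that("simulated mass errors scale as expected with the ppm setting", {
  p <- parse_peptide("KVIKMVWDES")
  theo <- fragment_table(p, charges = 1L)
  theo <- theo[!(theo$series == "b" & theo$index == 1L), ]
  errs <- c()
  for (seed in 1:40) {
    s <- simulate_ms2(p, sim_params(mass_error_sd = 10, seed = seed),
                      charge = 1L)
    errs <- c(errs, (sort(s$peaks$mz) - sort(theo$mz)) / sort(theo$mz) * 1e6)
  }
  # mean |error| of a zero-mean Gaussian is sd * sqrt(2/pi)
  expect_equal(mean(abs(errs)), 10 * sqrt(2 / pi), tolerance = 0.15)
})

test_that("diagnostic neutral losses appear for carboxybenzoyl precursors", {
  s <- simulate_ms2("cBz-AGH", clean_params())
  prec <- precursor_mz(parse_peptide("cBz-AGH"), 1)
  expect_true(any(abs(s$peaks$mz - (prec - 43.98983)) < 1e-4))
  expect_true(any(abs(s$peaks$mz - (prec - 62.00039)) < 1e-4))
})

test_that("ETD MS3 spectra carry the site-specific w ion", {
  p <- parse_peptide("KVI/LKMV")
  sI <- simulate_etd_ms3(p, 3, "I", clean_params())
  expect_true(any(abs(sI$peaks$mz - 474.2870) < 1e-4))  # z4
  expect_true(any(abs(sI$peaks$mz - 445.2479) < 1e-4))  # w4 = z4 - C2H5
  sL <- simulate_etd_ms3(p, 3, "L", clean_params())
  expect_true(any(abs(sL$peaks$mz - 431.2323) < 1e-4))  # w4 = z4 - C3H7
  expect_identical(sI$ms_level, 3L)
  expect_identical(sI$activation, "ETD")
  expect_error(simulate_etd_ms3(parse_peptide("I/LKMV"), 1, "I",
                                clean_params()), "cannot be probed")
  expect_error(simulate_etd_ms3(p, 4, "I", clean_params()), "not an Ile/Leu")
})

test_that("immonium MS3 spectra implement the 86/69 abundance rule", {
  sI <- simulate_immonium_ms3("I", params = clean_params())
  base <- max(sI$peaks$intensity)
  r69 <- sI$peaks$intensity[abs(sI$peaks$mz - 69.0699) < 1e-3] / base
  expect_equal(r69, 0.40, tolerance = 1e-6)
  sL <- simulate_immonium_ms3("L", params = clean_params())
  r69L <- sL$peaks$intensity[abs(sL$peaks$mz - 69.0699) < 1e-3] /
    max(sL$peaks$intensity)
  expect_lt(r69L, 0.10)
  s0 <- simulate_immonium_ms3("I", ratio_69 = 0, params = clean_params())
  expect_false(any(abs(s0$peaks$mz - 69.0699) < 0.02))
  expect_equal(sI$parent_selection, 86.0964, tolerance = 1e-3)
})

test_that("benchmark sets honor lengths, modifications and I/L bookkeeping", {
  bench <- generate_benchmark_set(60, length_range = c(2, 12),
                                  params = sim_params(seed = 7))
  lens <- vapply(bench, function(r) length(r$peptide$residues), integer(1))
  expect_true(all(lens >= 2 & lens <= 12))
  # every I/L-ambiguous position has a recorded truth
  for (r in bench) {
    amb <- which(r$peptide$residues == "J")
    expect_setequal(as.character(amb), names(r$il_truth))
    expect_true(all(r$il_truth %in% c("I", "L")))
  }
  # zero modification frequencies give unmodified records
  plain <- generate_benchmark_set(20, mod_frequencies = c(benzoyl = 0),
                                  params = sim_params(seed = 8))
  for (r in plain) {
    expect_true(is.na(r$peptide$nterm))
    expect_true(is.na(r$peptide$cterm))
    expect_length(r$peptide$residue_mods, 0)
  }
  expect_error(generate_benchmark_set(5, length_range = c(1, 3)),
               "length_range")
})
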