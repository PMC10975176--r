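test_that("w-ion calls recover both ground truths on clean ETD spectra", {
  p <- parse_peptide("KVI/LKMV")
  sI <- simulate_etd_ms3(p, 3, "I", clean_params())
  callI <- call_il_from_wd(sI, p, 3)
  expect_identical(callI$call, "I")
  expect_identical(callI$method, "wd_ion")
  expect_equal(callI$diagnostic_delta, 29.03913, tolerance = 1e-4)
  sL <- simulate_etd_ms3(p, 3, "L", clean_params())
  callL <- call_il_from_wd(sL, p, 3)
  expect_identical(callL$call, "L")
  expect_equal(callL$diagnostic_delta, 43.05478, tolerance = 1e-4)
})

test_that("conflicting or missing w-ion evidence downgrades to ambiguous", {
  p <- parse_peptide("KVI/LKMV")
  sI <- simulate_etd_ms3(p, 3, "I", clean_params())
  # inject the other side-chain loss as well
  z4 <- fragment_mz(p, ion("z", 4))
  both <- spectrum(precursor_mz = sI$precursor_mz, charge = 2L,
                   ms_level = 3L, activation = "ETD",
                   parent_selection = sI$parent_selection,
                   peaks = rbind(sI$peaks,
                                 data.frame(mz = z4 - 43.05478,
                                            intensity = 100)))
  expect_identical(call_il_from_wd(both, p, 3)$call, "ambiguous")
  # strip the covering z ion: w alone is not accepted
  noz <- spectrum(precursor_mz = sI$precursor_mz, charge = 2L,
                  ms_level = 3L, activation = "ETD",
                  parent_selection = sI$parent_selection,
                  peaks = sI$peaks[abs(sI$peaks$mz - z4) > 1e-4, ])
  callz <- call_il_from_wd(noz, p, 3)
  expect_identical(callz$call, "ambiguous")
  expect_match(callz$reason, "backbone")
  expect_error(call_il_from_wd(simulate_ms2("KVIKMV", clean_params()),
                               p, 3), "ETD")
})

test_that("w-ion calls ignore noise peaks away from the diagnostics", {
  p <- parse_peptide("KVI/LKMV")
  params <- sim_params(mass_error_sd = 0, noise_peaks = 40,
                       noise_intensity_max = 0.5, seed = 5)
  s <- simulate_etd_ms3(p, 3, "I", params)
  near <- abs(outer(s$peaks$mz, c(445.2479, 431.2323), "-")) < 0.02
  bad <- rowSums(near) > 0 &
    abs(s$peaks$mz - 445.2479) > 1e-3  # keep the real w ion
  s2 <- spectrum(precursor_mz = s$precursor_mz, charge = 2L, ms_level = 3L,
                 activation = "ETD", parent_selection = s$parent_selection,
                 peaks = s$peaks[!bad, ])
  expect_identical(call_il_from_wd(s2, p, 3)$call, "I")
})

test_that("immonium calls follow the inclusive 10% threshold", {
  expect_identical(
    call_il_from_immonium(simulate_immonium_ms3("I", params = clean_params()))$call,
    "I")
  expect_identical(
    call_il_from_immonium(simulate_immonium_ms3("L", params = clean_params()))$call,
    "L")
  # boundary: exactly 10% is called I
  s10 <- simulate_immonium_ms3("L", ratio_69 = 0.10, params = clean_params())
  expect_identical(call_il_from_immonium(s10)$call, "I")
  s09 <- simulate_immonium_ms3("L", ratio_69 = 0.0999,
                               params = clean_params())
  expect_identical(call_il_from_immonium(s09)$call, "L")
  # wrong parent selection is a precondition error
  wrong <- spectrum(precursor_mz = 120, charge = 1L, ms_level = 3L,
                    activation = "HCD", parent_selection = 120,
                    peaks = data.frame(mz = 120, intensity = 1))
  expect_error(call_il_from_immonium(wrong), "immonium")
})

test_that("external identifications fill ambiguous positions on agreement", {
  cands <- list(score_candidate("KVI/LKMV",
                                simulate_ms2("KVIKMV", clean_params())))
  ext <- data.frame(spectrum_title = "t1", sequence = "KVIKMV")
  out <- reconcile_external_ids(cands, ext)
  expect_identical(out[[1]]$peptide$residues[3], "I")
  expect_identical(unname(attr(out[[1]]$peptide, "il_methods")["3"]),
                   "external")
  expect_length(attr(out, "log"), 0)

  # mismatching sequence: unchanged and logged
  out2 <- reconcile_external_ids(cands,
    data.frame(spectrum_title = "t1", sequence = "KVAKMV"))
  expect_identical(out2[[1]]$peptide$residues[3], "J")
  expect_length(attr(out2, "log"), 1)

  # row for an unknown spectrum: skipped and logged
  out3 <- reconcile_external_ids(cands,
    data.frame(spectrum_title = "zzz", sequence = "KVIKMV"),
    titles = "t1")
  expect_identical(out3[[1]]$peptide$residues[3], "J")
  expect_length(attr(out3, "log"), 1)
  expect_error(reconcile_external_ids(cands, data.frame(x = 1)), "columns")
})

test_that("method precedence is wd > immonium > external, disagreement downgrades", {
  wd <- call_il_from_wd(simulate_etd_ms3(parse_peptide("KVI/LKMV"), 3, "I",
                                         clean_params()),
                        parse_peptide("KVI/LKMV"), 3)
  imm_agree <- call_il_from_immonium(
    simulate_immonium_ms3("I", params = clean_params()))
  imm_clash <- call_il_from_immonium(
    simulate_immonium_ms3("L", params = clean_params()))
  expect_identical(resolve_il_calls(list(imm_agree, wd))$method, "wd_ion")
  expect_identical(resolve_il_calls(list(wd, imm_clash))$call, "ambiguous")
  expect_identical(resolve_il_calls(list())$call, "ambiguous")
})

test_that("benchmark MS3 spectra are called perfectly under clean conditions", {
  bench <- generate_benchmark_set(40, params = clean_params(seed = 42))
  n_checked <- 0L
  for (rec in bench) {
    for (nm in names(rec$spectra)) {
      if (grepl("^etd\\.", nm)) {
        site <- as.integer(sub("^etd\\.", "", nm))
        call <- call_il_from_wd(rec$spectra[[nm]], rec$peptide, site)
        expect_identical(call$call, unname(rec$il_truth[as.character(site)]))
        n_checked <- n_checked + 1L
      }
      if (grepl("^imm\\.", nm)) {
        site <- as.integer(sub("^imm\\.", "", nm))
        call <- call_il_from_immonium(rec$spectra[[nm]])
        expect_identical(call$call, unname(rec$il_truth[as.character(site)]))
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gt(n_checked, 20)
})
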