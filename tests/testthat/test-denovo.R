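test_that("the spectrum graph anchors 0 and the neutral mass", {
  s <- simulate_ms2("AG", clean_params(), charge = 1L)
  g <- build_spectrum_graph(s, 0.02, charge = 1)
  expect_equal(min(g$nodes), 0)
  expect_equal(max(g$nodes), 146.0691, tolerance = 1e-3)
  # the A edge from the anchor and the final G+H2O step both exist
  expect_true(any(g$edges$from == 0 &
                    g$edges$explanation == "A" &
                    abs(g$edges$to - 71.0371) < 0.02))
  expect_true(any(abs(g$edges$to - g$neutral_mass) < 1e-9 &
                    g$edges$explanation == "G+H2O"))
})

test_that("an empty spectrum gives an anchor-only graph and no candidates", {
  s <- spectrum(precursor_mz = 500.777, charge = 1L,
                peaks = data.frame(mz = numeric(0), intensity = numeric(0)))
  g <- build_spectrum_graph(s, 0.02, charge = 1)
  expect_length(g$nodes, 2)
  expect_identical(nrow(g$edges), 0L)
  r <- denovo(s)
  expect_length(r$candidates, 0)
})

test_that("a missing charge raises the hypothesis error path", {
  s <- spectrum(precursor_mz = 147.0764, charge = 0L,
                peaks = data.frame(mz = 76.0393, intensity = 1))
  expect_error(build_spectrum_graph(s, 0.02), "charge")
  # denovo tries 1+ then 2+ hypotheses instead
  r <- denovo(s)
  expect_true("AG" %in% r$table$sequence)
})

test_that("enumeration on the clean AG ladder matches exhaustive search", {
  s <- simulate_ms2("AG", clean_params(), charge = 1L)
  got <- enumerate_sequences(s, charge = 1)
  expect_identical(got, c("AG", "GA", "Q"))
  expect_identical(got, oracle_enumerate(s, charge = 1))
})

test_that("enumeration equals the generate-and-test oracle on short ladders", {
  set.seed(31)
  peps <- c(replicate(4, random_peptide_string(2)),
            replicate(4, random_peptide_string(3)),
            replicate(4, random_peptide_string(4)))
  for (txt in peps) {
    s <- simulate_ms2(txt, clean_params(), charge = 1L,
                      registry = empty_registry())
    expect_identical(enumerate_sequences(s, charge = 1),
                     oracle_enumerate(s, charge = 1), label = txt)
  }
})

test_that("top candidates reproduce the worked examples", {
  r <- denovo(simulate_ms2("KVIKMV", clean_params()))
  expect_identical(r$table$sequence[1], "KVI/LKMV")
  expect_true(is.na(r$candidates[[1]]$peptide$cterm))  # free acid
  r2 <- denovo(simulate_ms2("Bz-ARFG", clean_params()))
  expect_identical(r2$table$sequence[1], "Bz-ARFG")
  r3 <- denovo(simulate_ms2("Bz-ARF-NH2", clean_params()))
  expect_identical(r3$table$sequence[1], "Bz-ARF-NH2")
})

test_that("scoring rewards site coverage and matched intensity", {
  p <- parse_peptide("KVAGF")
  s <- simulate_ms2(p, clean_params())
  full <- score_candidate(p, s)
  expect_equal(full$coverage, 1)
  # removing y ions that are redundant with b support keeps coverage
  keep <- !(abs(s$peaks$mz - fragment_mz(p, ion("y", 2))) < 1e-4)
  s2 <- spectrum(precursor_mz = s$precursor_mz, charge = s$charge,
                 peaks = s$peaks[keep, ])
  partial <- score_candidate(p, s2)
  expect_equal(partial$coverage, 1)
  expect_lt(partial$score, full$score)
  # no matches at all: score 0
  s3 <- spectrum(precursor_mz = s$precursor_mz, charge = s$charge,
                 peaks = data.frame(mz = 1500, intensity = 1))
  expect_equal(score_candidate(p, s3)$score, 0)
})

test_that("ranking is invariant to input peak order", {
  s <- simulate_ms2("KVAGF", clean_params())
  set.seed(32)
  perm <- sample(nrow(s$peaks))
  s2 <- spectrum(title = s$title, precursor_mz = s$precursor_mz,
                 charge = s$charge, peaks = s$peaks[perm, ])
  expect_identical(denovo(s)$table$sequence, denovo(s2)$table$sequence)
})

test_that("removing peaks never increases a candidate's coverage", {
  p <- parse_peptide("KVAGFH")
  s <- simulate_ms2(p, clean_params())
  base_cov <- score_candidate(p, s)$coverage
  set.seed(33)
  for (k in 1:8) {
    keep <- sort(sample(nrow(s$peaks), sample(nrow(s$peaks), 1)))
    s2 <- spectrum(precursor_mz = s$precursor_mz, charge = s$charge,
                   peaks = s$peaks[keep, ])
    expect_lte(score_candidate(p, s2)$coverage, base_cov)
  }
})

test_that("every returned candidate is precursor-consistent", {
  for (txt in c("KVIKMV", "Bz-ARFG", "ARF-NH2")) {
    s <- simulate_ms2(txt, clean_params())
    r <- denovo(s)
    M <- (s$precursor_mz - 1.007276) * s$charge
    for (cand in r$candidates) {
      off <- cand$unexplained_terminal_mass
      if (is.na(off)) off <- 0
      expect_lt(abs(cand$neutral_mass + off - M), 0.021)
    }
  }
})

test_that("an unregistered terminal mass is reported as an open offset", {
  p <- parse_peptide("GVAFK")
  delta <- 100.0
  theo <- fragment_table(p, charges = 1L)
  theo <- theo[!(theo$series == "b" & theo$index == 1), ]
  theo$mz[theo$series == "b"] <- theo$mz[theo$series == "b"] + delta
  s <- spectrum(precursor_mz = precursor_mz(p, 1) + delta, charge = 1L,
                peaks = data.frame(mz = theo$mz, intensity = 1000))
  r <- denovo(s)
  expect_gt(length(r$candidates), 0)
  offs <- vapply(r$candidates, `[[`, numeric(1), "unexplained_terminal_mass")
  seqs <- r$table$sequence
  hit <- which(seqs == "GVAFK")
  expect_true(length(hit) > 0)
  expect_equal(offs[hit[1]], delta, tolerance = 0.02)
})
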