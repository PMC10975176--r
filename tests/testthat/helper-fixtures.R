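# Independently sourced monoisotopic residue (chain) masses, transcribed
# from standard proteomics reference tables -- deliberately not derived from
# the package's own atomic-mass arithmetic.
REF_RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

REF_PROTON <- 1.007276
REF_WATER <- 18.010565
REF_NH3 <- 17.026549

clean_params <- function(seed = 1L, ...) {
  sim_params(mass_error_sd = 0, ion_detection_prob = 1, noise_peaks = 0,
             seed = seed, ...)
}

random_peptide_string <- function(len,
                                  alphabet = names(REF_RESIDUE_MASS)) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# An "empty" registry: no modifications enabled or known.
empty_registry <- function() mod_registry()[0, ]

# Independent generate-and-test oracle for candidate enumeration on a
# spectrum, free-acid hypothesis, no modifications. A sequence of length n
# is accepted when (i) its neutral mass matches the precursor-derived
# neutral mass within tol and (ii) a contiguous run of prefix cleavage
# sites s..e is supported by observed peaks (interpreted as b- or y-ions),
# where the first unsupported stretch may span residues 1-2 (mirroring the
# two-residue first step) and the last may span the final two residues
# (mirroring the two-residue completion): s <= 2 and e >= n - 2.
oracle_enumerate <- function(s, charge, tol = 0.02, max_len = 4) {
  M <- (s$precursor_mz - REF_PROTON) * charge
  peaks <- s$peaks$mz
  res <- REF_RESIDUE_MASS[setdiff(names(REF_RESIDUE_MASS), c("I", "L"))]
  res <- c(res, J = unname(REF_RESIDUE_MASS[["L"]]))
  supported <- function(prefix) {
    any(abs(peaks - (prefix + REF_PROTON)) <= tol) ||
      any(abs(peaks - (M - prefix + REF_PROTON)) <= tol)
  }
  accept <- function(codes) {
    n <- length(codes)
    masses <- res[codes]
    if (abs(sum(masses) + REF_WATER - M) > tol) return(FALSE)
    if (n <= 2) return(TRUE)
    sup <- vapply(cumsum(masses)[seq_len(n - 1)], supported, logical(1))
    for (st in 1:2) for (en in c(n - 2, n - 1)) {
      if (st > en) next
      if (all(sup[st:en])) return(TRUE)
    }
    FALSE
  }
  found <- character(0)
  codes <- names(res)
  for (n in seq_len(max_len)) {
    grid <- do.call(expand.grid,
                    c(rep(list(codes), n), stringsAsFactors = FALSE))
    mass <- rowSums(do.call(cbind, lapply(grid, function(col) res[col])))
    keep <- abs(mass + REF_WATER - M) <= tol
    if (!any(keep)) next
    for (r in which(keep)) {
      codes_r <- unlist(grid[r, ], use.names = FALSE)
      if (accept(codes_r))
        found <- c(found, paste(gsub("J", "I/L", codes_r), collapse = ""))
    }
  }
  sort(unique(found))
}

# Spectrum-graph enumeration restricted to the oracle's universe
# (free acid, no modifications, length <= max_len).
enumerate_sequences <- function(s, charge, tol = 0.02, max_len = 4) {
  cfg <- denovo_config(tol_da = tol, min_coverage = 0,
                       cterm_hypotheses = "acid", allow_offset = FALSE,
                       max_paths = 500000L)
  g <- build_spectrum_graph(s, tol, registry = empty_registry(),
                            charge = charge)
  cands <- enumerate_candidates(g, s, cfg, registry = empty_registry())
  cands <- Filter(function(x) length(x$peptide$residues) <= max_len, cands)
  sort(unique(vapply(cands, function(x) format_peptide(x$peptide), "")))
}
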