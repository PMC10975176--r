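#' Simulation parameters
#'
#' Controls for the synthetic spectrum generator. The defaults emulate a
#' well-behaved high-resolution acquisition: 5 ppm mass error, every
#' theoretical ion detected, no chemical noise. The intensity model is a
#' simple rank decay (y-ions above b-ions above a-ions, a pragmatic stand-in
#' for fragmentation propensities, which coverage-based scoring does not
#' depend on).
#'
#' @param mass_error_sd Gaussian m/z error, standard deviation in ppm.
#' @param ion_detection_prob Probability that each theoretical fragment ion
#'   is observed.
#' @param noise_peaks Number of uniform noise peaks added.
#' @param noise_intensity_max Noise intensity ceiling as a fraction of the
#'   base peak.
#' @param intensity_model `"rank-decay"` or `"uniform"`.
#' @param include_a_ions Also emit a-ions (b - CO).
#' @param include_neutral_losses Emit the registry's diagnostic precursor
#'   neutral-loss peaks for modified peptides.
#' @param include_precursor Emit the precursor ion peak itself.
#' @param seed Integer seed; identical parameters give identical spectra.
#' @return List of class `"sim_params"`.
#' @export
sim_params <- function(mass_error_sd = 5, ion_detection_prob = 1,
                       noise_peaks = 0, noise_intensity_max = 0.05,
                       intensity_model = c("rank-decay", "uniform"),
                       include_a_ions = FALSE, include_neutral_losses = TRUE,
                       include_precursor = FALSE, seed = 1L) {
  intensity_model <- match.arg(intensity_model)
  stopifnot(ion_detection_prob >= 0, ion_detection_prob <= 1,
            mass_error_sd >= 0, noise_peaks >= 0)
  structure(list(mass_error_sd = mass_error_sd,
                 ion_detection_prob = ion_detection_prob,
                 noise_peaks = as.integer(noise_peaks),
                 noise_intensity_max = noise_intensity_max,
                 intensity_model = intensity_model,
                 include_a_ions = include_a_ions,
                 include_neutral_losses = include_neutral_losses,
                 include_precursor = include_precursor,
                 seed = as.integer(seed)),
            class = "sim_params")
}

.series_intensity <- function(series, model) {
  if (model == "uniform") return(rep(1000, length(series)))
  rank <- c(y = 1, b = 2, a = 3, z = 2, c = 3, w = 3, loss = 3,
            precursor = 4, imm = 1)[series]
  1000 / rank
}

.apply_noise_and_error <- function(theo, params, mz_range) {
  keep <- stats::runif(nrow(theo)) <= params$ion_detection_prob
  theo <- theo[keep, , drop = FALSE]
  if (nrow(theo) && params$mass_error_sd > 0)
    theo$mz <- theo$mz * (1 + stats::rnorm(nrow(theo), 0,
                                           params$mass_error_sd * 1e-6))
  if (params$noise_peaks > 0) {
    noise <- data.frame(
      mz = stats::runif(params$noise_peaks, mz_range[1], mz_range[2]),
      intensity = stats::runif(params$noise_peaks, 0,
                               params$noise_intensity_max * 1000))
    theo <- rbind(theo[, c("mz", "intensity")], noise)
  } else theo <- theo[, c("mz", "intensity")]
  theo
}

#' Simulate a CID MS2 spectrum
#'
#' Emits the b/y fragment ladder of a peptide (singly charged; doubly
#' charged copies are added when the precursor is 2+), with Gaussian ppm
#' mass error, per-ion dropout, optional a-ions, and the registry's
#' diagnostic precursor neutral losses for modified peptides (e.g. the
#' CO2 and CO2+H2O losses of a carboxybenzoylated N-terminus). Following
#' standard low-energy CID chemistry, the b1 ion is emitted only when the
#' N-terminus is acylated; the `b_n` ion is emitted for amidated peptides.
#' Deterministic for a given `params$seed`.
#'
#' @param p A [peptide()] or parseable sequence string (length >= 2).
#' @param params A [sim_params()].
#' @param charge Precursor charge; default 1 for peptides of up to five
#'   residues, 2 above.
#' @param registry Modification registry.
#' @return A [spectrum()] (MS2, CID) titled with the peptide's text form.
#' @export
simulate_ms2 <- function(p, params = sim_params(), charge = NULL,
                         registry = mod_registry()) {
  p <- as_peptide(p, registry)
  n <- length(p$residues)
  if (n < 2) stop("simulate_ms2 needs a peptide of length >= 2")
  if (is.null(charge)) charge <- if (n >= 6) 2L else 1L
  set.seed(params$seed)
  prec <- precursor_mz(p, charge, registry)

  series <- c("b", "y"); if (params$include_a_ions) series <- c(series, "a")
  rows <- list()
  for (s in series) {
    idx <- seq_len(n - 1L)
    if (s %in% c("b", "a") && is.na(p$nterm)) idx <- setdiff(idx, 1L)
    if (s == "b" && identical(p$cterm, "amidation")) idx <- c(idx, n)
    zs <- if (charge >= 2) c(1L, 2L) else 1L
    for (i in idx) for (z in zs)
      rows[[length(rows) + 1L]] <- data.frame(
        series = s, mz = fragment_mz(p, ion(s, i, z), registry))
  }
  if (params$include_neutral_losses) {
    lossmods <- c(if (!is.na(p$nterm)) p$nterm,
                  if (!is.na(p$cterm)) p$cterm)
    for (mn in lossmods) {
      for (loss in .mod_row(mn, registry)$losses[[1]])
        rows[[length(rows) + 1L]] <- data.frame(
          series = "loss",
          mz = fragment_mz(p, ion("precursor", charge = charge,
                                  neutral_losses = loss), registry))
    }
  }
  if (params$include_precursor)
    rows[[length(rows) + 1L]] <- data.frame(series = "precursor", mz = prec)
  theo <- if (length(rows)) do.call(rbind, rows)
          else data.frame(series = character(0), mz = numeric(0))
  theo$intensity <- .series_intensity(theo$series, params$intensity_model)
  pk <- .apply_noise_and_error(theo, params, c(50, prec))
  spectrum(title = format_peptide(p, registry), precursor_mz = prec,
           charge = charge, ms_level = 2L, activation = "CID", peaks = pk)
}

#' Simulate an ETD MS3 spectrum probing one Ile/Leu site
#'
#' Produces the z-radical ion ladder of the peptide and, for the probed
#' site, the corresponding w-ion displaced by the partial side-chain loss:
#' 29.03913 Da (ethyl) when the true residue is Ile, 43.05478 Da
#' (isopropyl) when Leu. The z-ion covering the site is `z_(n-site+1)`, so
#' the site must not be the first residue.
#'
#' @param p Peptide (the probed position may hold `I`, `L` or `J`).
#' @param site 1-based position of the probed residue.
#' @param truth `"I"` or `"L"`: which side-chain loss to emit.
#' @param params A [sim_params()].
#' @param registry Modification registry.
#' @return A [spectrum()] (MS3, ETD) whose `parent_selection` records the
#'   isolated 2+ precursor.
#' @export
simulate_etd_ms3 <- function(p, site, truth = c("I", "L"),
                             params = sim_params(),
                             registry = mod_registry()) {
  truth <- match.arg(truth)
  p <- as_peptide(p, registry)
  n <- length(p$residues)
  if (site < 1 || site > n) stop("'site' out of range")
  if (!p$residues[site] %in% c("I", "L", "J"))
    stop("residue at site ", site, " is ", p$residues[site],
         ", not an Ile/Leu position")
  if (site < 2)
    stop("the z-ion covering position 1 (z_n) is not formed; ",
         "an N-terminal I/L site cannot be probed by ETD MS3")
  set.seed(params$seed + 1L)
  prec <- precursor_mz(p, 2L, registry)
  jcov <- n - site + 1L
  rows <- list()
  for (j in seq_len(n - 1L))
    rows[[length(rows) + 1L]] <- data.frame(
      series = "z", mz = fragment_mz(p, ion("z", j), registry))
  loss <- if (truth == "I") .MASS_C2H5 else .MASS_C3H7
  rows[[length(rows) + 1L]] <- data.frame(
    series = "w",
    mz = fragment_mz(p, ion("w", jcov, side_chain_loss = loss), registry))
  theo <- do.call(rbind, rows)
  theo$intensity <- .series_intensity(theo$series, params$intensity_model)
  pk <- .apply_noise_and_error(theo, params, c(50, prec))
  spectrum(title = sprintf("%s|etd|site=%d", format_peptide(p, registry), site),
           precursor_mz = prec, charge = 2L, ms_level = 3L,
           activation = "ETD", parent_selection = prec, peaks = pk)
}

#' Simulate an HCD immonium MS3 spectrum
#'
#' Fragmentation of the isolated 86-Da Ile/Leu immonium ion: the base peak
#' sits at the immonium m/z (86.0964) and the 69-Da diagnostic (loss of
#' NH3, 69.0699) appears at relative abundance `ratio_69`. Ile typically
#' yields an abundant 69-Da ion (default 0.40) while Leu yields under 10%
#' (default 0.03).
#'
#' @param truth `"I"` or `"L"`; sets the default `ratio_69`.
#' @param ratio_69 Relative abundance of the 69-Da ion (0-1); overrides the
#'   truth-based default.
#' @param params A [sim_params()].
#' @return A [spectrum()] (MS3, HCD) with `parent_selection` at the
#'   immonium m/z.
#' @export
simulate_immonium_ms3 <- function(truth = c("I", "L"), ratio_69 = NULL,
                                  params = sim_params()) {
  truth <- match.arg(truth)
  if (is.null(ratio_69)) ratio_69 <- if (truth == "I") 0.40 else 0.03
  stopifnot(ratio_69 >= 0, ratio_69 <= 1)
  set.seed(params$seed + 2L)
  theo <- data.frame(series = "imm", mz = .IMM_IL, intensity = 1000)
  if (ratio_69 > 0)
    theo <- rbind(theo, data.frame(series = "imm", mz = .IMM_69,
                                   intensity = 1000 * ratio_69))
  if (params$mass_error_sd > 0)
    theo$mz <- theo$mz * (1 + stats::rnorm(nrow(theo), 0,
                                           params$mass_error_sd * 1e-6))
  if (params$noise_peaks > 0)
    theo <- rbind(theo, data.frame(
      series = "noise",
      mz = stats::runif(params$noise_peaks, 50, 90),
      intensity = stats::runif(params$noise_peaks, 0,
                               params$noise_intensity_max * 1000)))
  spectrum(title = sprintf("immonium|%s", truth), precursor_mz = .IMM_IL,
           charge = 1L, ms_level = 3L, activation = "HCD",
           parent_selection = .IMM_IL,
           peaks = theo[, c("mz", "intensity")])
}

#' Generate a ground-truthed benchmark set
#'
#' Draws `n` random peptides with lengths uniform over `length_range`,
#' residues uniform over the 20-residue alphabet, and modifications applied
#' independently at the given frequencies (the three N-terminal
#' modifications are mutually exclusive; a drawn pyroglutamate forces Glu at
#' position 1, a drawn oxidation forces a Met if none is present). For each
#' record an MS2 spectrum is simulated, plus, for every internal Ile/Leu
#' site, an ETD MS3 w-ion spectrum and an HCD immonium MS3 spectrum keyed to
#' that site's true residue. The returned peptide carries the ambiguity
#' symbol `J` at I/L positions; `il_truth` holds the concrete residues.
#'
#' @param n Number of records.
#' @param length_range Integer vector `c(min, max)` within \[2, 12\].
#' @param mod_frequencies Named numeric vector of per-peptide modification
#'   probabilities for the five registry classes.
#' @param params A [sim_params()]; `params$seed` drives the whole set.
#' @param registry Modification registry.
#' @return List of records: each has `peptide`, `sequence` (text form),
#'   `concrete_sequence`, `charge`, `spectra` (named list: `ms2`, and
#'   `etd.<site>` / `imm.<site>` per probed site), and `il_truth` (named
#'   character vector, position to `"I"`/`"L"`).
#' @export
generate_benchmark_set <- function(n, length_range = c(2L, 12L),
                                   mod_frequencies = c(
                                     benzoyl = 0.1, carboxybenzoyl = 0.1,
                                     pyroglutamate = 0.1, amidation = 0.1,
                                     oxidation = 0.1),
                                   params = sim_params(),
                                   registry = mod_registry()) {
  if (n < 1) stop("'n' must be >= 1")
  if (length_range[1] < 2 || length_range[2] > 12 ||
      length_range[1] > length_range[2])
    stop("'length_range' must satisfy 2 <= min <= max <= 12")
  aa20 <- setdiff(names(.RESIDUE_FORMULA), "J")
  nterm_mods <- intersect(names(mod_frequencies),
                          registry$name[registry$target == "N-term"])
  records <- vector("list", n)
  set.seed(params$seed)
  draws <- lapply(seq_len(n), function(i) {
    len <- sample(seq.int(length_range[1], length_range[2]), 1L)
    list(len = len,
         residues = sample(aa20, len, replace = TRUE),
         u_mods = stats::runif(length(mod_frequencies)),
         u_nterm_pick = stats::runif(1),
         u_pos = stats::runif(2))
  })
  for (i in seq_len(n)) {
    d <- draws[[i]]
    residues <- d$residues
    len <- d$len
    modded <- names(mod_frequencies)[d$u_mods <= mod_frequencies]
    nterm <- NA_character_
    picks <- intersect(modded, nterm_mods)
    if (length(picks))
      nterm <- picks[ceiling(d$u_nterm_pick * length(picks))]
    if (!is.na(nterm)) {
      req <- .mod_row(nterm, registry)$residue
      if (nzchar(req)) residues[1] <- req
    }
    cterm <- if ("amidation" %in% modded) "amidation" else NA_character_
    residue_mods <- list()
    if ("oxidation" %in% modded) {
      mpos <- which(residues == "M")
      if (!length(mpos)) {
        mpos <- 1L + ceiling(d$u_pos[1] * (len - 1L))  # keep position 1 free
        residues[mpos] <- "M"
      }
      oxp <- mpos[ceiling(d$u_pos[2] * length(mpos))]
      residue_mods[[as.character(oxp)]] <- "oxidation"
    }
    il_pos <- which(residues %in% c("I", "L"))
    il_truth <- stats::setNames(residues[il_pos], il_pos)
    masked <- residues
    masked[il_pos] <- "J"
    p_true <- peptide(residues, nterm, cterm, residue_mods, registry)
    p_masked <- peptide(masked, nterm, cterm, residue_mods, registry)
    charge <- if (len >= 6) 2L else 1L

    rec_seed <- (params$seed + 7919L * i) %% .Machine$integer.max
    sp <- list(ms2 = simulate_ms2(p_true, utils::modifyList(
      params, list(seed = rec_seed)), charge = charge, registry = registry))
    for (site in il_pos[il_pos >= 2]) {
      sp[[paste0("etd.", site)]] <- simulate_etd_ms3(
        p_masked, site, truth = il_truth[[as.character(site)]],
        params = utils::modifyList(params, list(seed = rec_seed + site)),
        registry = registry)
    }
    for (site in il_pos) {
      sp[[paste0("imm.", site)]] <- simulate_immonium_ms3(
        truth = il_truth[[as.character(site)]],
        params = utils::modifyList(params, list(seed = rec_seed + 100L + site)))
    }
    records[[i]] <- list(peptide = p_masked,
                         sequence = format_peptide(p_masked, registry),
                         concrete_sequence = format_peptide(p_true, registry),
                         charge = charge, spectra = sp, il_truth = il_truth)
  }
  records
}
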