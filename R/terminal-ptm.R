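#' Terminal/residue PTM evidence
#'
#' Internal constructor for the evidence records returned by the detectors.
#' A verdict is `"confirmed"` with two or more supporting ions (the
#' precursor match counts as one), `"suggested"` with exactly one, and
#' `"absent"` otherwise.
#' @noRd
.ptm_evidence <- function(modification, terminus, supporting, offset = NA_real_) {
  n <- if (is.null(supporting)) 0L else nrow(supporting)
  verdict <- if (n >= 2L) "confirmed" else if (n == 1L) "suggested" else "absent"
  structure(list(modification = modification, terminus = terminus,
                 supporting_ions = supporting, offset = offset,
                 verdict = verdict),
            class = "ptm_evidence")
}

#' @export
print.ptm_evidence <- function(x, ...) {
  cat(sprintf("<ptm_evidence> %s (%s-terminus): %s (%d supporting ion%s)\n",
              x$modification, x$terminus, x$verdict,
              NROW(x$supporting_ions),
              if (NROW(x$supporting_ions) == 1) "" else "s"))
  invisible(x)
}

.cand_peptide <- function(c) if (inherits(c, "seq_candidate")) c$peptide else
  as_peptide(c)

.prec_match <- function(s, neutral, charge, ppm = 50) {
  mz <- (neutral + charge * .PROTON) / charge
  err <- s$precursor_mz - mz
  if (abs(err) <= ppm * 1e-6 * mz)
    data.frame(label = "precursor", theoretical_mz = mz,
               observed_mz = s$precursor_mz, observed_intensity = NA_real_,
               error = err, relative_intensity = NA_real_, ambiguous = FALSE)
  else NULL
}

#' Detect C-terminal amidation
#'
#' Tests the amidated reading of a candidate's residue sequence against the
#' spectrum: the precursor must match the amidated neutral mass (within
#' `precursor_ppm`), and supporting fragments are the `b_n` ion sitting
#' 17.02655 Da below `[M + H]+` and y-ions carrying the -0.98402 Da amide
#' shift. Verdicts: precursor plus at least one fragment ion is
#' `"confirmed"`; a matching precursor alone is `"suggested"`; otherwise
#' `"absent"`.
#'
#' @param c A `seq_candidate` or [peptide()] (its C-terminal state is
#'   ignored; both readings are formed from its residues).
#' @param s The MS2 [spectrum()].
#' @param tol_da Fragment tolerance in Da.
#' @param precursor_ppm Precursor tolerance in ppm.
#' @param registry Modification registry.
#' @return A `ptm_evidence` record for `"amidation"`.
#' @export
detect_cterm_amidation <- function(c, s, tol_da = 0.02, precursor_ppm = 50,
                                   registry = mod_registry()) {
  p <- .cand_peptide(c)
  pam <- peptide(p$residues, nterm = p$nterm, cterm = "amidation",
                 residue_mods = p$residue_mods, registry = registry)
  n <- length(pam$residues)
  neutral <- peptide_neutral_mass(pam, registry)
  z <- max(s$charge, 1L)
  sup <- .prec_match(s, neutral, z, precursor_ppm)
  if (is.null(sup))
    return(.ptm_evidence("amidation", "C", NULL))
  theo <- data.frame(label = paste0("y", seq_len(n - 1L)),
                     mz = vapply(seq_len(n - 1L), function(j)
                       fragment_mz(pam, ion("y", j), registry), numeric(1)))
  theo <- rbind(theo, data.frame(
    label = paste0("b", n),
    mz = fragment_mz(pam, ion("b", n), registry)))
  m <- match_peaks(s, theo, tol_da)
  # only amide-specific evidence counts: drop y-ions that also fit the
  # free-acid reading (they differ by 0.984 Da, so any match within tol
  # is specific as long as tol < 0.49; kept explicit for clarity)
  sup <- rbind(sup, m[, names(sup)])
  .ptm_evidence("amidation", "C", sup)
}

#' Detect N-terminal modifications
#'
#' For every enabled N-terminal modification in the registry, tests the
#' evidence chain on the spectrum: the acylated b1 ion (first residue +
#' modification delta + proton), its a1 companion (b1 - CO), the
#' two-residue N-terminal block as a b2 ion, and the modification's
#' diagnostic precursor neutral losses (for carboxybenzoyl, the CO2 and
#' CO2+H2O losses). A modification that declares diagnostic losses is only
#' `"confirmed"` when all of them are observed. Pyroglutamate is tested
#' with its required residue (Glu) at position 1.
#'
#' @inheritParams detect_cterm_amidation
#' @return List of `ptm_evidence` records, one per candidate modification.
#' @export
detect_nterm_mod <- function(c, s, tol_da = 0.02, registry = mod_registry()) {
  p <- .cand_peptide(c)
  n <- length(p$residues)
  nmods <- registry[registry$target == "N-term" & registry$enabled, ,
                    drop = FALSE]
  out <- list()
  for (k in seq_len(nrow(nmods))) {
    mod <- nmods[k, ]
    r1 <- if (nzchar(mod$residue)) mod$residue else p$residues[1]
    b1 <- .residue_masses[[r1]] + mod$delta + .PROTON
    theo <- data.frame(label = c("b1", "a1"), mz = c(b1, b1 - .MASS_CO))
    if (n >= 2) {
      r2 <- if (nzchar(mod$residue)) p$residues[if (p$residues[1] == r1) 2 else 1]
            else p$residues[2]
      theo <- rbind(theo, data.frame(
        label = "b2", mz = b1 + .residue_masses[[r2]]))
    }
    losses <- mod$losses[[1]]
    if (length(losses)) {
      z <- max(s$charge, 1L)
      theo <- rbind(theo, data.frame(
        label = paste0("loss", seq_along(losses)),
        mz = s$precursor_mz - losses / z))
    }
    m <- match_peaks(s, theo, tol_da)
    if (length(losses) &&
        !all(paste0("loss", seq_along(losses)) %in% m$label))
      m <- m[0, , drop = FALSE]  # diagnostic losses are mandatory
    out[[mod$name]] <- .ptm_evidence(mod$name, "N", if (nrow(m)) m else NULL)
  }
  out
}

#' Run all registry PTM detectors on a candidate spectrum
#'
#' Convenience wrapper combining [detect_nterm_mod()],
#' [detect_cterm_amidation()] and a Met-oxidation check (fragment ions
#' covering an oxidized Met shift by +15.99491 Da; precursor consistency
#' counts as one supporting ion, as for the terminal detectors).
#'
#' @inheritParams detect_cterm_amidation
#' @return Named list of `ptm_evidence` records covering every enabled
#'   registry modification.
#' @export
detect_ptms <- function(c, s, tol_da = 0.02, precursor_ppm = 50,
                        registry = mod_registry()) {
  out <- detect_nterm_mod(c, s, tol_da, registry)
  out$amidation <- detect_cterm_amidation(c, s, tol_da, precursor_ppm,
                                          registry)
  if ("oxidation" %in% registry$name[registry$enabled])
    out$oxidation <- .detect_oxidation(c, s, tol_da, precursor_ppm, registry)
  out
}

.detect_oxidation <- function(c, s, tol_da, precursor_ppm, registry) {
  p <- .cand_peptide(c)
  n <- length(p$residues)
  mpos <- which(p$residues == "M")
  for (pos in mpos) {
    mods <- p$residue_mods
    mods[[as.character(pos)]] <- "oxidation"
    pox <- peptide(p$residues, p$nterm, p$cterm, mods, registry)
    z <- max(s$charge, 1L)
    sup <- .prec_match(s, peptide_neutral_mass(pox, registry), z,
                       precursor_ppm)
    if (is.null(sup)) next
    theo <- list()
    bidx <- if (pos <= n - 1L) seq.int(pos, n - 1L) else integer(0)
    yidx <- if (n - pos + 1L <= n - 1L) seq.int(n - pos + 1L, n - 1L)
            else integer(0)
    for (i in bidx)
      theo[[length(theo) + 1L]] <- data.frame(
        label = paste0("b", i), mz = fragment_mz(pox, ion("b", i), registry))
    for (j in yidx)
      theo[[length(theo) + 1L]] <- data.frame(
        label = paste0("y", j), mz = fragment_mz(pox, ion("y", j), registry))
    m <- if (length(theo))
      match_peaks(s, do.call(rbind, theo), tol_da) else NULL
    sup <- rbind(sup, if (!is.null(m) && nrow(m)) m[, names(sup)])
    return(.ptm_evidence("oxidation", "residue", sup))
  }
  .ptm_evidence("oxidation", "residue", NULL)
}

#' Decompose an unexplained terminal mass into elemental formulas
#'
#' Exhaustive CHNOS search within the given bounds for compositions whose
#' monoisotopic mass (neutral, or singly-charged cation when `as_cation`)
#' lies within `tol_da` of the offset; compositions with a negative
#' ring-plus-double-bond equivalent are excluded. This is the reasoning
#' that assigns the 176.0705 b1 cation the formula C10H10NO2.
#'
#' @param offset Mass offset in Da, e.g. a candidate's
#'   `unexplained_terminal_mass`, or `c` itself if it is a candidate with
#'   one set.
#' @param tol_da Tolerance in Da.
#' @param as_cation Interpret the offset as a singly-protonated cation m/z
#'   rather than a neutral delta.
#' @param bounds Named upper bounds for element counts.
#' @return `data.frame` with columns `formula`, `mass`, `error`, `rdbe`,
#'   sorted by absolute error.
#' @export
open_terminal_offset <- function(offset, tol_da = 0.005, as_cation = FALSE,
                                 bounds = c(C = 15, H = 25, N = 3, O = 6,
                                            S = 1)) {
  if (inherits(offset, "seq_candidate")) {
    offset <- offset$unexplained_terminal_mass
    if (is.na(offset)) stop("candidate has no unexplained terminal mass")
  }
  grid <- expand.grid(C = 0:bounds[["C"]], H = 0:bounds[["H"]],
                      N = 0:bounds[["N"]], O = 0:bounds[["O"]],
                      S = 0:bounds[["S"]])
  mass <- grid$C * .ATOMIC[["C"]] + grid$H * .ATOMIC[["H"]] +
    grid$N * .ATOMIC[["N"]] + grid$O * .ATOMIC[["O"]] + grid$S * .ATOMIC[["S"]]
  if (as_cation) mass <- mass - .ELECTRON
  rdbe <- grid$C - grid$H / 2 + grid$N / 2 + 1
  err <- mass - offset
  keep <- abs(err) <= tol_da & rdbe >= 0 & rowSums(grid) > 0
  if (!any(keep))
    return(data.frame(formula = character(0), mass = numeric(0),
                      error = numeric(0), rdbe = numeric(0)))
  grid <- grid[keep, , drop = FALSE]
  fmt <- function(el, n) ifelse(n == 0, "",
                                ifelse(n == 1, el, paste0(el, n)))
  out <- data.frame(
    formula = paste0(fmt("C", grid$C), fmt("H", grid$H), fmt("N", grid$N),
                     fmt("O", grid$O), fmt("S", grid$S)),
    mass = mass[keep], error = err[keep], rdbe = rdbe[keep])
  out <- out[order(abs(out$error)), ]
  rownames(out) <- NULL
  out
}
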