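.il_call <- function(position, call, method = NA_character_,
                     diagnostic_delta = NA_real_,
                     diagnostic_ratio = NA_real_, reason = NA_character_) {
  structure(list(position = as.integer(position), call = call,
                 method = method, diagnostic_delta = diagnostic_delta,
                 diagnostic_ratio = diagnostic_ratio, reason = reason),
            class = "il_call")
}

#' @export
print.il_call <- function(x, ...) {
  cat(sprintf("<il_call> position %d: %s%s%s\n", x$position, x$call,
              if (!is.na(x$method)) paste0(" (", x$method, ")") else "",
              if (!is.na(x$reason)) paste0(" - ", x$reason) else ""))
  invisible(x)
}

#' Call Ile vs Leu from an ETD MS3 w-ion spectrum
#'
#' Locates the z-radical ion covering the probed site (`z_(n-site+1)`) and
#' searches for its w-ion displaced by the partial side-chain loss:
#' -29.03913 Da (ethyl) evidences Ile, -43.05478 Da (isopropyl) evidences
#' Leu. Because w-ions of very short peptides are prone to
#' misidentification (hydrogen abstraction), the covering z-ion itself must
#' be observed before a w-ion is accepted. Exactly one matching loss gives
#' a call; both or neither leaves the site ambiguous.
#'
#' @param ms3 An ETD/EThCD MS3 [spectrum()].
#' @param c A `seq_candidate` or [peptide()] whose `site` is I/L-ambiguous.
#' @param site 1-based position of the probed residue.
#' @param tol_da Matching tolerance in Da.
#' @param registry Modification registry.
#' @return An `il_call` with method `"wd_ion"` (or an ambiguous call with a
#'   reason).
#' @export
call_il_from_wd <- function(ms3, c, site, tol_da = 0.02,
                            registry = mod_registry()) {
  if (!ms3$activation %in% c("ETD", "EThCD"))
    stop("'ms3' must be an ETD or EThCD spectrum")
  p <- .cand_peptide(c)
  n <- length(p$residues)
  if (site < 1 || site > n || !p$residues[site] %in% c("I", "L", "J"))
    stop("'site' is not an I/L position of the candidate")
  j <- n - site + 1L
  if (j > n - 1L)
    return(.il_call(site, "ambiguous", reason = "no supporting backbone ion"))
  zmz <- fragment_mz(p, ion("z", j), registry)
  zm <- match_peaks(ms3, data.frame(label = "z", mz = zmz), tol_da)
  if (!nrow(zm))
    return(.il_call(site, "ambiguous", reason = "no supporting backbone ion"))
  wI <- match_peaks(ms3, data.frame(label = "wI", mz = zmz - .MASS_C2H5),
                    tol_da)
  wL <- match_peaks(ms3, data.frame(label = "wL", mz = zmz - .MASS_C3H7),
                    tol_da)
  hitI <- nrow(wI) > 0; hitL <- nrow(wL) > 0
  if (hitI && !hitL)
    return(.il_call(site, "I", "wd_ion", diagnostic_delta = .MASS_C2H5))
  if (hitL && !hitI)
    return(.il_call(site, "L", "wd_ion", diagnostic_delta = .MASS_C3H7))
  if (hitI && hitL)
    return(.il_call(site, "ambiguous", reason = "both side-chain losses present"))
  .il_call(site, "ambiguous", reason = "no w-ion within tolerance")
}

#' Call Ile vs Leu from an HCD immonium MS3 spectrum
#'
#' Applies the 86/69 rule: fragmentation of the isolated 86-Da I/L immonium
#' ion yields an abundant 69-Da ion (loss of NH3) for Ile, but minimal
#' (below 10%) or none for Leu. The comparison with `threshold` is
#' inclusive: a relative abundance of exactly the threshold calls Ile.
#'
#' @param ms3 An MS3 [spectrum()] whose `parent_selection` is the 86-Da
#'   immonium ion.
#' @param threshold Relative-abundance threshold (default 0.10).
#' @param tol_da Matching tolerance in Da.
#' @return An `il_call` with method `"immonium"` and the observed
#'   `diagnostic_ratio`.
#' @export
call_il_from_immonium <- function(ms3, threshold = 0.10, tol_da = 0.02) {
  if (is.na(ms3$parent_selection) ||
      abs(ms3$parent_selection - .IMM_IL) > 0.05)
    stop("'ms3' parent selection is not the 86-Da I/L immonium ion")
  pk <- ms3$peaks
  if (!nrow(pk))
    return(.il_call(NA_integer_, "ambiguous", reason = "empty spectrum"))
  base <- max(pk$intensity)
  sel <- abs(pk$mz - .IMM_69) <= tol_da
  ratio <- if (any(sel)) max(pk$intensity[sel]) / base else 0
  call <- if (ratio >= threshold) "I" else "L"
  .il_call(NA_integer_, call, "immonium", diagnostic_ratio = ratio)
}

#' Reconcile candidates with external search-engine identifications
#'
#' Where an external identification (e.g. an exported Mascot peptide table)
#' matches a candidate's sequence up to I/L ambiguity, the candidate's
#' ambiguous positions adopt the external residues (method `"external"`).
#' Mismatching or unmatched rows are left alone and reported in the
#' `log` attribute.
#'
#' @param candidates List of `seq_candidate` objects (or peptides/strings).
#' @param external `data.frame` with columns `spectrum_title` and
#'   `sequence`, or a path to a tab-separated file with that header.
#' @param titles Optional character vector pairing each candidate with a
#'   spectrum title; defaults to matching on sequence alone.
#' @param registry Modification registry.
#' @return The updated candidate list, with a `log` attribute (character
#'   vector describing skipped/mismatched rows) and, per updated candidate,
#'   an `il_methods` attribute on the peptide marking external positions.
#' @export
reconcile_external_ids <- function(candidates, external, titles = NULL,
                                   registry = mod_registry()) {
  if (is.character(external) && length(external) == 1L)
    external <- utils::read.delim(external, stringsAsFactors = FALSE)
  if (!all(c("spectrum_title", "sequence") %in% names(external)))
    stop("external table needs columns 'spectrum_title' and 'sequence'")
  log <- character(0)
  for (r in seq_len(nrow(external))) {
    ext_seq <- external$sequence[r]
    ext_p <- tryCatch(parse_peptide(ext_seq, registry), error = function(e) NULL)
    if (is.null(ext_p)) {
      log <- c(log, sprintf("row %d: unparseable sequence '%s'", r, ext_seq))
      next
    }
    matched <- FALSE
    for (i in seq_along(candidates)) {
      cand <- candidates[[i]]
      p <- .cand_peptide(cand)
      if (!is.null(titles) &&
          !identical(titles[i], external$spectrum_title[r])) next
      if (length(p$residues) != length(ext_p$residues)) next
      amb <- p$residues == "J"
      same <- p$residues == ext_p$residues |
        (amb & ext_p$residues %in% c("I", "L"))
      if (!all(same) || !identical(p$nterm, ext_p$nterm) ||
          !identical(p$cterm, ext_p$cterm)) next
      p$residues[amb] <- ext_p$residues[amb]
      attr(p, "il_methods") <- stats::setNames(
        rep("external", sum(amb)), which(amb))
      if (inherits(cand, "seq_candidate")) cand$peptide <- p else cand <- p
      candidates[[i]] <- cand
      matched <- TRUE
    }
    if (!matched)
      log <- c(log, sprintf(
        "row %d: '%s' (%s) matches no candidate; left unchanged",
        r, ext_seq, external$spectrum_title[r]))
  }
  attr(candidates, "log") <- log
  candidates
}

#' Combine I/L calls with deterministic precedence
#'
#' Precedence is `wd_ion > immonium > external`; agreeing methods keep the
#' highest-precedence one, disagreeing methods downgrade the site to
#' ambiguous (with a reason).
#'
#' @param calls List of `il_call` objects for one site.
#' @return A single consolidated `il_call`.
#' @export
resolve_il_calls <- function(calls) {
  calls <- Filter(function(x) x$call %in% c("I", "L"), calls)
  if (!length(calls))
    return(.il_call(NA_integer_, "ambiguous", reason = "no informative call"))
  prec <- c(wd_ion = 1, immonium = 2, external = 3)
  ord <- order(prec[vapply(calls, `[[`, "", "method")])
  calls <- calls[ord]
  verdicts <- unique(vapply(calls, `[[`, "", "call"))
  if (length(verdicts) > 1)
    return(.il_call(calls[[1]]$position, "ambiguous",
                    reason = "methods disagree"))
  calls[[1]]
}
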