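#' Construct a centroided spectrum
#'
#' @param title Spectrum title.
#' @param precursor_mz Precursor m/z.
#' @param charge Precursor charge; 0 means unknown (downstream stages then
#'   try 1+ and 2+ hypotheses).
#' @param ms_level 2 or 3.
#' @param activation One of `"CID"`, `"HCD"`, `"ETD"`, `"EThCD"`.
#' @param parent_selection For MS3 spectra, the fragment m/z isolated from
#'   the MS2 scan; required when `ms_level == 3`.
#' @param peaks Two-column `data.frame` (`mz`, `intensity`) or matrix; peaks
#'   are sorted by m/z, intensities must be non-negative.
#' @return Object of class `"spectrum"`.
#' @export
spectrum <- function(title = "", precursor_mz = NA_real_, charge = 0L,
                     ms_level = 2L, activation = "CID",
                     parent_selection = NA_real_,
                     peaks = data.frame(mz = numeric(0),
                                        intensity = numeric(0))) {
  activation <- match.arg(activation, c("CID", "HCD", "ETD", "EThCD"))
  if (!ms_level %in% c(2L, 3L)) stop("'ms_level' must be 2 or 3")
  if (ms_level == 3L && is.na(parent_selection))
    stop("MS3 spectra require 'parent_selection'")
  peaks <- as.data.frame(peaks)
  if (!nrow(peaks)) peaks <- data.frame(mz = numeric(0), intensity = numeric(0))
  names(peaks)[1:2] <- c("mz", "intensity")
  if (any(peaks$intensity < 0)) stop("intensities must be non-negative")
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(title = title, precursor_mz = precursor_mz,
                 charge = as.integer(charge), ms_level = as.integer(ms_level),
                 activation = activation, parent_selection = parent_selection,
                 peaks = peaks),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s\n  MS%d %s  precursor %.4f (%s)  %d peaks\n",
              x$title, x$ms_level, x$activation, x$precursor_mz,
              if (x$charge > 0) paste0(x$charge, "+") else "charge unknown",
              nrow(x$peaks)))
  if (x$ms_level == 3L)
    cat(sprintf("  parent selection %.4f\n", x$parent_selection))
  invisible(x)
}

#' Stick plot of a spectrum
#'
#' @param x A [spectrum()].
#' @param matches Optional [match_peaks()] table; matched peaks are drawn in
#'   red and labelled with their ion names.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.spectrum <- function(x, matches = NULL, ...) {
  pk <- x$peaks
  if (!nrow(pk)) {
    graphics::plot(0, 0, type = "n", xlab = "m/z", ylab = "intensity",
                   main = x$title, ...)
    return(invisible(x))
  }
  graphics::plot(pk$mz, pk$intensity, type = "h", xlab = "m/z",
                 ylab = "intensity", main = x$title, ...)
  if (!is.null(matches) && nrow(matches)) {
    graphics::segments(matches$observed_mz, 0, matches$observed_mz,
                       matches$observed_intensity, col = "red")
    graphics::text(matches$observed_mz, matches$observed_intensity,
                   labels = matches$label, pos = 3, col = "red", cex = 0.7)
  }
  invisible(x)
}

#' Read a Mascot Generic Format file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks with `TITLE`, `PEPMASS` and
#' `CHARGE` headers. The MSn dialect written by [write_mgf()] adds
#' `MSLEVEL=`, `ACTIVATION=` and `PARENT=` key lines (plain MGF has no MSn
#' provenance); other readers ignore them. A block without `CHARGE` loads
#' with charge 0 ("unknown").
#'
#' @param source File path or connection.
#' @return List of [spectrum()] objects.
#' @export
read_mgf <- function(source) {
  lines <- readLines(source)
  spectra <- list()
  inblock <- FALSE
  hdr <- NULL; mzs <- NULL; ints <- NULL; start <- 0L
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (line == "BEGIN IONS") {
      if (inblock) stop("line ", ln, ": BEGIN IONS inside an open block")
      inblock <- TRUE; start <- ln
      hdr <- list(); mzs <- numeric(0); ints <- numeric(0)
      next
    }
    if (line == "END IONS") {
      if (!inblock) stop("line ", ln, ": END IONS without BEGIN IONS")
      inblock <- FALSE
      pep <- if (!is.null(hdr$PEPMASS))
        as.numeric(strsplit(hdr$PEPMASS, "[ \t]+")[[1]][1]) else NA_real_
      ch <- 0L
      if (!is.null(hdr$CHARGE)) {
        chtok <- sub("\\+$", "", hdr$CHARGE)
        ch <- suppressWarnings(as.integer(chtok))
        if (is.na(ch)) stop("line ", start, ": unparseable CHARGE '",
                            hdr$CHARGE, "'")
      }
      lvl <- if (!is.null(hdr$MSLEVEL)) as.integer(hdr$MSLEVEL) else 2L
      act <- if (!is.null(hdr$ACTIVATION)) hdr$ACTIVATION else "CID"
      par <- if (!is.null(hdr$PARENT)) as.numeric(hdr$PARENT) else NA_real_
      spectra[[length(spectra) + 1L]] <- spectrum(
        title = if (!is.null(hdr$TITLE)) hdr$TITLE else "",
        precursor_mz = pep, charge = ch, ms_level = lvl, activation = act,
        parent_selection = par,
        peaks = data.frame(mz = mzs, intensity = ints))
      next
    }
    if (!inblock) next
    if (grepl("^[A-Z][A-Z0-9]*=", line)) {
      key <- sub("=.*$", "", line)
      hdr[[key]] <- sub("^[A-Z][A-Z0-9]*=", "", line)
      next
    }
    vals <- suppressWarnings(as.numeric(strsplit(line, "[ \t]+")[[1]]))
    if (length(vals) < 2L || anyNA(vals[1:2]))
      stop("line ", ln, ": expected 'mz intensity', got '", line, "'")
    mzs <- c(mzs, vals[1]); ints <- c(ints, vals[2])
  }
  if (inblock)
    stop("block starting at line ", start, " is missing END IONS")
  spectra
}

#' Write spectra in Mascot Generic Format
#'
#' m/z values are written to 5 decimals and intensities to 2;
#' [read_mgf()] of the output reproduces the input at that precision.
#'
#' @param spectra A [spectrum()] or list of them.
#' @param sink File path or connection.
#' @return Invisibly, the path/connection written to.
#' @export
write_mgf <- function(spectra, sink) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  out <- character(0)
  for (s in spectra) {
    blk <- c("BEGIN IONS",
             paste0("TITLE=", s$title),
             paste0("PEPMASS=", sprintf("%.5f", s$precursor_mz)))
    if (s$charge > 0) blk <- c(blk, paste0("CHARGE=", s$charge, "+"))
    blk <- c(blk, paste0("MSLEVEL=", s$ms_level),
             paste0("ACTIVATION=", s$activation))
    if (!is.na(s$parent_selection))
      blk <- c(blk, sprintf("PARENT=%.5f", s$parent_selection))
    if (nrow(s$peaks))
      blk <- c(blk, sprintf("%.5f %.2f", s$peaks$mz, s$peaks$intensity))
    out <- c(out, blk, "END IONS", "")
  }
  writeLines(out, sink)
  invisible(sink)
}

#' Match observed peaks to theoretical ions
#'
#' Each theoretical ion is matched to the nearest observed peak within
#' `tol_da`; ties between equidistant peaks resolve to the lower m/z. One
#' observed peak may satisfy several theoretical ions, in which case the
#' `ambiguous` flag is set on all of them. Relative intensities are
#' normalized to the base peak.
#'
#' @param s A [spectrum()].
#' @param theoretical `data.frame` with columns `mz` and (optionally)
#'   `label`; extra columns are carried through.
#' @param tol_da Matching tolerance in Da (> 0).
#' @return `data.frame` with columns `label`, `theoretical_mz`,
#'   `observed_mz`, `observed_intensity`, `error`, `relative_intensity`,
#'   `ambiguous` — one row per matched theoretical ion.
#' @export
match_peaks <- function(s, theoretical, tol_da = 0.02) {
  if (!is.numeric(tol_da) || tol_da <= 0) stop("'tol_da' must be > 0")
  theoretical <- as.data.frame(theoretical)
  if (is.null(theoretical$label))
    theoretical$label <- sprintf("ion%d", seq_len(nrow(theoretical)))
  pk <- s$peaks
  empty <- data.frame(label = character(0), theoretical_mz = numeric(0),
                      observed_mz = numeric(0), observed_intensity = numeric(0),
                      error = numeric(0), relative_intensity = numeric(0),
                      ambiguous = logical(0))
  if (!nrow(pk) || !nrow(theoretical)) return(empty)
  base <- max(pk$intensity)
  if (base <= 0) base <- 1
  rows <- vector("list", nrow(theoretical))
  hit_peak <- integer(0)
  for (i in seq_len(nrow(theoretical))) {
    d <- abs(pk$mz - theoretical$mz[i])
    j <- which(d <= tol_da)
    if (!length(j)) next
    j <- j[order(d[j], pk$mz[j])][1]
    hit_peak <- c(hit_peak, j)
    rows[[i]] <- data.frame(
      label = theoretical$label[i], theoretical_mz = theoretical$mz[i],
      observed_mz = pk$mz[j], observed_intensity = pk$intensity[j],
      error = pk$mz[j] - theoretical$mz[i],
      relative_intensity = pk$intensity[j] / base,
      ambiguous = FALSE, peak = j)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  dup <- out$peak %in% out$peak[duplicated(out$peak)]
  out$ambiguous <- dup
  out$peak <- NULL
  rownames(out) <- NULL
  out
}
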