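#' Load a modification registry
#'
#' The registry is a plain-text tab-separated table with one row per named
#' modification: its terminus or residue target, signed elemental formula
#' delta, diagnostic precursor neutral losses (semicolon-separated formulas),
#' the prefix/suffix token used in peptide strings, and an enabled flag.
#' The packaged default registers the five modification classes observed in
#' scorpion-venom short peptides: N-terminal benzoyl (+C7H4O),
#' carboxybenzoyl (+C8H4O3), pyroglutamate (Glu - H2O; a Gln-derived variant
#' ships disabled), C-terminal amidation (-0.98402 Da) and Met oxidation
#' (+15.99491 Da).
#'
#' @param path Path to a registry file; defaults to the packaged registry.
#' @return `data.frame` of class `"mod_registry"` with computed `delta`
#'   (monoisotopic Da) and parsed `losses` (list of numeric loss masses).
#' @export
load_modifications <- function(path = system.file("extdata",
                                                  "modifications.tsv",
                                                  package = "venomdenovo")) {
  reg <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = NULL, colClasses = "character")
  needed <- c("name", "target", "residue", "formula", "diagnostic_losses",
              "prefix", "enabled")
  if (!all(needed %in% names(reg)))
    stop("registry is missing columns: ",
         paste(setdiff(needed, names(reg)), collapse = ", "))
  if (anyDuplicated(reg$name))
    stop("registry names must be unique")
  if (!all(reg$target %in% c("N-term", "C-term", "residue")))
    stop("registry target must be one of N-term, C-term, residue")
  reg$enabled <- as.logical(reg$enabled)
  reg$delta <- vapply(reg$formula, function(f) formula_mass(f), numeric(1))
  reg$losses <- lapply(reg$diagnostic_losses, function(s) {
    if (!nzchar(s)) return(numeric(0))
    vapply(strsplit(s, ";", fixed = TRUE)[[1]], formula_mass, numeric(1))
  })
  class(reg) <- c("mod_registry", "data.frame")
  reg
}

.registry_cache <- new.env(parent = emptyenv())

#' Default modification registry
#'
#' Cached accessor for the packaged registry (see [load_modifications()]).
#' @return A `"mod_registry"` data frame.
#' @export
mod_registry <- function() {
  if (is.null(.registry_cache$reg))
    .registry_cache$reg <- load_modifications()
  .registry_cache$reg
}

.mod_row <- function(name, registry) {
  i <- match(name, registry$name)
  if (is.na(i)) stop("modification '", name, "' is not in the registry")
  registry[i, ]
}

.mod_delta <- function(name, registry) .mod_row(name, registry)$delta

#' Construct a peptide
#'
#' A peptide is an ordered vector of one-letter residue codes (the 20
#' standard amino acids plus `J`, the Ile/Leu-ambiguous residue) with an
#' optional N-terminal modification, an optional C-terminal amidation, and
#' per-residue modifications (Met oxidation).
#'
#' @param residues Character vector of residue codes, or a single string.
#' @param nterm Registry name of the N-terminal modification, or `NA`.
#' @param cterm `"amidation"` for an amidated C-terminus, or `NA` (free
#'   acid).
#' @param residue_mods Named list/character vector, names are 1-based
#'   positions, values registry names (e.g. `list("5" = "oxidation")`).
#' @param registry Modification registry used for validation.
#' @return Object of class `"peptide"`.
#' @seealso [parse_peptide()] for the text syntax.
#' @export
peptide <- function(residues, nterm = NA_character_, cterm = NA_character_,
                    residue_mods = list(), registry = mod_registry()) {
  if (is.character(residues) && length(residues) == 1L && nchar(residues) > 1L)
    residues <- strsplit(residues, "")[[1]]
  residues <- as.character(residues)
  if (!length(residues)) stop("a peptide needs at least one residue")
  bad <- setdiff(residues, names(.RESIDUE_FORMULA))
  if (length(bad)) stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  if (!is.na(nterm)) {
    row <- .mod_row(nterm, registry)
    if (row$target != "N-term")
      stop("'", nterm, "' is not an N-terminal modification")
    if (nzchar(row$residue) && residues[1] != row$residue)
      stop("'", nterm, "' requires ", row$residue, " at the N-terminus")
  }
  if (!is.na(cterm)) {
    row <- .mod_row(cterm, registry)
    if (row$target != "C-term")
      stop("'", cterm, "' is not a C-terminal modification")
  }
  residue_mods <- as.list(residue_mods)
  if (length(residue_mods)) {
    pos <- suppressWarnings(as.integer(names(residue_mods)))
    if (anyNA(pos) || any(pos < 1 | pos > length(residues)))
      stop("residue_mods must be named by valid 1-based positions")
    for (k in seq_along(residue_mods)) {
      row <- .mod_row(residue_mods[[k]], registry)
      if (row$target != "residue")
        stop("'", residue_mods[[k]], "' is not a residue modification")
      if (nzchar(row$residue) && residues[pos[k]] != row$residue)
        stop("'", residue_mods[[k]], "' applies to ", row$residue,
             ", not ", residues[pos[k]])
    }
    residue_mods <- residue_mods[order(pos)]
  }
  structure(list(residues = residues, nterm = nterm, cterm = cterm,
                 residue_mods = residue_mods),
            class = "peptide")
}

as_peptide <- function(x, registry = mod_registry()) {
  if (inherits(x, "peptide")) return(x)
  if (is.character(x) && length(x) == 1L) return(parse_peptide(x, registry))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a peptide")
}

#' Parse peptide text syntax
#'
#' Accepts sequences in the notation used throughout this package:
#' an optional N-terminal prefix token followed by `-` (`Bz-` benzoyl,
#' `cBz-` carboxybenzoyl, `pE-` pyroglutamate, which contributes the Glu
#' itself), an optional `-NH2` (amidation) or `-OH` (explicit free acid)
#' suffix, `(ox)` after an oxidized Met, and `I/L` (or `J`) for the
#' Ile/Leu-ambiguous residue. Examples: `"Bz-ARF-NH2"`, `"pE-DWI/LP"`,
#' `"KVIKM(ox)V"`.
#'
#' @param text Peptide string.
#' @param registry Modification registry (provides the prefix tokens).
#' @return A [peptide()] object.
#' @export
parse_peptide <- function(text, registry = mod_registry()) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text))
    stop("'text' must be a non-empty string")
  s <- text
  nterm <- NA_character_
  cterm <- NA_character_
  lead <- character(0)

  nrows <- registry[registry$target == "N-term" & nzchar(registry$prefix), ]
  for (k in order(-nchar(nrows$prefix))) {
    pre <- paste0(nrows$prefix[k], "-")
    if (startsWith(s, pre)) {
      nterm <- nrows$name[k]
      if (nzchar(nrows$residue[k])) lead <- nrows$residue[k]
      s <- substring(s, nchar(pre) + 1L)
      break
    }
  }
  if (endsWith(s, "-NH2")) {
    cterm <- "amidation"
    s <- substring(s, 1L, nchar(s) - 4L)
  } else if (endsWith(s, "-OH")) {
    s <- substring(s, 1L, nchar(s) - 3L)
  }

  residues <- character(0)
  residue_mods <- list()
  i <- 1L
  while (i <= nchar(s)) {
    if (substring(s, i, i + 2L) == "I/L") {
      residues <- c(residues, "J"); i <- i + 3L; next
    }
    ch <- substring(s, i, i)
    if (ch == "(") {
      j <- regexpr(")", substring(s, i), fixed = TRUE)
      if (j < 0) stop("unclosed '(' in peptide string '", text, "'")
      tok <- substring(s, i + 1L, i + j - 2L)
      row <- registry[registry$prefix == tok & registry$target == "residue", ]
      if (nrow(row) != 1L)
        stop("unknown residue modification token '(", tok, ")'")
      if (!length(residues)) stop("'(", tok, ")' must follow a residue")
      residue_mods[[as.character(length(residues) + length(lead))]] <- row$name
      i <- i + j
      next
    }
    if (!ch %in% names(.RESIDUE_FORMULA))
      stop("unknown residue code '", ch, "' in '", text, "'")
    residues <- c(residues, ch)
    i <- i + 1L
  }
  peptide(c(lead, residues), nterm = nterm, cterm = cterm,
          residue_mods = residue_mods, registry = registry)
}

#' Format a peptide as text
#'
#' Inverse of [parse_peptide()]: `J` renders as `I/L`, an oxidized Met as
#' `M(ox)`, terminal modifications as their prefix/suffix tokens (the Glu
#' consumed by a `pE-` prefix is not repeated).
#'
#' @inheritParams peptide_neutral_mass
#' @return Character scalar.
#' @export
format_peptide <- function(p, registry = mod_registry()) {
  p <- as_peptide(p, registry)
  res <- p$residues
  body <- ifelse(res == "J", "I/L", res)
  if (length(p$residue_mods)) {
    pos <- as.integer(names(p$residue_mods))
    for (k in seq_along(pos)) {
      tok <- .mod_row(p$residue_mods[[k]], registry)$prefix
      body[pos[k]] <- paste0(body[pos[k]], "(", tok, ")")
    }
  }
  pre <- ""
  if (!is.na(p$nterm)) {
    row <- .mod_row(p$nterm, registry)
    pre <- paste0(row$prefix, "-")
    if (nzchar(row$residue)) body <- body[-1L]
  }
  paste0(pre, paste(body, collapse = ""),
         if (identical(p$cterm, "amidation")) "-NH2" else "")
}

#' @export
print.peptide <- function(x, ...) {
  cat("<peptide> ", format_peptide(x), "  (", length(x$residues),
      " residues, M = ", sprintf("%.4f", peptide_neutral_mass(x)), " Da)\n",
      sep = "")
  invisible(x)
}

#' @export
format.peptide <- function(x, ...) format_peptide(x)
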