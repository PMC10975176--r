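#' Reconstruct truncation/amidation peptide families
#'
#' Links peptides by the post-translational processing steps seen in venom
#' maturation: (a) loss of one terminal residue with otherwise identical
#' modifications (carboxypeptidase/aminopeptidase truncation; mass change =
#' the residue mass), (b) loss of a C-terminal Gly with gain of amidation
#' (the PHM/PAL two-step conversion; mass change 58.00548 Da), and (c)
#' identity up to Met/Met-oxidation (mass change 15.99491 Da). Edges are
#' directed from the longer (or unoxidized) parent to the child; connected
#' components form families.
#'
#' @param peptides List of [peptide()] objects or parseable strings.
#' @param registry Modification registry.
#' @return List of `peptide_family` objects, each with `members` (indices
#'   into the input and text forms) and `edges` (data frame `parent`,
#'   `child`, `transformation`, `mass_delta`).
#' @export
find_families <- function(peptides, registry = mod_registry()) {
  peps <- lapply(peptides, as_peptide, registry = registry)
  seqs <- vapply(peps, function(p) format_peptide(p, registry), "")
  n <- length(peps)
  edges <- list()
  add_edge <- function(parent, child, transformation) {
    delta <- peptide_neutral_mass(peps[[parent]], registry) -
      peptide_neutral_mass(peps[[child]], registry)
    edges[[length(edges) + 1L]] <<- data.frame(
      parent = seqs[parent], child = seqs[child],
      parent_index = parent, child_index = child,
      transformation = transformation, mass_delta = delta)
  }
  key <- function(p, drop = NULL) {
    res <- p$residues
    mods <- p$residue_mods
    if (!is.null(drop)) {
      keep <- res[-drop]
      pos <- as.integer(names(mods))
      pos <- pos[pos != drop]
      pos[pos > drop] <- pos[pos > drop] - 1L
      mods <- stats::setNames(as.list(unlist(mods[as.character(
        as.integer(names(mods))[as.integer(names(mods)) != drop])])), pos)
      res <- keep
    }
    paste(paste(res, collapse = ""), p$nterm, p$cterm,
          paste(names(mods), unlist(mods), collapse = ","), sep = "|")
  }
  full_keys <- vapply(peps, key, "")
  for (a in seq_len(n)) {
    pa <- peps[[a]]
    la <- length(pa$residues)
    for (b in seq_len(n)) {
      if (a == b) next
      pb <- peps[[b]]
      lb <- length(pb$residues)
      if (la == lb + 1L) {
        # (a) single terminal truncation, modifications unchanged
        if (identical(key(pa, drop = la), full_keys[b]) &&
            !(la %in% as.integer(names(pa$residue_mods))))
          add_edge(a, b, "C-terminal truncation")
        if (is.na(pa$nterm) && is.na(pb$nterm) &&
            identical(key(pa, drop = 1L), full_keys[b]) &&
            !(1L %in% as.integer(names(pa$residue_mods))))
          add_edge(a, b, "N-terminal truncation")
        # (b) C-terminal Gly converted to amidation
        if (pa$residues[la] == "G" && is.na(pa$cterm) &&
            identical(pb$cterm, "amidation") &&
            identical(paste(pa$residues[-la], collapse = ""),
                      paste(pb$residues, collapse = "")) &&
            identical(pa$nterm, pb$nterm) &&
            identical(pa$residue_mods, pb$residue_mods))
          add_edge(a, b, "Gly-to-amide")
      } else if (la == lb) {
        # (c) identical up to Met oxidation (parent = unoxidized)
        if (identical(paste(pa$residues, collapse = ""),
                      paste(pb$residues, collapse = "")) &&
            identical(pa$nterm, pb$nterm) && identical(pa$cterm, pb$cterm) &&
            length(pa$residue_mods) == 0L && length(pb$residue_mods) > 0L &&
            all(unlist(pb$residue_mods) == "oxidation"))
          add_edge(a, b, "oxidation")
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(parent = character(0), child = character(0),
                           parent_index = integer(0), child_index = integer(0),
                           transformation = character(0),
                           mass_delta = numeric(0))
  # connected components by union-find
  comp <- seq_len(n)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  for (k in seq_len(nrow(edges))) {
    ra <- find(edges$parent_index[k]); rb <- find(edges$child_index[k])
    if (ra != rb) comp[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  fams <- lapply(sort(unique(roots)), function(r) {
    idx <- which(roots == r)
    structure(list(
      members = seqs[idx], member_index = idx,
      edges = edges[edges$parent_index %in% idx |
                      edges$child_index %in% idx, , drop = FALSE]),
      class = "peptide_family")
  })
  fams[order(-vapply(fams, function(f) length(f$members), integer(1)))]
}

#' @export
print.peptide_family <- function(x, ...) {
  cat("<peptide_family> ", paste(x$members, collapse = ", "), "\n", sep = "")
  if (nrow(x$edges))
    for (k in seq_len(nrow(x$edges)))
      cat(sprintf("  %s -> %s  [%s, %+0.4f Da]\n", x$edges$parent[k],
                  x$edges$child[k], x$edges$transformation[k],
                  -x$edges$mass_delta[k]))
  invisible(x)
}

#' Peptide length distribution
#'
#' @param peptides List of [peptide()]s or parseable strings.
#' @return Named numeric vector mapping length to percentage of the input
#'   (one decimal, summing to 100 within rounding).
#' @export
length_distribution <- function(peptides) {
  if (!length(peptides)) stop("'peptides' must be nonempty")
  lens <- vapply(peptides, function(p) length(as_peptide(p)$residues),
                 integer(1))
  tab <- table(lens)
  round(100 * as.numeric(tab) / sum(tab), 1) |>
    stats::setNames(names(tab))
}

#' Load a dipeptide bioactivity fixture table
#'
#' The packaged table transcribes literature bioactivity annotations for the
#' ten ACE-inhibitory dipeptides recovered from scorpion-venom
#' ultrafiltrate, with per-source activity lists (AHTPDB and BIOPEP
#' fixtures) and the externally computed PeptideRanker score, which this
#' package only echoes, never computes.
#'
#' @param path Path to a tab-separated fixture; defaults to the packaged
#'   table.
#' @return `data.frame` with columns `no`, `sequence`, `ranker_score`,
#'   `ahtpdb`, `biopep` (the last two semicolon-separated lists).
#' @export
load_activity_table <- function(path = system.file(
  "extdata", "dipeptide_activities.tsv", package = "venomdenovo")) {
  if (!nzchar(path) || !file.exists(path))
    stop("activity fixture table not found")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                           colClasses = "character", fill = TRUE)
  tab$ahtpdb[is.na(tab$ahtpdb)] <- ""
  tab$biopep[is.na(tab$biopep)] <- ""
  tab
}

#' Expand I/L-ambiguous sequence text to concrete variants
#'
#' @param seq_text Sequence in package notation (may contain `I/L` or `J`).
#' @return Character vector of `2^k` concrete sequences for `k` ambiguous
#'   positions.
#' @export
expand_il <- function(seq_text) {
  p <- as_peptide(seq_text)
  amb <- which(p$residues == "J")
  if (!length(amb)) return(paste(p$residues, collapse = ""))
  grid <- expand.grid(rep(list(c("I", "L")), length(amb)),
                      stringsAsFactors = FALSE)
  apply(grid, 1, function(row) {
    r <- p$residues; r[amb] <- row
    paste(r, collapse = "")
  })
}

#' Annotate peptides with fixture bioactivities
#'
#' Each query is expanded over its Ile/Leu assignments and every concrete
#' expansion is looked up in the fixture sources (whose own I/L-ambiguous
#' keys are expanded the same way). Modified peptides are looked up by bare
#' residue sequence and flagged. PeptideRanker scores are carried through
#' from the fixture, never computed.
#'
#' @param peptides List of [peptide()]s or sequence strings.
#' @param fixtures Activity table from [load_activity_table()].
#' @param registry Modification registry.
#' @return List of annotation records, one per query: `sequence`,
#'   `expansions`, `activities` (data frame `source`, `label`),
#'   `ranker_score` (fixture value or `NA`), `modified` flag.
#' @export
annotate_activity <- function(peptides, fixtures = load_activity_table(),
                              registry = mod_registry()) {
  # expand fixture keys once
  lut <- list()
  for (r in seq_len(nrow(fixtures))) {
    for (sq in expand_il(fixtures$sequence[r])) {
      lut[[sq]] <- rbind(
        lut[[sq]],
        .source_rows("AHTPDB-fixture", fixtures$ahtpdb[r],
                     fixtures$ranker_score[r]),
        .source_rows("BIOPEP-fixture", fixtures$biopep[r],
                     fixtures$ranker_score[r]))
    }
  }
  lapply(peptides, function(q) {
    p <- as_peptide(q, registry)
    modified <- !is.na(p$nterm) || !is.na(p$cterm) || length(p$residue_mods) > 0
    bare <- paste(p$residues, collapse = "")
    expansions <- expand_il(bare)
    acts <- list(); ranker <- NA_character_
    for (sq in expansions) {
      hit <- lut[[sq]]
      if (is.null(hit)) next
      acts[[length(acts) + 1L]] <- hit[, c("source", "label")]
      ranker <- hit$ranker[1]
    }
    acts <- if (length(acts)) unique(do.call(rbind, acts))
            else data.frame(source = character(0), label = character(0))
    rownames(acts) <- NULL
    list(sequence = format_peptide(p, registry), expansions = expansions,
         activities = acts, ranker_score = ranker, modified = modified)
  })
}

.split_labels <- function(s) {
  if (!nzchar(s)) return(character(0))
  unique(trimws(strsplit(s, ";", fixed = TRUE)[[1]]))
}

.source_rows <- function(source, labels, ranker) {
  labels <- .split_labels(labels)
  if (!length(labels)) return(NULL)
  data.frame(source = source, label = labels, ranker = ranker)
}
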