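#' De novo sequencing configuration
#'
#' @param tol_da Fragment matching tolerance in Da.
#' @param precursor_ppm Precursor tolerance in ppm, used when
#'   `precursor_tol_da` is `NA`.
#' @param precursor_tol_da Absolute precursor tolerance in Da; overrides the
#'   ppm tolerance when set.
#' @param min_coverage Minimum fraction of cleavage sites that must be
#'   supported by at least one b/y ion for a candidate to be kept.
#' @param lambda Weight of the summed relative intensity of matched peaks in
#'   the candidate score.
#' @param top_k Number of ranked candidates returned by [denovo()].
#' @param max_paths Cap on partial paths explored in the spectrum graph
#'   (50,000 keeps 12-residue ladders, whose spurious-node searches branch
#'   heavily, exhaustively enumerable in well under a second).
#' @param cterm_hypotheses C-terminal forms evaluated against the precursor
#'   mass: subset of `c("acid", "amide")`.
#' @param allow_offset Allow a fallback search with one unexplained
#'   N-terminal mass offset when the spectrum is poorly explained.
#' @param offset_trigger Coverage below which the offset fallback engages:
#'   if no candidate reaches this site coverage, the search is repeated
#'   allowing an open N-terminal offset and the candidate pools are merged.
#' @param charges_unknown Charge hypotheses tried when a spectrum's CHARGE
#'   is unknown (0).
#' @return List of class `"denovo_config"`.
#' @export
denovo_config <- function(tol_da = 0.02, precursor_ppm = 50,
                          precursor_tol_da = NA_real_, min_coverage = 0.5,
                          lambda = 0.1, top_k = 50L, max_paths = 50000L,
                          cterm_hypotheses = c("acid", "amide"),
                          allow_offset = TRUE, offset_trigger = 0.75,
                          charges_unknown = c(1L, 2L)) {
  cterm_hypotheses <- match.arg(cterm_hypotheses, c("acid", "amide"),
                                several.ok = TRUE)
  structure(list(tol_da = tol_da, precursor_ppm = precursor_ppm,
                 precursor_tol_da = precursor_tol_da,
                 min_coverage = min_coverage, lambda = lambda,
                 top_k = as.integer(top_k), max_paths = as.integer(max_paths),
                 cterm_hypotheses = cterm_hypotheses,
                 allow_offset = allow_offset,
                 offset_trigger = offset_trigger,
                 charges_unknown = as.integer(charges_unknown)),
            class = "denovo_config")
}

.precursor_neutral <- function(s, charge) (s$precursor_mz - .PROTON) * charge

#' Build the spectrum graph
#'
#' Every peak is interpreted both as a b-ion (prefix mass = peak - proton)
#' and as a y-ion (prefix mass = neutral mass - peak + proton); prefix
#' values closer than half the tolerance are merged. Anchor nodes 0 and the
#' precursor-derived neutral mass are always present. Edges record every
#' single-residue, modified-residue and registered terminal-block mass
#' difference within `tol_da`, plus the final residue-plus-terminus steps
#' into the neutral-mass anchor.
#'
#' @param s A [spectrum()] with known (or hypothesized) precursor charge.
#' @param tol_da Matching tolerance in Da.
#' @param registry Modification registry.
#' @param charge Charge hypothesis overriding `s$charge`.
#' @return List of class `"spectrum_graph"` with `nodes` (sorted Da values),
#'   `edges` (data frame `from`, `to`, `explanation`, `error`) and
#'   `neutral_mass`.
#' @export
build_spectrum_graph <- function(s, tol_da = 0.02, registry = mod_registry(),
                                 charge = NULL) {
  z <- if (!is.null(charge)) charge else s$charge
  if (is.na(z) || z < 1)
    stop("precursor charge unknown; pass an explicit charge hypothesis")
  M <- .precursor_neutral(s, z)
  pk <- s$peaks$mz
  vals <- c(pk - .PROTON, M - pk + .PROTON)
  vals <- vals[vals > 2 & vals < M - 40]
  vals <- sort(vals)
  merged <- numeric(0)
  if (length(vals)) {
    grp <- cumsum(c(TRUE, diff(vals) > tol_da / 2))
    merged <- as.numeric(tapply(vals, grp, mean))
  }
  nodes <- sort(c(0, merged, M))
  inner <- c(0, merged)
  edges <- .graph_edges(inner, M, tol_da, registry)
  structure(list(nodes = nodes, neutral_mass = M, tol_da = tol_da,
                 charge = z, edges = edges),
            class = "spectrum_graph")
}

.graph_edges <- function(inner, M, tol_da, registry) {
  out <- list()
  add <- function(from, to, explanation, error)
    out[[length(out) + 1L]] <<- data.frame(from = from, to = to,
                                           explanation = explanation,
                                           error = error)
  tab <- .delta_table(registry)
  for (u in inner) for (v in c(inner[inner > u], M)) {
    if (v == M) {  # last step absorbs the C-terminal group
      err <- tab$mass + .MASS_H2O - (v - u)
      sel <- abs(err) <= tol_da & tab$kind != "terminal_block"
      if (any(sel)) {
        expl <- data.frame(explanation = paste0(tab$explanation[sel], "+H2O"),
                           error = err[sel])
      } else expl <- NULL
    } else {
      err <- tab$mass - (v - u)
      sel <- abs(err) <= tol_da
      if (u > 0)  # terminal blocks only leave the N-terminal anchor
        sel <- sel & tab$kind != "terminal_block"
      expl <- if (any(sel))
        data.frame(explanation = tab$explanation[sel], error = err[sel])
      else NULL
    }
    if (!is.null(expl))
      for (k in seq_len(nrow(expl)))
        add(u, v, expl$explanation[k], expl$error[k])
  }
  if (!length(out))
    return(data.frame(from = numeric(0), to = numeric(0),
                      explanation = character(0), error = numeric(0)))
  do.call(rbind, out)
}

#' @export
print.spectrum_graph <- function(x, ...) {
  cat(sprintf("<spectrum_graph> %d nodes, %d edges, neutral mass %.4f (%d+)\n",
              length(x$nodes), nrow(x$edges), x$neutral_mass, x$charge))
  invisible(x)
}

# Alphabet used for path building: 19 mass-distinct residues (I/L collapsed
# to J) plus, when the registry enables it, oxidized Met.
.path_alphabet <- function(registry) {
  res <- .residue_masses[setdiff(names(.residue_masses), c("I", "L"))]
  lab <- names(res)
  mods <- rep(NA_character_, length(res))
  if ("oxidation" %in% registry$name[registry$enabled]) {
    res <- c(res, .residue_masses[["M"]] + .mod_delta("oxidation", registry))
    lab <- c(lab, "M")
    mods <- c(mods, "oxidation")
  }
  list(mass = unname(res), code = lab, mod = mods)
}

#' Enumerate sequence candidates from a spectrum graph
#'
#' Depth-first search over the graph's prefix-mass nodes from the
#' N-terminal anchor. Each step appends a residue (or, leaving the anchor,
#' a registered modified terminal block) whose exact cumulative prefix mass
#' lies within `tol_da` of a node; the final step absorbs the last one or
#' two residues together with the C-terminal group (free acid and/or amide,
#' per the configuration) to land on the precursor-derived neutral mass.
#' Ile/Leu positions are emitted as the ambiguity residue `J`. Candidates
#' whose site coverage falls below `config$min_coverage` are dropped; if no
#' candidate explains the spectrum well (best coverage below
#' `config$offset_trigger`) and `config$allow_offset` is set, the search is
#' additionally run allowing one unexplained N-terminal mass offset,
#' reported in the candidate's `unexplained_terminal_mass`, and the pools
#' are merged.
#'
#' @param g A [build_spectrum_graph()] result.
#' @param s The spectrum the graph was built from (used for scoring).
#' @param config A [denovo_config()].
#' @param registry Modification registry.
#' @return List of candidate objects (class `"seq_candidate"`), unsorted.
#' @export
enumerate_candidates <- function(g, s, config = denovo_config(),
                                 registry = mod_registry()) {
  score_all <- function(cands)
    lapply(cands, score_candidate, s = s, tol_da = config$tol_da,
           lambda = config$lambda, registry = registry)
  cands <- score_all(.enumerate_paths(g, config, registry,
                                      offset_mode = FALSE))
  covs <- vapply(cands, `[[`, numeric(1), "coverage")
  best <- if (length(covs)) max(covs) else 0
  if (config$allow_offset && best < config$offset_trigger)
    cands <- c(cands, score_all(.enumerate_paths(g, config, registry,
                                                 offset_mode = TRUE)))
  keep <- vapply(cands, function(x) x$coverage >= config$min_coverage,
                 logical(1))
  cands[keep]
}

.enumerate_paths <- function(g, config, registry, offset_mode = FALSE) {
  M <- g$neutral_mass
  tol <- config$tol_da
  prec_tol <- if (is.na(config$precursor_tol_da))
    config$precursor_ppm * 1e-6 * M else config$precursor_tol_da
  nodes <- g$nodes
  inner <- sort(nodes[nodes > 0 & nodes < M])
  alpha <- .path_alphabet(registry)
  na <- length(alpha$mass)

  # completion table: residue part (single or ordered pair) + C-term group
  pair_i <- rep(seq_len(na), each = na)
  pair_j <- rep(seq_len(na), times = na)
  cterm_add <- c(acid = .MASS_H2O, amide = .MASS_NH3)[config$cterm_hypotheses]
  comp <- list()
  for (h in names(cterm_add)) {
    comp[[length(comp) + 1L]] <- data.frame(
      mass = alpha$mass + cterm_add[[h]], i1 = seq_len(na), i2 = NA_integer_,
      hyp = h)
    comp[[length(comp) + 1L]] <- data.frame(
      mass = alpha$mass[pair_i] + alpha$mass[pair_j] + cterm_add[[h]],
      i1 = pair_i, i2 = pair_j, hyp = h)
  }
  comp <- do.call(rbind, comp)
  ord <- order(comp$mass)
  comp_mass <- comp$mass[ord]
  comp_i1 <- comp$i1[ord]; comp_i2 <- comp$i2[ord]; comp_hyp <- comp$hyp[ord]

  nmods <- registry[registry$target == "N-term" & registry$enabled, ,
                    drop = FALSE]
  out <- new.env(parent = emptyenv())
  out$res <- list(); out$seen <- new.env(parent = emptyenv()); out$paths <- 0L

  add_mod <- function(mods, pos, mod) {
    if (!is.na(mod)) mods[[as.character(pos)]] <- mod
    mods
  }

  emit <- function(residues, mods, nterm, cterm, offset) {
    key <- paste(nterm, paste(residues, collapse = ""),
                 paste(names(mods), unlist(mods), collapse = ","),
                 cterm, sprintf("%.4f", offset), sep = "|")
    if (exists(key, envir = out$seen, inherits = FALSE)) return(invisible())
    assign(key, TRUE, envir = out$seen)
    p <- peptide(residues,
                 nterm = nterm,
                 cterm = if (cterm == "amide") "amidation" else NA_character_,
                 residue_mods = mods, registry = registry)
    neutral <- peptide_neutral_mass(p, registry)
    if (abs(neutral + offset - M) > max(prec_tol, tol)) return(invisible())
    out$res[[length(out$res) + 1L]] <- structure(
      list(peptide = p, unexplained_terminal_mass =
             if (offset != 0) offset else NA_real_,
           neutral_mass = neutral, target_neutral = M,
           score = NA_real_, coverage = NA_real_, matches = NULL),
      class = "seq_candidate")
  }

  step <- function(prefix, residues, mods, nterm, offset) {
    if (out$paths > config$max_paths) return(invisible())
    out$paths <- out$paths + 1L
    nres <- length(residues)
    # complete with one or two residues plus the C-terminal group
    tgt <- M - prefix
    lo <- findInterval(tgt - tol, comp_mass) + 1L
    hi <- findInterval(tgt + tol, comp_mass)
    if (hi >= lo) for (k in lo:hi) {
      i1 <- comp_i1[k]; i2 <- comp_i2[k]
      mods2 <- add_mod(mods, nres + 1L, alpha$mod[i1])
      res2 <- c(residues, alpha$code[i1])
      if (!is.na(i2)) {
        mods2 <- add_mod(mods2, nres + 2L, alpha$mod[i2])
        res2 <- c(res2, alpha$code[i2])
      }
      emit(res2, mods2, nterm, comp_hyp[k], offset)
    }
    # extend by one residue to a supported prefix node
    vlo <- findInterval(prefix + 30, inner) + 1L
    vhi <- findInterval(prefix + 220, inner)
    if (vhi >= vlo) for (vi in vlo:vhi) {
      d <- inner[vi] - prefix
      for (k in which(abs(alpha$mass - d) <= tol))
        step(prefix + alpha$mass[k], c(residues, alpha$code[k]),
             add_mod(mods, nres + 1L, alpha$mod[k]), nterm, offset)
    }
  }

  # plain start
  step(0, character(0), list(), NA_character_, 0)

  # unmodified two-residue first step (mirrors the two-residue completion:
  # the first cleavage site may be unobserved, the second must be a node)
  if (!offset_mode) {
    pstarts <- inner[inner < max(alpha$mass) * 2 + tol]
    for (v in pstarts) {
      hits <- which(abs(alpha$mass[pair_i] + alpha$mass[pair_j] - v) <= tol)
      for (k in hits) {
        i1 <- pair_i[k]; i2 <- pair_j[k]
        mods2 <- add_mod(add_mod(list(), 1L, alpha$mod[i1]), 2L,
                         alpha$mod[i2])
        step(alpha$mass[i1] + alpha$mass[i2],
             c(alpha$code[i1], alpha$code[i2]), mods2, NA_character_, 0)
      }
    }
  }

  # modified terminal-block starts
  if (!offset_mode && nrow(nmods)) {
    res19 <- .residue_masses[setdiff(names(.residue_masses), c("I", "L"))]
    for (m in seq_len(nrow(nmods))) {
      delta <- nmods$delta[m]
      first <- if (nzchar(nmods$residue[m])) nmods$residue[m] else names(res19)
      for (r1 in first) {
        base <- delta + .residue_masses[[r1]]
        if (any(abs(inner - base) <= tol))
          step(base, r1, list(), nmods$name[m], 0)
        # two-residue block (b1 unobserved): only for residue-anchored mods
        if (nzchar(nmods$residue[m])) {
          for (r2 in names(res19)) {
            b2 <- base + res19[[r2]]
            if (any(abs(inner - b2) <= tol))
              step(b2, c(r1, r2), list(), nmods$name[m], 0)
          }
        }
      }
    }
  }

  # offset mode: one unexplained N-terminal mass before the first residue
  if (offset_mode) {
    for (v in inner) for (k in seq_along(alpha$mass)) {
      off <- v - alpha$mass[k]
      if (off <= tol) next
      mods2 <- add_mod(list(), 1L, alpha$mod[k])
      step(v, alpha$code[k], mods2, NA_character_, off)
    }
  }
  out$res
}

#' Score a sequence candidate against a spectrum
#'
#' `score = coverage + lambda * sum(relative intensity of matched peaks)`,
#' where coverage is the fraction of the peptide's `n - 1` cleavage sites
#' supported by at least one matched b- or y-ion (singly charged, plus
#' doubly charged when the precursor is 2+). A candidate's theoretical b
#' ions are shifted by its unexplained N-terminal mass, if any.
#'
#' @param cand A candidate from [enumerate_candidates()], or a [peptide()].
#' @param s The [spectrum()].
#' @param tol_da Matching tolerance in Da.
#' @param lambda Intensity weight.
#' @param registry Modification registry.
#' @return The candidate with `matches`, `coverage` and `score` filled in.
#' @export
score_candidate <- function(cand, s, tol_da = 0.02, lambda = 0.1,
                            registry = mod_registry()) {
  if (inherits(cand, "peptide") || is.character(cand))
    cand <- structure(list(peptide = as_peptide(cand, registry),
                           unexplained_terminal_mass = NA_real_,
                           neutral_mass = peptide_neutral_mass(
                             as_peptide(cand, registry), registry),
                           target_neutral = NA_real_, score = NA_real_,
                           coverage = NA_real_, matches = NULL),
                      class = "seq_candidate")
  p <- cand$peptide
  n <- length(p$residues)
  charges <- if (!is.na(s$charge) && s$charge >= 2) c(1L, 2L) else 1L
  theo <- fragment_table(p, charges = charges, series = c("b", "y"),
                         registry = registry)
  off <- cand$unexplained_terminal_mass
  if (!is.na(off) && nrow(theo)) {
    bsel <- theo$series == "b"
    theo$mz[bsel] <- theo$mz[bsel] + off / theo$charge[bsel]
  }
  if (nrow(theo)) {
    theo$label <- paste0(theo$series, theo$index,
                         ifelse(theo$charge > 1,
                                paste0("^", theo$charge, "+"), ""))
    theo$site <- ifelse(theo$series == "b", theo$index, n - theo$index)
  }
  m <- match_peaks(s, theo, tol_da)
  sites_hit <- integer(0)
  intsum <- 0
  if (nrow(m)) {
    idx <- match(m$label, theo$label)
    site <- theo$site[idx]
    sites_hit <- unique(site[site >= 1 & site <= n - 1])
    intsum <- sum(m$relative_intensity[!duplicated(m$observed_mz)])
  }
  cand$matches <- m
  cand$coverage <- if (n > 1) length(sites_hit) / (n - 1) else 0
  cand$score <- cand$coverage + lambda * intsum
  cand$mean_abs_error <- if (nrow(m)) mean(abs(m$error)) else Inf
  cand
}

#' @export
print.seq_candidate <- function(x, ...) {
  cat(sprintf("<candidate> %s  score %.3f  coverage %.2f%s\n",
              format_peptide(x$peptide), x$score, x$coverage,
              if (!is.na(x$unexplained_terminal_mass))
                sprintf("  +%.4f Da unexplained at N-term",
                        x$unexplained_terminal_mass) else ""))
  invisible(x)
}

.candidate_mod_count <- function(cand) {
  p <- cand$peptide
  sum(!is.na(p$nterm), identical(p$cterm, "amidation"),
      length(p$residue_mods), !is.na(cand$unexplained_terminal_mass))
}

#' Rank candidate table
#'
#' @param candidates List of scored candidates.
#' @return `data.frame` with one row per candidate: `rank`, `sequence`,
#'   `score`, `coverage`, `n_mods`, `unexplained_mass`, `neutral_mass`.
#' @export
candidate_table <- function(candidates) {
  if (!length(candidates))
    return(data.frame(rank = integer(0), sequence = character(0),
                      score = numeric(0), coverage = numeric(0),
                      n_mods = integer(0), unexplained_mass = numeric(0),
                      neutral_mass = numeric(0)))
  df <- data.frame(
    sequence = vapply(candidates, function(x) format_peptide(x$peptide), ""),
    score = vapply(candidates, `[[`, numeric(1), "score"),
    coverage = vapply(candidates, `[[`, numeric(1), "coverage"),
    n_mods = vapply(candidates, .candidate_mod_count, numeric(1)),
    unexplained_mass = vapply(candidates, `[[`, numeric(1),
                              "unexplained_terminal_mass"),
    neutral_mass = vapply(candidates, `[[`, numeric(1), "neutral_mass"))
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  df
}

#' De novo sequencing of one spectrum
#'
#' Builds the spectrum graph, enumerates and scores candidates, and returns
#' them ranked by score (descending), ties broken by smaller mean absolute
#' matching error (which separates candidates that are near-isobaric within
#' the tolerance, e.g. a carboxybenzoyl-Ser block vs a benzoyl-Met block at
#' 19 mDa, or an Asn vs a Gly-Gly reading), then by parsimony (fewer
#' residues, fewer modifications — an exactly isobaric split such as Gln vs
#' Gly-Ala can tie on evidence and error alike), then lexicographically by
#' sequence. When the spectrum's charge is unknown
#' (0), the configured charge hypotheses are tried and their candidates
#' pooled.
#'
#' @param s A [spectrum()].
#' @param config A [denovo_config()].
#' @param registry Modification registry.
#' @return Object of class `"denovo_result"`: list with `candidates` (ranked
#'   list) and `table` (see [candidate_table()]).
#' @export
denovo <- function(s, config = denovo_config(), registry = mod_registry()) {
  charges <- if (!is.na(s$charge) && s$charge >= 1) s$charge
             else config$charges_unknown
  cands <- list()
  for (z in charges) {
    g <- build_spectrum_graph(s, config$tol_da, registry, charge = z)
    cands <- c(cands, enumerate_candidates(g, s, config, registry))
  }
  if (length(cands)) {
    score <- vapply(cands, `[[`, numeric(1), "score")
    nm <- vapply(cands, .candidate_mod_count, numeric(1))
    err <- vapply(cands, function(x)
      if (is.null(x$mean_abs_error)) Inf else x$mean_abs_error, numeric(1))
    nres <- vapply(cands, function(x) length(x$peptide$residues), integer(1))
    seqs <- vapply(cands, function(x) format_peptide(x$peptide), "")
    # keys quantized far below measurement precision so that last-ulp
    # arithmetic differences between isobaric candidates cannot outrank
    # the parsimony criteria
    ord <- order(-round(score, 9), round(err, 7), nres, nm, seqs)
    cands <- cands[ord]
    seqs <- seqs[ord]
    cands <- cands[!duplicated(seqs)]
    cands <- cands[seq_len(min(length(cands), config$top_k))]
  }
  structure(list(title = s$title, candidates = cands,
                 table = candidate_table(cands)),
            class = "denovo_result")
}

#' @export
print.denovo_result <- function(x, ...) {
  cat("<denovo_result> ", x$title, ": ", length(x$candidates),
      " candidate(s)\n", sep = "")
  if (nrow(x$table)) print(utils::head(x$table, 10))
  invisible(x)
}
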