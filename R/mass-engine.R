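#' Parse a signed elemental formula
#'
#' Parses strings such as `"C10H10NO2"`, `"H-2O-1"` or `"HNO-1"` into a named
#' vector of signed element counts. Supported elements are C, H, N, O and S.
#'
#' @param formula Character scalar. Elements followed by an optional signed
#'   integer count; a missing count means 1.
#' @return Named numeric vector of element counts (C, H, N, O, S).
#' @examples
#' parse_formula("C7H4O")
#' parse_formula("H-2O-1")  # loss of water
#' @export
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula))
    stop("'formula' must be a single character string")
  counts <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
  if (formula == "" || formula == "0") return(counts)
  pat <- "([A-Z][a-z]?)(-?[0-9]*)"
  m <- gregexpr(pat, formula, perl = TRUE)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  toks <- toks[nzchar(toks)]
  leftover <- gsub(pat, "", formula, perl = TRUE)
  if (nzchar(leftover))
    stop("unparseable formula: '", formula, "'")
  for (tok in toks) {
    el <- sub("^([A-Z][a-z]?).*$", "\\1", tok)
    n  <- sub("^[A-Z][a-z]?", "", tok)
    if (!el %in% names(counts))
      stop("unsupported element '", el, "' in formula '", formula, "'")
    counts[el] <- counts[el] + if (nzchar(n)) as.numeric(n) else 1
  }
  counts
}

#' Monoisotopic mass of an elemental formula
#'
#' With `charge = 0` the neutral monoisotopic mass is returned; with
#' `charge >= 1` the m/z of the corresponding cation, i.e. the neutral mass
#' minus `charge` electron masses, divided by `charge`. Use this for cation
#' assignments such as the \[C10H10NO2\]+ b1 ion of an N-benzoylated
#' alanine (176.0706).
#'
#' @param formula Signed elemental formula string (see [parse_formula()]),
#'   or a named numeric vector of element counts.
#' @param charge Non-negative integer.
#' @return Monoisotopic mass (Da) or m/z.
#' @examples
#' formula_mass("H2O")               # 18.01056
#' formula_mass("C10H10NO2", 1)      # 176.0706
#' @export
formula_mass <- function(formula, charge = 0) {
  if (!is.numeric(charge) || length(charge) != 1L || charge < 0 ||
      charge != round(charge))
    stop("'charge' must be a non-negative integer")
  counts <- if (is.numeric(formula)) {
    stopifnot(!is.null(names(formula)), all(names(formula) %in% names(.ATOMIC)))
    formula
  } else parse_formula(formula)
  neutral <- sum(counts * .ATOMIC[names(counts)])
  if (charge == 0) return(neutral)
  (neutral - charge * .ELECTRON) / charge
}

.residue_masses <- local({
  m <- vapply(.RESIDUE_FORMULA, function(f) formula_mass(f), numeric(1))
  names(m) <- names(.RESIDUE_FORMULA)
  m
})

#' Residue alphabet and monoisotopic chain masses
#'
#' @return Named numeric vector of monoisotopic residue (chain) masses for the
#'   20 standard amino acids plus `J`, the Ile/Leu ambiguity symbol
#'   (113.08406).
#' @export
residue_table <- function() .residue_masses

#' Monoisotopic residue mass
#'
#' @param code One-letter residue code (one of the 20 standard amino acids or
#'   `"J"` / `"I/L"` for the Ile/Leu-ambiguous residue).
#' @return Monoisotopic chain mass in Da.
#' @examples
#' residue_mass("G")  # 57.02146
#' residue_mass("J")  # 113.08406
#' @export
residue_mass <- function(code) {
  if (identical(code, "I/L")) code <- "J"
  if (!is.character(code) || length(code) != 1L || !code %in% names(.residue_masses))
    stop("unknown residue code '", code, "'; alphabet is ",
         paste(names(.residue_masses), collapse = ""))
  unname(.residue_masses[code])
}

#' Neutral monoisotopic mass of a peptide
#'
#' Sum of residue chain masses plus the terminal group: +H2O (18.01056) for a
#' free acid, +NH3 (17.02655) when the C-terminus is amidated. N-terminal and
#' per-residue modification deltas from the registry are applied additively.
#'
#' @param p A [peptide()] object.
#' @param registry Modification registry (defaults to [mod_registry()]).
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_neutral_mass(parse_peptide("AG"))          # 146.0691
#' peptide_neutral_mass(parse_peptide("Bz-ARF-NH2"))  # 495.2594
#' @export
peptide_neutral_mass <- function(p, registry = mod_registry()) {
  p <- as_peptide(p, registry)
  m <- sum(.residue_masses[p$residues])
  m <- m + if (identical(p$cterm, "amidation")) .MASS_NH3 else .MASS_H2O
  if (!is.na(p$nterm)) m <- m + .mod_delta(p$nterm, registry)
  if (length(p$residue_mods))
    for (nm in p$residue_mods) m <- m + .mod_delta(nm, registry)
  unname(m)
}

#' Precursor m/z of a peptide
#'
#' `(neutral mass + charge * 1.007276) / charge`.
#'
#' @inheritParams peptide_neutral_mass
#' @param charge Positive integer charge state.
#' @return m/z of the `[M + charge H]^charge+` ion.
#' @examples
#' precursor_mz(parse_peptide("KVIKMV"), 1)    # 717.4691
#' precursor_mz(parse_peptide("Bz-ARFG"), 1)   # 554.2721
#' @export
precursor_mz <- function(p, charge = 1, registry = mod_registry()) {
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1 ||
      charge != round(charge))
    stop("'charge' must be a positive integer")
  (peptide_neutral_mass(p, registry) + charge * .PROTON) / charge
}

#' Ion specification
#'
#' Describes one theoretical fragment ion of a peptide: series, cleavage
#' index, charge, optional neutral losses and (for w/d ions) the side-chain
#' loss mass.
#'
#' @param series One of `"a"`, `"b"`, `"c"`, `"y"`, `"z"` (the z-radical z
#'   dot), `"w"`, `"d"`, `"immonium"`, `"precursor"`.
#' @param index 1-based cleavage index counted from the series' own terminus
#'   (the residue position for `"immonium"`; ignored for `"precursor"`).
#' @param charge Positive integer.
#' @param neutral_losses Numeric vector of neutral-loss masses (Da) subtracted
#'   before charge scaling.
#' @param side_chain_loss Side-chain loss in Da; required for `"w"` (from z
#'   dot) and `"d"` (from a): 29.03913 evidences Ile, 43.05478 Leu.
#' @return An object of class `"ion_spec"`.
#' @export
ion <- function(series, index = 1L, charge = 1L, neutral_losses = numeric(0),
                side_chain_loss = NULL) {
  series <- match.arg(series,
    c("a", "b", "c", "y", "z", "w", "d", "immonium", "precursor"))
  if (charge < 1 || charge != round(charge)) stop("charge must be >= 1")
  if (series %in% c("w", "d") && is.null(side_chain_loss))
    stop(series, " ions require 'side_chain_loss'")
  structure(list(series = series, index = as.integer(index),
                 charge = as.integer(charge),
                 neutral_losses = neutral_losses,
                 side_chain_loss = side_chain_loss),
            class = "ion_spec")
}

#' Theoretical fragment m/z
#'
#' Singly-charged conventions: `b_i` = prefix residue masses + N-terminal
#' modification + proton; `a_i = b_i - CO`; `c_i = b_i + NH3`;
#' `y_j` = suffix residue masses + C-terminal contribution (H2O free acid,
#' NH3 amide) + proton; `z_j = y_j - 16.01872` (the z-radical);
#' `w_j = z_j - side_chain_loss`; `d_i = a_i - side_chain_loss`;
#' immonium = residue - CO + proton. Multiply-charged ions are
#' `(mz1 + (z - 1) * proton) / z`; neutral losses are subtracted from the
#' neutral fragment before protonation. Index `n` (full length) is admitted
#' for b/y: the `b_n` ion of an amidated peptide sits 17.02655 below
#' `[M + H]+`, a diagnostic this package relies on.
#'
#' @inheritParams peptide_neutral_mass
#' @param ionspec An [ion()] specification.
#' @return m/z in Da.
#' @examples
#' p <- parse_peptide("Bz-ARF-NH2")
#' fragment_mz(p, ion("b", 1))  # 176.0706, the benzoyl-Ala b1
#' fragment_mz(p, ion("y", 1))  # 165.1022, amidated Phe y1
#' @export
fragment_mz <- function(p, ionspec, registry = mod_registry()) {
  p <- as_peptide(p, registry)
  stopifnot(inherits(ionspec, "ion_spec"))
  n <- length(p$residues)
  i <- ionspec$index
  s <- ionspec$series
  if (s == "precursor")
    return(.scale_charge(peptide_neutral_mass(p, registry) + .PROTON -
                           sum(ionspec$neutral_losses), ionspec$charge))
  if (s == "immonium") {
    if (i < 1 || i > n) stop("immonium index out of range")
    mz1 <- .residue_masses[[p$residues[i]]] + .IMMONIUM_OFFSET -
      sum(ionspec$neutral_losses)
    return(.scale_charge(mz1, ionspec$charge))
  }
  maxidx <- if (s %in% c("b", "y")) n else n - 1L
  if (i < 1 || i > maxidx) stop(s, i, ": index out of range for length ", n)

  prefix_mods <- function(k) {
    m <- if (!is.na(p$nterm)) .mod_delta(p$nterm, registry) else 0
    if (length(p$residue_mods)) {
      pos <- as.integer(names(p$residue_mods))
      for (j in which(pos <= k)) m <- m + .mod_delta(p$residue_mods[[j]], registry)
    }
    m
  }
  suffix_mods <- function(k) {  # k residues from the C-terminus
    m <- 0
    if (length(p$residue_mods)) {
      pos <- as.integer(names(p$residue_mods))
      for (j in which(pos > n - k)) m <- m + .mod_delta(p$residue_mods[[j]], registry)
    }
    if (k == n && !is.na(p$nterm)) m <- m + .mod_delta(p$nterm, registry)
    m
  }

  neutral <- switch(s,
    b = , a = , c = , d = {
      frag <- sum(.residue_masses[p$residues[seq_len(i)]]) + prefix_mods(i)
      frag <- switch(s, b = frag, a = frag - .MASS_CO, c = frag + .MASS_NH3,
                     d = frag - .MASS_CO - ionspec$side_chain_loss)
      frag
    },
    y = , z = , w = {
      cterm <- if (identical(p$cterm, "amidation")) .MASS_NH3 else .MASS_H2O
      frag <- sum(.residue_masses[p$residues[seq.int(n - i + 1L, n)]]) +
        cterm + suffix_mods(i)
      frag <- switch(s, y = frag, z = frag - .MASS_NH2,
                     w = frag - .MASS_NH2 - ionspec$side_chain_loss)
      frag
    })
  mz1 <- neutral + .PROTON - sum(ionspec$neutral_losses)
  .scale_charge(mz1, ionspec$charge)
}

.scale_charge <- function(mz1, z) {
  if (z == 1) mz1 else (mz1 + (z - 1) * .PROTON) / z
}

#' Table of theoretical backbone fragment ions
#'
#' Convenience wrapper enumerating the b/y (optionally a) series of a peptide
#' at the given charges, including the `b_n` ion when the peptide is
#' amidated.
#'
#' @inheritParams peptide_neutral_mass
#' @param charges Integer vector of fragment charge states.
#' @param series Character vector among `"a"`, `"b"`, `"y"`.
#' @return `data.frame` with columns `series`, `index`, `charge`, `mz`.
#' @export
fragment_table <- function(p, charges = 1L, series = c("b", "y"),
                           registry = mod_registry()) {
  p <- as_peptide(p, registry)
  n <- length(p$residues)
  rows <- list()
  for (s in series) {
    idx <- seq_len(max(n - 1L, 0L))
    if (s == "b" && identical(p$cterm, "amidation")) idx <- c(idx, n)
    for (i in idx) for (z in charges)
      rows[[length(rows) + 1L]] <- data.frame(
        series = s, index = i, charge = z,
        mz = fragment_mz(p, ion(s, i, z), registry))
  }
  if (!length(rows))
    return(data.frame(series = character(), index = integer(),
                      charge = integer(), mz = numeric()))
  do.call(rbind, rows)
}

#' Explain an observed mass difference
#'
#' Ranks every single residue, modified residue, and terminal block (residue
#' or residue pair carrying an N-terminal modification) whose monoisotopic
#' mass lies within `tol` of `observed_delta`, by absolute error. This is the
#' arithmetic behind reading a 226.059 Da N-terminal gap as the
#' pyroGlu-Asp (pED) block.
#'
#' @param observed_delta Observed mass difference in Da.
#' @param tol Tolerance in Da (> 0).
#' @param registry Modification registry.
#' @return `data.frame` with columns `explanation`, `kind`
#'   (`residue`/`modified_residue`/`terminal_block`), `mass`, `error`,
#'   sorted by `abs(error)`.
#' @examples
#' mass_delta_match(113.084, 0.02)   # the I/L residue
#' mass_delta_match(226.059, 0.02)   # includes pE-D terminal block
#' @export
mass_delta_match <- function(observed_delta, tol = 0.02,
                             registry = mod_registry()) {
  if (!is.numeric(tol) || tol <= 0) stop("'tol' must be > 0")
  cand <- .delta_table(registry)
  cand$error <- cand$mass - observed_delta
  cand <- cand[abs(cand$error) <= tol, , drop = FALSE]
  cand <- cand[order(abs(cand$error)), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

# All single-residue, modified-residue and N-terminal-block masses the
# registry can explain; vectorized build, used by mass_delta_match and the
# spectrum-graph edge annotation.
.delta_table <- function(registry) {
  res <- .residue_masses[setdiff(names(.residue_masses), c("I", "L"))]
  expl <- names(res); kind <- rep("residue", length(res)); mass <- unname(res)
  reg <- registry[registry$enabled, , drop = FALSE]
  for (k in seq_len(nrow(reg))) {
    mod <- reg[k, ]
    if (mod$target == "residue") {
      expl <- c(expl, paste0(mod$residue, "(", mod$name, ")"))
      kind <- c(kind, "modified_residue")
      mass <- c(mass, .residue_masses[[mod$residue]] + mod$delta)
    } else if (mod$target == "N-term") {
      first <- if (nzchar(mod$residue)) mod$residue else names(res)
      one <- paste0(mod$name, "-", first)
      m1 <- unname(res[first]) + mod$delta
      grid <- expand.grid(r2 = names(res), r1 = first,
                          stringsAsFactors = FALSE)
      two <- paste0(mod$name, "-", grid$r1, grid$r2)
      m2 <- unname(res[grid$r1] + res[grid$r2]) + mod$delta
      expl <- c(expl, one, two)
      kind <- c(kind, rep("terminal_block", length(one) + length(two)))
      mass <- c(mass, m1, m2)
    }
  }
  data.frame(explanation = expl, kind = kind, mass = mass,
             stringsAsFactors = FALSE)
}
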