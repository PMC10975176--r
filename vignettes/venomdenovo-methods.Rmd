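---
title: "Methods: de novo identification of short venom peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: de novo identification of short venom peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomdenovo)
```

## The problem

Scorpion venom contains, besides its well-studied disulfide-bridged toxins,
a population of very short peptides (2–12 residues) that carry unusual
terminal chemistry: N-terminal benzoylation and carboxybenzoylation,
N-terminal pyroglutamate, C-terminal amidation, and methionine oxidation.
These peptides are too short for database search to be reliable, so their
sequences must be read directly off tandem mass spectra: successive b- and
y-ion mass differences spell the residues, terminal mass offsets reveal the
modifications, and dedicated MS³ experiments separate the isobaric residues
Ile and Leu. This package implements that workflow end to end, together
with a ground-truthed spectrum simulator, so that every stage is testable
without access to raw venom data.

## Mass conventions

All arithmetic is monoisotopic over CHNOS, built from atomic masses at
full double precision (values are reported rounded to 4 decimals). The
conventions, chosen once and used consistently by the simulator, the
sequencer and the resolvers:

* proton 1.007276 Da, electron 0.000549 Da; cation m/z from an elemental
  formula subtracts the electron mass, while peptide/fragment m/z uses the
  proton-addition form `(M + z·1.007276)/z`;
* `b_i` = prefix residues + N-terminal modification + proton;
  `a = b − CO`; `c = b + NH3`;
* `y_j` = suffix residues + terminal group (H₂O free acid, NH₃ amide) +
  proton; the z-radical `z• = y − 16.0187`;
* `w = z• − side-chain loss` with 29.0391 (ethyl, Ile) or 43.0548
  (isopropyl, Leu); `d = a − side-chain loss`. The z-ion convention is
  immaterial to I/L discrimination because only the z→w difference enters
  the rule;
* the Ile/Leu immonium cation is residue − CO + proton = 86.0964, and its
  NH₃ loss is 69.0699 — the nominal 86/69 pair;
* `b_n` (index = peptide length) is admitted for b ions: for an amidated
  peptide it sits exactly one NH₃ (17.0265) below `[M+H]⁺`, which is the
  operative amide diagnostic.

The modification registry is a plain-text table (name, target, signed
elemental formula, diagnostic precursor neutral losses). Pyroglutamate is
registered from Glu (−H₂O); a Gln-derived variant (−NH₃) is included but
disabled by default, because the two cannot be separated by mass and the
observed N-terminal block arithmetic (e.g. the 226.059 Da pE-Asp block,
18.011 below Glu-Asp) is consistent with the Glu route. Carboxybenzoyl is
stored as +C₈H₄O₃ without fixing the carboxyl position on the ring, which
does not affect mass.

## Spectrum-graph sequencing

Each MS² peak is interpreted twice: as a b-ion (prefix mass = peak −
proton) and as a y-ion (prefix = precursor-derived neutral mass − peak +
proton). Interpreted prefix values closer than half the fragment tolerance
are merged (mean); anchors 0 and the neutral mass are always present.

Candidates are enumerated by depth-first search from the N-terminal
anchor. The search tracks the *exact* cumulative residue mass and requires
each intermediate prefix to lie within the fragment tolerance (default
0.02 Da) of a node — pointwise anchoring rather than edge-difference
chaining, so matching errors cannot accumulate along a path. Steps are:

* a single residue from the 19 mass-distinct residues (I/L collapsed into
  the ambiguity residue `J`, emitted as `I/L`), plus oxidized Met when the
  registry enables it;
* leaving the anchor: a registered modified terminal block — modification
  + first residue (benzoyl-Ala is the canonical example), or modification
  + two residues for residue-anchored modifications such as pyroglutamate
  (covering the common case where the pE b₁ is unobserved);
* a plain two-residue first step landing on a supported second prefix.
  This mirrors the completion rule below: the first cleavage site of an
  unmodified peptide is evidenced only by `y_{n−1}` (b₁ is suppressed in
  low-energy CID of free amines), so its loss would otherwise make the
  true sequence unreachable;
* completion: the final one or two residues plus the C-terminal group,
  evaluated under both the free-acid and the amide hypothesis.

The search is capped at 50,000 partial paths. The cap was sized so that
12-residue ladders — whose doubly-interpreted peaks generate many spurious
branch points — are explored exhaustively in well under a second; a much
smaller cap silently truncates long searches and costs recovery. If no
candidate explains the spectrum well (best site coverage below 0.75), the
search is additionally run allowing one unexplained N-terminal mass
offset, which is carried on the candidate and can be decomposed into
CHNOS formulas by
`open_terminal_offset()` (bounds C≤15, H≤25, N≤3, O≤6, S≤1; ring-plus-
double-bond equivalent ≥ 0).

### Scoring and ranking

`score = coverage + λ · Σ(relative intensity of matched peaks)` with λ =
0.1, where coverage is the fraction of the n−1 cleavage sites supported by
at least one matched b/y ion (1+ and, for 2+ precursors, 2+). The minimum
coverage to report a candidate defaults to 0.5 — the literature-style
requirement of a "diverse array" of sequence ions made operational; it is
a configuration knob.

Ranking is by score, then mean absolute matching error, then parsimony
(fewer residues, then fewer modifications), then lexicographic order.
The error criterion separates candidates that are *near*-isobaric within
the tolerance (carboxybenzoyl-Ser vs benzoyl-Met blocks differ by 19 mDa;
Asn vs Gly-Gly by 11 µDa is below it, see degeneracies). Ranking keys are
quantized (score to 1e-9, error to 1e-7 Da) before comparison so that
last-ulp floating-point differences between chemically identical
candidates cannot override the parsimony rules. All keys are
deterministic, so permuting input peaks never changes the output.

### Genuine degeneracies

Some confusions are not resolvable by any mass measurement:

* a C-terminal amidated Glu and a C-terminal free-acid Gln have identical
  elemental composition — every fragment coincides exactly. The parsimony
  rule reports the unmodified (Gln) reading;
* Gln vs Gly+Ala and Asn vs Gly+Gly differ by ~1e-5 Da; when the extra
  cleavage site of the two-residue reading happens to be supported by a
  coincidental peak, the readings tie and parsimony (fewer residues)
  prefers the single residue;
* the order of the first two residues of an unmodified peptide is
  undecidable when `y_{n−1}` is missing (b₁ suppressed), as is the order
  of the final two when `y₁`/`b_{n−1}` are missing.

## The simulator and what it does (not) emulate

`simulate_ms2()` emits the b/y ladder (a-ions optional; 2+ fragment copies
for 2+ precursors), with b₁ only for N-acylated peptides and `b_n` for
amidated ones; the registry's diagnostic precursor losses (CO₂ and
CO₂+H₂O for carboxybenzoyl); Gaussian ppm mass error; per-ion dropout; and
uniform noise peaks. Intensities follow a rank-decay model (y > b > a);
no claim of fidelity to real fragmentation propensities is made — the
scorer uses intensities only as a soft bonus, never as evidence.
`simulate_etd_ms3()` produces the z-ion ladder plus the site's w-ion;
`simulate_immonium_ms3()` the 86-Da base peak with a 69-Da ion at 40%
(Ile) or 3% (Leu) relative abundance — Ile defaults chosen as a clearly
"significant" abundance, Leu under the 10% bound reported for it.
Everything is seeded and reproducible.

Not emulated: isotope envelopes, co-isolation chimeras, retention time,
intensity physics, charge states above 2+. Passing benchmarks therefore
demonstrates the correctness of the inference logic under controlled
error/dropout/noise, not instrument-grade performance on real venom data.

The benchmark generator draws lengths uniformly on 2–12, residues
uniformly from the 20-residue alphabet, and applies the five modification
classes independently at 10% frequency each (N-terminal classes mutually
exclusive; a drawn pyroglutamate forces Glu at position 1, and a drawn
oxidation forces one Met so that the nominal modification frequency is
honored). Precursor charge is 1+ up to five residues, 2+ above, matching
the low charge capacity of such short peptides. The acceptance benchmark
uses 200 records under two conditions: clean (no error, full detection)
and degraded (5 ppm error, 90% per-ion detection); 200 records keeps the
full two-condition run around four minutes on one core while leaving the
binomial noise on recovery rates near one percentage point.

## Terminal-modification inference

Evidence is counted in ions, with the precursor match itself counting as
one supporting ion: two or more ions give a `confirmed` verdict, exactly
one `suggested`, none `absent`. For amidation the fragments tested are the
amide-shifted y-series (−0.984 Da) and `b_n` at `[M+H]⁺` − 17.0265. For
each N-terminal modification the tested ions are the acylated b₁, its a₁
companion (b₁ − CO), the two-residue N-terminal block as b₂, and the
modification's diagnostic precursor losses — which are *mandatory* for
confirmation when declared (carboxybenzoyl without its CO₂ and CO₂+H₂O
losses is never confirmed). Oxidized Met is detected from the +15.995
shift of the fragments covering the site.

## I/L resolution

The w-ion rule calls Ile on a 29.039 Da loss and Leu on a 43.055 Da loss
from the z-ion covering the site (`z_{n−site+1}`). Because w-ions of very
short peptides are prone to hydrogen-abstraction artifacts, the covering
z-ion itself must be observed before a w-ion is accepted; conflicting or
missing losses leave the site ambiguous. The immonium rule compares the
69/86 relative abundance with a single 10% threshold, *inclusive* for Ile
(an abundance of exactly 10% calls Ile), since Leu is defined by "below
10%". External search-engine identifications only ever fill positions that
are ambiguous after the spectral methods, and method precedence is fixed:
w-ion > immonium > external, with disagreement downgrading to ambiguous.

## Families and annotation

Family edges encode venom maturation steps: single-residue terminal
truncation (carboxypeptidase/aminopeptidase), C-terminal Gly conversion to
an amide (the PHM/PAL two-step route, mass change 58.0055 Da), and Met
oxidation. Multi-residue truncations are represented as ladders of single
steps when the intermediates were observed, never as long-range edges; the
longer (or unoxidized) peptide is always the parent. Bioactivity
annotation expands every I/L-ambiguous query into its concrete variants
and looks each up in packaged plain-text fixture tables transcribed from
literature database reports (AHTPDB and BIOPEP entries for ten
ACE-inhibitory dipeptides); the external PeptideRanker score is carried
through from the fixture and never computed.

## Verification strategy

Beyond unit tests, two oracle-style checks anchor the implementation:

* *Additivity and complementarity*: peptide and fragment masses are
  compared against an independently transcribed residue-mass table, and
  `b_i + y_{n−i} = [M+H]⁺ + proton` is asserted for random peptides at
  1e-6 Da.
* *Enumeration equivalence*: on clean ladders of peptides up to length 4,
  spectrum-graph enumeration must equal an exhaustive generate-and-test
  oracle that scans all sequences and accepts on precursor match plus the
  same site-support rule (first site may be skipped by a two-residue first
  step, last site by a two-residue completion). This comparison is run
  with the free-acid hypothesis and an empty modification registry on both
  sides; the canonical micro-example is precursor-neutral 146.0691, whose
  admissible reading set is exactly {AG, GA, Q} — adding the amide
  hypothesis would also admit Glu-NH₂, which is elementally identical to
  Gln.

## Known limitations

* All inference is mass-based at 0.02 Da fragment tolerance; K/Q
  (Δ 36 mDa) and F/M(ox) (Δ 33 mDa) separate at that tolerance, but the
  exact degeneracies above are intrinsic.
* The pipeline handles charge states 1–2 (unknown charge tries both),
  which covers peptides of this size class.
* PeptideRanker scores and live database queries are out of scope by
  design; fixtures are transcriptions, not services.
* The simulator's intensity model is a stand-in; recovery rates quoted on
  synthetic benchmarks should not be read as real-data performance.
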