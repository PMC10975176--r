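# venomdenovo

De novo identification of very short peptides (2–12 residues) from tandem
mass spectra, built for the short-peptide fraction of scorpion venom:
non-disulfide-bridged peptides carrying unusual terminal chemistry such as
N-terminal benzoylation and carboxybenzoylation, N-terminal pyroglutamate,
C-terminal amidation, and methionine oxidation. The package is aimed at
peptidomics analysts who need sequence and modification calls for peptides
too short for database search to be reliable.

## What it does

* **Exact monoisotopic mass arithmetic** for residues, elemental formulas,
  modifications, precursors and the a/b/c/y/z•/w/d/immonium fragment
  series, at the conventions spelled out in the methods vignette
  (`b_i` = prefix + N-mod + 1.00728; `y_j` = suffix + H₂O or NH₃ + 1.00728;
  `z• = y − 16.0187`; `w = z•` minus a 29.0391/43.0548 side-chain loss).
* **MGF reading/writing** with an MSⁿ dialect (`MSLEVEL`, `ACTIVATION`,
  `PARENT` keys) carrying MS³ provenance, and peak↔ion matching at a
  configurable tolerance (default 0.02 Da).
* **Spectrum-graph de novo sequencing**: every peak is read both as a
  b-ion and as a y-ion, prefix-mass nodes are linked by residue and
  registered terminal-block mass differences, and full paths from 0 to the
  precursor-derived neutral mass are scored by cleavage-site coverage plus
  an intensity bonus. Ile/Leu positions are reported as `I/L`.
* **Terminal PTM inference** from diagnostic ions: the acylated b₁/a₁ pair
  and the two-residue N-terminal block for benzoyl/carboxybenzoyl/pyro-Glu
  (carboxybenzoyl additionally requires its CO₂ and CO₂+H₂O precursor
  losses), and the amide-shifted y-series plus the `b_n` ion 17.0265 below
  `[M+H]⁺` for C-terminal amidation. Unexplained terminal offsets are
  decomposed into CHNOS formulas.
* **I/L resolution** from ETD MS³ w-ions (loss of 29.039 Da → Ile,
  43.055 Da → Leu off the covering z•-ion) and HCD MS³ immonium spectra
  (69/86 relative abundance, 10% threshold, inclusive for Ile), with
  optional reconciliation against exported search-engine identifications.
* **Family reconstruction** (single-residue truncations, the
  PHM/PAL Gly→amide conversion at +58.0055 Da, Met oxidation) and
  **dipeptide bioactivity annotation** from packaged AHTPDB/BIOPEP fixture
  tables, expanding I/L-ambiguous queries before lookup.
* A **seeded synthetic-spectrum generator** producing ground-truthed MS²
  b/y ladders, ETD MS³ w-ion spectra and immonium MS³ spectra with
  configurable ppm error, ion dropout and noise — the benchmark substrate
  for every stage.

## Worked example

```r
library(venomdenovo)

p <- parse_peptide("Bz-ARF-NH2")     # benzoylated, amidated tripeptide
peptide_neutral_mass(p)              # 495.2594
precursor_mz(p, 1)                   # 496.2667
fragment_mz(p, ion("b", 1))          # 176.0706  (benzoyl-Ala b1)
fragment_mz(p, ion("y", 1))          # 165.1022  (amidated Phe y1)

# simulate its clean CID MS2 spectrum and sequence it back
s <- simulate_ms2(p, sim_params(mass_error_sd = 0, seed = 7))
denovo(s)$table[1, c("sequence", "score", "coverage")]
#     sequence score coverage
# 1 Bz-ARF-NH2  1.35        1

# confirm the terminal chemistry from the diagnostic ions
sapply(detect_ptms(p, s), `[[`, "verdict")
#        benzoyl carboxybenzoyl  pyroglutamate      amidation      oxidation
#    "confirmed"       "absent"       "absent"    "confirmed"       "absent"

# resolve an I/L site from an ETD MS3 spectrum
q <- parse_peptide("KVI/LKMV")
ms3 <- simulate_etd_ms3(q, site = 3, truth = "I",
                        sim_params(mass_error_sd = 0, seed = 7))
call_il_from_wd(ms3, q, site = 3)
# <il_call> position 3: I (wd_ion)     # w4 = z4 - 29.039

# maturation family and dipeptide bioactivity
print(find_families(list("Bz-ARFG", "Bz-ARF", "Bz-ARF-NH2"))[[1]])
# <peptide_family> Bz-ARFG, Bz-ARF, Bz-ARF-NH2
#   Bz-ARFG -> Bz-ARF  [C-terminal truncation, -57.0215 Da]
#   Bz-ARFG -> Bz-ARF-NH2  [Gly-to-amide, -58.0055 Da]
annotate_activity(list("FR"))[[1]]$activities
#           source                            label
# 1 AHTPDB-fixture                    ACE inhibitor
# 2 BIOPEP-fixture                    ACE inhibitor
# 3 BIOPEP-fixture dipeptidyl peptidase IV inhibitor
```

The numbers above mean: the modified tripeptide's singly-protonated mass
is 496.2667; its benzoyl group announces itself as the 176.07 b₁ cation
and its amide as a y₁ at 165.10 (0.98 Da below the free-acid value); the
sequencer reads the full ladder back with complete site coverage; and the
FR dipeptide is annotated as an angiotensin-converting-enzyme inhibitor by
both fixture sources.

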