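Package: venomdenovo
Title: De Novo Sequencing and Annotation of Short Venom Peptides from Tandem Mass Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying very short (2-12 residue) peptides, such as
    the non-disulfide-bridged peptides of scorpion venom, from centroided
    tandem mass spectra. Implements exact monoisotopic mass arithmetic for
    residues, modifications and fragment ions; reading and writing of Mascot
    Generic Format (MGF) peak lists with MSn provenance; spectrum-graph de
    novo sequence enumeration from b/y ion ladders; inference of N- and
    C-terminal post-translational modifications (benzoylation,
    carboxybenzoylation, pyroglutamate formation, amidation) from diagnostic
    ions and neutral losses; isoleucine/leucine discrimination from ETD w-ion
    and HCD immonium MS3 spectra; reconstruction of truncation/amidation
    peptide families; and dipeptide bioactivity annotation from packaged
    lookup tables. A seeded synthetic-spectrum generator provides
    ground-truthed benchmarks for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
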