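Package: pepscreen
Title: Bioactive Peptide Census and In Silico Anti-Diabetic Screening for
    Food Peptidomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining cheese (and other food) peptidomes for
    anti-diabetic peptides. Maps identified peptides onto their mature
    casein precursors, annotates them against a reference table of
    previously reported bioactive peptides, computes cross-sample
    occurrence statistics over ripening time (Venn partitions, shared-core
    fractions, precursor incidence), and runs an in silico
    candidate-selection cascade: bioactivity-score and length filters,
    docking significance, structure-activity consensus rules for DPP-IV
    and alpha-glucosidase inhibitors, and gastro-intestinal stability
    under a protease cleavage-rule engine. Also provides log-linear IC50
    estimation from dose-response inhibition assays, a serving-size
    intestinal-dilution model, and seeded synthetic-data generators for
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
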