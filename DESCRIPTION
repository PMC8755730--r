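Package: glycobrain
Title: MALDI-TOF Glycomics of the Mammalian Brain: Annotation, Classification and Regional Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing permethylated N- and O-glycan MALDI-TOF
    peak lists from brain tissue. Computes theoretical monoisotopic masses of
    permethylated sodiated glycans from monosaccharide compositions, parses a
    compact structure nomenclature, classifies N-glycans into paucimannose,
    high-mannose, antennary, hybrid and bisected categories and O-glycans into
    O-GalNAc and O-mannose core types, annotates centroided peak lists against
    a structure library with a signal-to-noise filter, infers endoglycosidase H
    sensitivity from differential-digestion experiments, enumerates glycosidic
    B/Y fragment ions for MS/MS isomer ranking, and compares relative
    abundances across brain regions and sexes with one-way ANOVA, Welch t-tests
    and simple regression. A seeded synthetic-spectrum generator emulates the
    acquisition process so the whole pipeline is testable without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
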