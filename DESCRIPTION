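Package: sbaselect
Title: Antibody Selectivity Analysis for Multiplexed Suspension Bead Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for antibody selectivity screening on
    multiplexed suspension bead arrays (SBA) against overexpressed,
    solubilized membrane-protein lysates. Takes raw median fluorescence
    intensity (MFI) and bead-count tables through quality control,
    mock-contrasted expression assessment (ANOVA with Dunnett contrasts),
    per-antibody robust Z-scoring with a data-driven density-peak threshold,
    four-class selectivity annotation (on-, co-, off-, no-target),
    cross-reactivity deconvolution by relative abundance and local-alignment
    E-values, paired-antibody agreement, and antigen feature analysis on
    predicted structures (pLDDT, Shrake-Rupley solvent accessibility,
    dihedral secondary structure). Includes a synthetic-data generator with
    a ground-truth ledger so every stage is testable without assay data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    Biostrings,
    multcomp,
    bio3d,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
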