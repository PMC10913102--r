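Package: taxoproteo
Title: Taxonomic Proteotyping of Microbial Isolates by Cascade Database Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the taxonomic identity of a microbial isolate from its
    shotgun tandem-mass-spectrometry peptidome. Reference proteomes are
    digested in silico with trypsin into a peptide-to-organism index; observed
    spectra (or externally produced peptide-to-spectrum matches) are searched
    in a three-step cascade with progressively reduced databases and stricter
    validation thresholds; taxon-to-spectrum matches (TSMs) and taxon-specific
    peptides (spePEPs) are accumulated per taxonomic rank; a deterministic
    caller reports the deepest confident rank together with novelty flags
    (potential new species or genus); and proteotyping calls are reconciled
    with 16S rRNA percent-identity classifications under the standard species
    delineation thresholds. A seeded simulator generates reference taxonomies,
    proteomes and peptidomes with realistic peptide-sharing structure so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    data.table (>= 1.14),
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
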