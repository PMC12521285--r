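Package: ssbondmap
Title: Mapping Disulfide Bonds from Bottom-Up Proteomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for locating intra- and intermolecular disulfide bonds in
    proteins from bottom-up liquid chromatography tandem mass spectrometry
    experiments. The package performs in-silico proteolytic digestion with
    missed cleavages and optional chymotryptic-like non-specific activity,
    enumerates candidate disulfide-linked peptidoforms (loop-linked,
    intra-protein and inter-protein species) with full variable-modification
    combinatorics, matches candidates to precursor observations at
    parts-per-million tolerance, annotates tandem mass spectra with
    bridge-aware b/y fragment ions including disulfide-specific cleavage
    variants, and compares relative abundances of bridged versus
    carboxyamidomethylated cysteine forms. A deterministic synthetic-spectrum
    generator with planted ground truth makes every pipeline stage testable
    without raw instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
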