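Package: propalin
Title: Sequence and Structural Survey of Peptide Palindromes in Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects peptide palindromes (PALINs) of pentapeptide length and
    larger in protein chains and annotates them with structure-derived
    properties: DSSP-style secondary structure assigned from hydrogen-bonding
    patterns, Shrake-Rupley solvent-accessible surface area, counted-once
    residue neighborhood contacts at a 3.2 Angstrom cutoff, Kyte-Doolittle
    hydropathy, functional-interaction flags (ligand, metal, annotated site,
    disulphide), position frequency matrices and consensus sequences,
    occurrence modes (nested, overlapping, consecutive, repeated, chameleon),
    protein-family aggregation, and Kabsch superposition of identical
    palindromes from different structures. Includes a synthetic-data module
    that plants palindromes in random background sequences and builds
    ideal-geometry peptide structures as valid PDB files, so the whole
    pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    graphics,
    seqinr,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
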