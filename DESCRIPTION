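Package: qtyshift
Title: Water-Solubilization of Membrane Proteins by the QTY Code
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Designs water-soluble variants of multi-pass membrane proteins
    (such as solute-carrier transporters) by the QTY code, which replaces the
    hydrophobic residues leucine, isoleucine, valine and phenylalanine inside
    annotated transmembrane helices with the neutral-polar residues glutamine,
    threonine and tyrosine. Computes the sequence-level consequences
    (substitution ledger, transmembrane and overall variation percentages,
    average molecular weight, Bjellqvist isoelectric point), superposes native
    and variant alpha-carbon models by the Kabsch algorithm with iterative
    outlier rejection, and quantifies the surface-hydrophobicity reduction via
    a coarse Shrake-Rupley solvent-accessible surface area and a
    hydropathy-weighted surface index. Includes a deterministic synthetic-data
    generator (transmembrane-architecture sequences, ideal helical traces,
    rigid-transformed noisy decoys with known ground truth) so the whole
    pipeline runs and is verified offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr,
    jsonlite,
    yaml
Config/testthat/edition: 3
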