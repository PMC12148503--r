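Package: cystinescan
Title: Disulfide Geometry, Torsion Strain and Rotamer Accessibility Scans
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing why some interchain disulfide bonds form
    infrequently in TGF-beta family growth-factor dimers. Reads PDB/mmCIF
    atomic models, extracts the cystine dihedral quintet (chi1, chi2, chi3,
    chi2', chi1'), scores torsion strain with classic AMBER cosine terms,
    builds background dihedral distributions from structure collections,
    and performs a chi1-sweep virtual-sulfur accessibility scan that places
    sulfur atoms on the geometric cone of each opposing free cysteine,
    removes sterically clashing rotamers, and decides whether any
    clash-free rotamer pair brings the two sulfurs within disulfide
    bonding distance. Includes a synthetic-structure generator (ideal
    cysteines, C2-symmetric dimers, clash probes, wrapped-normal dihedral
    ensembles) so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
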