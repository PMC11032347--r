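Package: pocketome
Title: Pocket-Centric Curation, Detection and Comparison of
    Protein-Protein Interaction Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for building pocket-centric datasets of
    protein-protein interactions (PPIs) and PPI-related ligand binding
    sites.  Curates heterodimer and protein-ligand structures with
    experimental-quality and ligand drug-likeness filters, detects
    binding pockets on a cubic grid with ray-cast buriedness scoring
    and pharmacophoric probe typing, classifies liganded pockets as
    orthosteric-competitive, orthosteric-non-competitive or allosteric
    relative to the partner epitope, computes a 109-component pocket
    descriptor vector, derives a Gaussian-kernel Pocket Similarity
    Index (PSI) from standardized descriptor distances, and organises
    the resulting pocketome as a minimum spanning tree with annotated
    GraphML and self-contained HTML exports.  Includes deterministic
    synthetic fixture generators (toy heterodimers, liganded monomers,
    planted descriptor samples) so the full pipeline can be exercised
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
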