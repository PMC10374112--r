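Package: hexcomb
Title: Geometric Analysis of Size-Dimorphic Comb Lattices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing how honey bees and social wasps join small
    worker cells and large reproductive cells within a single hexagonal
    lattice. Reconstructs cell polygons, wall counts and neighbour graphs
    from cell-centre coordinates via the Voronoi/Delaunay duality; generates
    synthetic combs (two triangular-lattice patches of different pitch merged
    along a straight transition line, one-step or through layers of
    intermediate-sized cells, with positional jitter); implements the
    closed-form theory of 5-7 topological defect pairs forced by cell-size
    dimorphism; fits a four-parameter plateau-ramp-plateau transition profile
    and estimates the number of transition layers and the effective residual
    dimorphism; compares four candidate defect-rate models by
    predicted-versus-observed regression; and fits phylogenetic generalized
    least squares with maximum-likelihood Pagel's lambda on species-level
    summaries over a time-calibrated tree.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deldir,
    jsonlite,
    ape,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    nlme,
    withr
Config/testthat/edition: 3
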