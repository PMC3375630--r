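Package: patchsurf
Title: Patch-Based Comparison and Retrieval of Ligand-Binding Pockets
Version: 0.1.0
Authors@R:
    person("patchsurf", "developers", email = "patchsurf@example.org",
           role = c("aut", "cre"))
Description: Represents protein ligand-binding pockets as sets of surface
    patches anchored to ligand heavy atoms, encodes the shape,
    electrostatic potential, hydrophobicity and concaveness of each patch
    as rotation-invariant 3D Zernike descriptors, and retrieves similar
    pockets from a descriptor database by weighted thresholded bipartite
    patch matching. Includes the pocket-database construction filters
    (heavy-atom count, ligand grouping, covalent and contact distance
    rules), binding-ligand prediction by rank aggregation, enrichment
    factor evaluation of ranked retrieval, and a deterministic generator
    of synthetic protein-ligand complexes for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
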