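Package: kporphyrin
Title: Tautomer Enumeration and Redox/Spectral Analysis of the DHI Porphyrin-Type Tetramer
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Combinatorial and thermodynamic analysis of the porphyrin-type
    cyclotetramer of 5,6-dihydroxyindole (DHI), a theoretical structural model
    for eumelanin pigments. Enumerates all closed-shell tautomers at each
    oxidation level by perfect-matching (Kekule structure) feasibility on the
    44-atom molecular graph, with deduplication under the cyclic symmetry of
    the 2,7'-linked macrocycle; detects macrocyclic conjugation circuits,
    counts their pi electrons and applies the Hueckel 4n+2 rule; post-processes
    quantum-chemistry summary records into relative stabilities, Boltzmann
    weights, pKa estimates by reference comparison, balanced disproportionation
    free energies and HOMO-LUMO gaps; and synthesizes broadened UV-Vis and IR
    spectra from transition and harmonic-mode lists. A synthetic-data module
    generates fully structured species records so that every downstream stage
    is testable without electronic-structure calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    graphics
Suggests:
    withr,
    testthat (>= 3.0.0),
    ChemmineR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
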