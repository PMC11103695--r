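Package: origamiCT
Title: Decoherent Charge Transport in DNA Origami and Duplex Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Green's-function charge-transport analysis of DNA duplexes and
    two-helix DNA origami from annotated Hamiltonian/overlap matrices.
    Implements Loewdin symmetric orthogonalization, per-atom block
    diagonalization into atomic molecular orbitals, Buettiker-probe
    decoherent transmission with floating probe potentials, per-atom density
    of states with base/strand/helix/region aggregation, orbital-localization
    profiles, and terminal-base contact-scheme conductance comparisons.
    Ships a tight-binding generator of annotated duplex and one-crossover
    origami systems (C1/C2 conformational variants) so the whole pipeline is
    testable without quantum-chemistry output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    rhdf5,
    jsonlite
Config/testthat/edition: 3
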