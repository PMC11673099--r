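Package: microdft
Title: Desk-Scale Gaussian-Basis Restricted Kohn-Sham DFT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: A compact, fully testable restricted Kohn-Sham density
    functional theory engine over contracted Gaussian basis sets.
    Implements McMurchie-Davidson one- and two-electron integrals with
    Cauchy-Schwarz screening and a three-rule mixed-precision dispatcher,
    block-sparse exchange-correlation quadrature on atom-centred
    Becke-partitioned grids, DIIS-accelerated SCF, and a five-task
    front end (single-point energy, forces, seminumerical Hessian,
    geometry optimisation, Born-Oppenheimer molecular dynamics) with
    QCSchema-style JSON input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
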