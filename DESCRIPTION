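Package: diagramflux
Title: Exact Steady-State Observables of Kinetic Diagrams by the Diagram Method
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the diagram method of King, Altman and Hill for
    discrete-state kinetic networks. From a user-defined kinetic diagram
    (states connected by reversible transitions with symbolic rate
    constants) the package enumerates partial diagrams (spanning trees),
    directional diagrams and flux diagrams, and assembles exact symbolic
    expressions for steady-state state probabilities, net cycle fluxes,
    net transition fluxes and operational fluxes. Expressions are sparse
    multilinear polynomials over the rate symbols and support parameter
    substitution, exact equality proofs and compilation to fast numeric
    evaluators. Numerical steady-state solvers (linear algebra and
    matrix-exponential integration of the master equations), a
    detailed-balance random rate generator for validation, and fixture
    builders for membrane-transporter case studies (a 4-state antiporter,
    a 6-state sodium/proton antiporter with a leak transition, and the
    8-state free-exchange model of the multidrug transporter EmrE) are
    included, together with a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
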