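Package: loopdimer
Title: Structural and Biophysical Analysis of Interface Loops in
        Homodimeric Enzymes
Version: 0.1.0
Authors@R: person("Package", "Author", email =
        "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the structural comparison of homodimeric enzyme crystal
 structures, built around the analyses commonly applied to cold-active
 alkaline phosphatases: least-squares (Kabsch) superposition of residue-matched
 monomers with per-residue C-alpha deviation traces, crystallographic B-factor
 aggregation, max-normalization and differential flexibility calls, distance-based
 enumeration of hydrogen bonds, salt bridges and water-mediated bridges at dimer
 interfaces, and thermal-stability analytics (Arrhenius inactivation fits with
 derived T50%, two-state melting-curve fits, Michaelis-Menten kinetics).  A
 synthetic dimer generator plants known displacements, B-factor profiles and
 polar contacts so the whole pipeline is testable without any structure download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports: bio3d,
 jsonlite,
 minpack.lm,
 stats,
 utils
Suggests: optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
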