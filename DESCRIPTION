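Package: aortaflow
Title: Immersed-Boundary Hemodynamics of Aortic-Stenosis Jet Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale computational hemodynamics for aortic stenosis: an
    incompressible Navier-Stokes solver on a Cartesian grid with a
    sharp-interface immersed boundary derived from a signed-distance map,
    echo-derived plug-jet inflow, and a two-element Windkessel outflow
    pressure model. Includes a procedural idealized (candy-cane) aorta,
    ingestion of binary segmentation masks, wall shear stress and wall
    pressure post-processing, circumferential band unwrapping, probe
    pressure traces, and metrics separating focal (dilation-associated)
    from dispersed wall-load patterns.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
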