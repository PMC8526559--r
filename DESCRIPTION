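Package: stethosim
Title: Simulation and Classification of Aortic Valve Heart Sounds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for studying how aortic valve function
    shapes the sounds recorded on the chest wall. A reduced
    degree-of-freedom model drives the three valve leaflets with a lumped
    displacement ODE, a surrogate source model paints turbulent pressure
    fluctuations, ejection clicks and closure (S2) impulses onto the
    aorta lumen boundary, and the free-space elastodynamic Green's tensor
    for a Kelvin-Voigt viscoelastic medium propagates those sources to an
    epidermal monitor point as surface acceleration. A PCA plus Fisher
    linear discriminant stack then detects anomalous (stenotic) valve
    function from the simulated phonocardiograms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
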