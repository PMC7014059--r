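Package: implantflow
Title: Two-Phase Blood Flow and Fibrinogen Transport Around Threaded Dental Implants
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finite-volume simulator of whole blood (plasma and red-blood-cell
    phases) infiltrating the interfacial zone of a threaded dental implant.
    Couples an incompressible variable-property projection solver with
    volume-of-fluid interface capturing, continuum-surface-force surface
    tension with a wall contact angle on the implant surface, and
    advection-diffusion transport of dissolved fibrinogen with a
    concentration-dependent plasma viscosity. Includes analytic verification
    benchmarks (plane Poiseuille flow, Gaussian diffusion, static and sessile
    droplets), infiltration metrics and stage summaries, contact-angle sweep
    orchestration, and CSV/VTK/PNG exporters.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
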