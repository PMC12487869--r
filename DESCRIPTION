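Package: petkin
Title: Compartment-Model Quantification of PET Radiotracer Kinetics
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracer-kinetic quantification of dynamic PET studies with
    arterial blood sampling. Builds metabolite-corrected plasma input
    functions from discrete blood samples (sum-of-exponentials plasma fit,
    integrated-gamma parent-fraction model), fits one- and two-tissue
    compartment models with blood-volume and time-delay terms by weighted
    nonlinear least squares, selects models by F-test, Akaike information
    criterion and parameter reliability, estimates drug occupancy and the
    nondisplaceable distribution volume from Lassen plots, compares
    radiotracers with Guo plots, and quantifies scan-shortening and
    rest-period bias by truncated refits. Includes a synthetic-study
    generator with known ground truth for validation of every stage.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
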