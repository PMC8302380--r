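Package: deerhunt
Title: Balanced Deer Hunting Optimization and Texture-Based Tumor Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Deer Hunting Optimization Algorithm (DHOA) and its
    Levy-flight Balanced variant (BDHOA) as general-purpose bounded continuous
    minimizers, together with the benchmark-function study harness used to
    compare them (Rastrigin, Rosenbrock, Ackley, Sphere). On top of the
    optimizer the package provides a computer-aided-diagnosis pipeline for
    grayscale breast MR-like images: min-max normalization and a four-filter
    hybrid denoiser with a trainable least-squares combiner, GLCM/Haralick and
    local-binary-pattern texture features with independent component analysis
    reduction, a small convolutional network whose weights are trained by the
    BDHOA metaheuristic instead of backpropagation, and OR-rule decision fusion
    of the two classification paths with confusion-matrix metrics. A seeded
    synthetic image generator emulates texture-differentiated lesion classes so
    the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    png,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    class,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
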