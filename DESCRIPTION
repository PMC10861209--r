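Package: pillarmech
Title: Single-Cell Mechanosensation Analysis on Micropillar Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for single-cell traction-force
    mechanosensation experiments on elastic micropillar arrays.
    Reconstructs per-pillar deflections and traction forces from
    fluorescence image stacks or pre-tracked centroid tables, computes
    static and dynamic force metrics (total, per-pillar, active and
    quiescent force, strain energy, normalized force traces, peak force
    and time-to-peak), derives instantaneous force amplitude and
    frequency spectra by empirical mode decomposition and the Hilbert
    transform, quantifies calcium transients and cytoskeletal marker
    images (intensity, actin orientation dispersion), and summarizes
    cohorts with standard statistics (Student's t, one-way ANOVA with
    Tukey's post hoc test, least-squares regression with confidence
    bands, min-max radar profiles). A synthetic-data module generates
    micropillar image stacks, calcium traces and fiber-texture images
    with packaged phenotype profiles so the whole pipeline can be
    exercised and validated without any experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
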