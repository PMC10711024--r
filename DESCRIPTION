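Package: uaeopt
Title: Box-Behnken Response Surfaces and Hybrid ANN-PSO Optimization of
    Ultrasound-Assisted Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for modeling and optimizing ultrasound-assisted
    extraction of phytochemicals (extraction yield, total phenolics,
    flavonoids, tannins, and DPPH antioxidant activity) from plant
    by-products such as green coconut shell.  Generates three-factor
    Box-Behnken designs with coded/natural unit conversion, fits and
    statistically characterizes coded second-order response surfaces
    (sequential ANOVA with lack of fit, pure error, PRESS-based
    predicted R-squared), trains feed-forward back-propagation neural
    network surrogates with tansig hidden units, and maximizes the five
    responses jointly with a standard particle swarm optimizer composed
    into a hybrid ANN-PSO pipeline.  Includes a seeded synthetic-data
    generator that simulates Box-Behnken experiments from bundled
    literature response surfaces, for parameter-recovery and
    end-to-end validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
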