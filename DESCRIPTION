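Package: rgcsubunits
Title: Nonlinear Subunit Models of Retinal Ganglion Cell Responses at
    Single-Cone Resolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits hierarchical linear-nonlinear-linear-nonlinear-Poisson
    (subunit) cascade models of retinal ganglion cell light responses in
    which individual cone photoreceptor inputs are pooled into non-overlapping
    nonlinear subunits, the functional correlate of bipolar cells. Provides
    the constrained maximum-likelihood fitting procedure (coordinate ascent
    over subunit weights, cone weights and cubic-spline nonlinearities, nested
    in a greedy agglomerative search over cone-to-subunit assignments),
    reductions to linear-nonlinear and single-cone-subunit models, a
    synthetic-data generator (white-noise cone stimulation, contrast-reversing
    gratings projected through Gaussian cone apertures, targeted single- and
    paired-cone trials, repeated-noise blocks), evaluation metrics
    (cross-validated R-squared, reliability-adjusted R-squared, maximally
    differentiating stimuli, frequency-doubling indices, paired-cone
    prediction scores and bootstrap model comparison), and a parameter
    recovery experiment.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
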