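Package: nucleoscan
Title: Nucleosome Positioning Prediction from Dinucleotide
    Physicochemical Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies 150-bp DNA segments as nucleosome-forming or
    linker (nucleosome-inhibiting) sequences.  Sequences are encoded as
    concatenated per-position profiles of twelve normalized dinucleotide
    physicochemical scales (A-philicity, base stacking, bendability,
    propeller twist and others), giving a 1788-dimensional feature
    vector, and classified with a covariant (equal-prior quadratic)
    discriminant: squared Mahalanobis distance to each class mean plus
    the log-determinant of the class covariance.  Includes F-score
    feature ranking with incremental feature selection, stratified
    k-fold cross-validation with sensitivity/specificity/overall success
    rate, a sliding-window scanner for arbitrary-length FASTA input with
    merged segment calls and optional BED export, synthetic two-class
    sequence and Gaussian generators for testing, and a command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    graphics
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
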