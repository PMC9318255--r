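Package: shelfsense
Title: Shelf-Life and Sensory Quality Inference for Mildly Processed Fish Fillets
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical toolchain for chilled fish-fillet shelf-life studies:
    Quality Index Method (QIM) demerit scoring with linear trend fitting and
    rejection-threshold shelf-life estimation, Thurstonian analysis of the
    tetrad discrimination protocol (exact binomial difference and similarity
    tests, d-prime estimation, sample-size planning), Baranyi-Roberts growth
    model fitting of spoilage microbiota on log10 plate counts, and the
    descriptive-analysis statistics stack (two-way ANOVA with sequential
    interaction elimination, Fisher's LSD compact letter display, covariance
    PCA with Varimax rotation and supplementary observations, partial-bootstrap
    convex hulls, and agglomerative hierarchical clustering in similarity and
    dissimilarity modes). Seeded synthetic-data generators emulate the panel,
    tetrad, plate-count and descriptive datasets so the full pipeline is
    testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    minpack.lm,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
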