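Package: cofosnet
Title: Activation Patterns and Functional Connectivity Networks from
    Regional c-Fos Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing per-animal regional c-Fos
    immunoreactivity tables from factorial (treatment x light/dark
    phase) designs. Classifies brain regions into activation patterns
    by two-way ANOVA with Bonferroni-corrected simple effects, infers
    inter-regional functional connectivity as the sum of absolute
    pairwise correlations per region, calibrates it against a
    permutation null built from independently shuffled sample orders,
    and tests group differences in per-region connectivity with a
    bootstrap group-relabelling procedure. Includes a synthetic-data
    generator (Gaussian copula over lognormal count margins) that
    emulates factorial c-Fos count tables with known mean structure
    and known latent correlation networks.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    car,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
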