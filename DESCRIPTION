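Package: vfasurf
Title: Response-Surface Modelling and Optimization of Volatile Fatty Acid
    Production from Wastewater Sludge Fermentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling total volatile fatty acid (VFA) production
    from anaerobic batch fermentation of wastewater sludge as a bivariate
    cubic response surface in temperature and retention time.  Provides the
    factorial study design (two sludge types, two organic loads, three
    initial pH levels, four temperatures), validated observation tables, a
    seeded synthetic-data generator with known ground-truth surfaces,
    per-treatment ordinary least squares fits with coefficient t-value
    diagnostics and degree comparison, brute-force grid optimization of the
    production optimum over a methane-censored feasible domain, parametric
    bootstrap uncertainty for the optimum, and between-treatment inference
    (one-way ANOVA with regression-adjusted degrees of freedom, two-sample
    t-test of the best treatments, Pareto ranking of coefficient t-values).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
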