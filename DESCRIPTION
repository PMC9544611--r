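Package: admixvar
Title: Variability of Ancestry Membership Coefficients in Admixture Q Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the variability of individual ancestry membership
    coefficient vectors in a Q matrix (the output of population structure
    inference programs such as STRUCTURE and ADMIXTURE) with the normalized
    statistic FST/FSTmax, where FSTmax is the constrained maximum of FST
    given the number of individuals and the mean membership of the
    highest-membership cluster. Provides row-bootstrap distributions of the
    statistic and rank-based tests (Wilcoxon rank-sum, Kruskal-Wallis) to
    compare variability between groups, a Dirichlet simulator of Q matrices
    with known parametric variance for validation experiments, readers and
    writers for the delimited-text Q-matrix dialects, and ggplot2
    stacked-bar visualizations of Q matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
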