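Package: stringsan
Title: Forbidden-Pattern Avoiding Missing-Value Replacement, String
    Sanitization and Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for replacing missing values in strings under
    forbidden-pattern constraints, for fully sanitizing private strings so
    that no forbidden length-k pattern occurs in the output, and for
    clustering collections of sanitized strings.  The core is a
    deterministic finite automaton over the proper prefixes of the
    forbidden patterns ("dangerous" strings) whose transitions avoid every
    pattern; missing-value replacement reduces to a shortest-path search
    on this automaton, and full sanitization splices optimal replacements
    into the unique shortest partial sanitization.  Collections are
    compared with an occurrence-list / longest-increasing-subsequence
    k-gram distance and clustered with a seeded K-medoids (PAM) heuristic;
    clustering agreement is scored with normalized mutual information and
    a pair-counting adjusted Rand index.  A synthetic-data generator with
    planted cluster structure supports end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    cluster,
    igraph,
    mclust,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
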