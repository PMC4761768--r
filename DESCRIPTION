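Package: betadecay
Title: Distance Decay of Community Similarity, Mantel Tests and
    Variation Partitioning for Presence-Absence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing spatial species turnover (beta diversity)
    from site-by-species incidence matrices: pairwise Jaccard and Simpson
    similarity, geodesic/environmental/elevational distance matrices,
    linear, logarithmic and exponential distance-decay regressions with a
    halving-distance statistic and matrix-permutation significance, simple
    and partial Mantel tests, multiple regression on distance matrices
    (MRM) with seven-fraction variation partitioning, zonal (latitudinal,
    longitudinal, elevational) decay comparisons, and a synthetic mountain
    landscape generator with controllable dispersal, niche and isolation
    mechanisms for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
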