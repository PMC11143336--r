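Package: phagemetrics
Title: Centroid Index and Companion Metrics for Phage Lytic Efficiency from
    Growth Curves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores the lytic efficiency of bacteriophages and phage cocktails
    from bacterial optical-density (OD) growth curves measured in microplate
    readers. Implements the Centroid Index (CI), which compares the geometric
    centroid of the region under a phage-treated growth curve against the
    centroid under the uninfected control and is therefore sensitive to when
    growth (including late bacterial regrowth) occurs, not only to how much.
    Also provides the area-ratio Virulence Index (VI) and the maximum specific
    growth rate (mu_max) for comparison, plate-reader data ingestion in wide
    and long delimited-text layouts, blank subtraction and replicate handling,
    treatment ranking, seeded synthetic growth-curve generators (logistic,
    lysis-then-regrowth, area-matched and mu_max-matched pairs), and a
    command-line workflow producing per-sample metric tables and rankings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    jsonlite,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
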