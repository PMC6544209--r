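Package: epiwindow
Title: Detectability of Pairwise Epistasis Against Stochastic Linkage in
    Wright-Fisher Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-time Wright-Fisher simulation of haploid binary genomes
    evolving under mutation, selection, genetic drift, optional recombination,
    and pairwise antagonistic epistasis, together with the analysis machinery
    needed to ask when epistatic locus pairs are detectable from a one-time
    population sample.  Provides a panel of six haplotype-based linkage
    disequilibrium statistics (Lewontin's D' in two allele conventions,
    Pearson r likewise, the WU log odds ratio, and the fitness-interpretable
    UFE measure), an a-priori-label threshold detector in one to three
    statistic dimensions with detection/false-positive accounting over time,
    multi-population averaging of haplotype frequencies, parameter sweeps
    delineating the detection window, and clonal/genealogical structure
    summaries (clone decomposition, clonal exclusion, hierarchical-clustering
    trees with Newick export).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
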