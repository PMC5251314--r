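Package: ldphase
Title: Linkage Disequilibrium, Gametic Phase Persistence and Genomic
    Diversity for SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising population structure and demographic
    history from diploid SNP genotype panels, aimed at livestock
    populations genotyped on medium-density chips. Implements composite
    linkage disequilibrium (D, r-squared and signed phase r) estimated
    directly from unphased genotypes, distance-binned LD decay summaries,
    persistence of gametic phase between populations or herds, and
    LD-based effective population size via Sved's equation. Also provides
    genotype quality control with Hardy-Weinberg testing, a misplaced-SNP
    screen, observed/expected heterozygosity and identity-by-state
    distances, runs of homozygosity, four inbreeding coefficients
    (excess homozygosity, VanRaden, ROH-based and pedigree-based), the
    VanRaden genomic relationship matrix with principal components, and a
    forward Wright-Fisher simulator with recombination for generating
    genotype panels with known demographic truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
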