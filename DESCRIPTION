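Package: mhcdrop
Title: Gene-Drop Neutrality Tests and MHC Fitness-Association Post-Processing
    for Pedigreed Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether major histocompatibility complex (MHC)
    haplotype frequencies in a pedigreed wild population have changed more (or
    less) than expected under genetic drift. Implements gene-drop simulation
    (Mendelian transmission of observed founder-cohort diplotypes down a fixed
    pedigree, with cohort-frequency imputation for unknown parents), empirical
    tests of trajectory slope and cumulative frequency change against the
    simulated null, and classification into directional, fluctuating or
    balancing selection. Also provides the MHC diversity layer (amino-acid
    p-distance divergence, heterozygosity, haplotype dosage coding), Wald tests
    and haplotype-versus-rest contrasts on posterior coefficient draws from
    external mixed-model fits, simplified fixed-effect fitness-model fitters,
    and a synthetic-data generator emulating an intensively monitored ungulate
    population with overlapping generations.
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
    MASS,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    glmmTMB,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
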