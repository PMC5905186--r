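Package: snpclock
Title: Dating Population Divergence from Joint SNP Class Frequencies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the age of a recently founded, partially isolated
    population (such as a cave population of Astyanax mexicanus) from pooled
    SNP data. Biallelic sites are polarized with an outgroup and classified
    into eight joint polymorphism patterns across the two populations;
    a forward-in-time Wright-Fisher simulator of neutral SNP evolution under
    an isolation-with-migration model with unequal generation times and a
    laboratory drift observation step generates the same class-frequency
    summary statistics; the divergence age is estimated as the simulated age
    minimizing a goodness-of-fit score against the observed class
    frequencies. Also provides Pool-seq style site filtering, a
    parsimony-informative quartet incongruence tool, and synthetic data
    generators for all inputs.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    graphics,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
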