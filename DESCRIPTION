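Package: archhap
Title: Archaic Introgression Inference for Candidate Haplotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether a candidate haplotype in present-day
    humans was inherited from archaic hominins (Neandertals, Denisovans).
    Delineates a haplotype block around an index variant by linkage
    disequilibrium (r-squared) on phased haplotypes, computes population
    allele frequencies, matches the block's defining alleles against
    archaic genotype calls, tests the alternative explanation of
    incomplete lineage sorting with a haplotype-length survival model
    driven by the local recombination rate, and places modern and archaic
    haplotypes in a rooted bootstrapped distance phylogeny (Tamura-Nei
    distances, neighbor joining). Includes a synthetic-data generator that
    plants an introgressed tract so the whole pipeline can be exercised
    and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
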