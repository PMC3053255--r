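Package: CodeOptimality
Title: Error-Minimization Optimality of the Genetic Code by Simulated Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how well genetic code tables minimize the
    phenotypic impact of single-base errors. Implements the mean-square (MS)
    change in amino-acid polar requirement over all single-base codon
    substitutions and its mistranslation-weighted variant (tMS), two models of
    hypothetical codes (amino-acid permutations over the canonical block
    structure, and codes evolved by single-codon reassignments), a genetic
    algorithm with tournament selection and elitism that searches for better
    adapted codes, random-code sampling with histogram summaries, and the
    percentage-distance-minimization (p.d.m.) statistic that locates the
    canonical code between the random-code mean and the best code found.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats
Suggests: testthat (>= 3.0.0), Biostrings, jsonlite, optparse, yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 'constants.R' 'AllClasses.R' 'AllGenerics.R' 'code-model.R'
    'fitness.R' 'evolution.R' 'stats.R' 'io.R'
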