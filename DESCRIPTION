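Package: neoprofiler
Title: Neoantigen Profiling of Somatic Mutation Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Profiling of candidate neoantigens in tumor cohorts from
    annotated somatic variants and HLA class-I genotypes: mutant-peptide
    enumeration (8-11mers covering the mutated residue), pluggable
    MHC-binding prediction with IC50 thresholds for weak and strong
    binders, somatic substitution-spectrum summaries on the
    pyrimidine-referenced six-class scheme, per-patient tumor mutation
    burden, recurrent-gene and cancer-gene-census filtering, HLA carrier
    frequencies, and one-sided rank-sum comparisons of neoantigen burden
    across clinical subgroups. Includes a seeded synthetic-cohort
    generator for end-to-end testing and a packaged 32-patient gastric
    cancer cohort summary used as a reference fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
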