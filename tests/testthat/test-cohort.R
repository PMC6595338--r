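clinical3 <- data.frame(
  patient_id = c("P1", "P2", "P3"),
  sex = c("F", "M", "M"), age = c(50, 60, 70),
  tnm = c("T2N0M0", "T4aN1M0", "T1aN0M0"),
  t_stage = c("T2", "T4a", "T1a"),
  stringsAsFactors = FALSE)

test_that("patient summaries count classes, TMB and hypermutators", {
  v <- rbind(
    make_variants(rep("P1", 138), "G", ref_base = "C", alt_base = "T",
                  ref_aa = "A", protein_pos = 1, alt_aa = "V"),
    make_variants(rep("P1", 4), "G", variant_class = "indel"),
    make_variants(rep("P2", 1336), "G", ref_base = "C", alt_base = "A",
                  ref_aa = "A", protein_pos = 1, alt_aa = "V"))
  s <- summarize_patients(v, calls = NULL, clinical = clinical3)
  expect_equal(s$n_missense, c(138L, 1336L, 0L))
  expect_equal(s$n_indel, c(4L, 0L, 0L))
  expect_equal(s$tmb, c(4.6, 1336 / 30, 0))
  expect_equal(s$hypermutator, c(FALSE, TRUE, FALSE))  # 44.5 > 40

  orphan <- make_variants("P9", "G", ref_base = "C", alt_base = "T",
                          ref_aa = "A", protein_pos = 1, alt_aa = "V")
  expect_error(summarize_patients(orphan, NULL, clinical3), "P9")
})

test_that("neoantigen counts are distinct peptide-allele pairs per patient", {
  calls <- data.frame(
    patient_id = c("P1", "P1", "P1", "P2"),
    peptide = c("AAAAAAAA", "AAAAAAAA", "AAAAAAAA", "CCCCCCCC"),
    allele = c("A*02:01", "A*02:01", "A*11:01", "A*02:01"),
    stringsAsFactors = FALSE)
  v <- make_variants("P1", "G", ref_base = "C", alt_base = "T",
                     ref_aa = "A", protein_pos = 1, alt_aa = "V")
  s <- summarize_patients(v, calls, clinical3)
  expect_equal(s$n_neoantigen, c(2L, 1L, 0L))  # duplicate pair counted once
})

test_that("gene recurrence counts patients, not mutations", {
  v <- rbind(
    # gene X: 9 distinct patients of a 32-patient cohort
    make_variants(sprintf("P%02d", 1:9), "X", ref_base = "C",
                  alt_base = "T", ref_aa = "A", protein_pos = 1,
                  alt_aa = "V"),
    # gene Y: twice in one patient only
    make_variants(c("P01", "P01"), "Y", ref_base = "C", alt_base = "G",
                  ref_aa = "A", protein_pos = c(1, 2), alt_aa = "V"))
  rec <- recurrent_genes(v, min_patients = 3, cohort_size = 32)
  expect_equal(rec$gene, "X")
  expect_equal(rec$n_patients, 9L)
  expect_equal(100 * rec$fraction, 28.125)  # printed as 28.13% half-up
  expect_equal(rec$total_mutations, 9L)

  all_genes <- recurrent_genes(v, min_patients = 1, cohort_size = 32)
  expect_setequal(all_genes$gene, c("X", "Y"))
  # partition property: totals sum to the cohort missense count
  expect_equal(sum(all_genes$total_mutations),
               sum(v$variant_class == "missense"))
})

test_that("census intersection is exact but case-insensitive", {
  rec <- data.frame(gene = c("TP53", "MUC4"), n_patients = c(9L, 30L),
                    fraction = c(9, 30) / 32, total_mutations = c(9L, 250L))
  hit <- intersect_census(rec, c("TP53"))
  expect_equal(hit$gene, "TP53")
  expect_true(all(hit$in_census))
  expect_equal(nrow(intersect_census(rec, c("Tp53"))), 1L)
  expect_equal(nrow(intersect_census(rec[0, ], "TP53")), 0L)
  expect_error(intersect_census(rec, character(0)), "empty")

  census_path <- tempfile()
  writeLines(c("TP53", "", "  EGFR "), census_path)
  expect_equal(intersect_census(rec, census_path)$gene, "TP53")
})

test_that("carrier frequencies use set semantics over patients", {
  hla <- rbind(
    data.frame(patient_id = sprintf("P%02d", 1:15), allele = "A*11:01"),
    data.frame(patient_id = sprintf("P%02d", 1:12), allele = "C*01:02"),
    data.frame(patient_id = sprintf("P%02d", 1:32), allele = "B*40:01"))
  f <- hla_carrier_frequencies(hla)
  expect_equal(round(100 * f$frequency[f$allele == "A*11:01"], 1), 46.9)
  expect_equal(f$frequency[f$allele == "C*01:02"], 0.375)
  expect_equal(f$frequency[f$allele == "B*40:01"], 1)
  expect_equal(f$frequency, sort(f$frequency, decreasing = TRUE))
})

test_that("incidence matrices agree with recurrence marginals", {
  cohort <- generate_cohort(fast_config(n_patients = 6, seed = 23))
  v <- cohort$variants
  rec <- recurrent_genes(v, min_patients = 1)
  mat <- incidence_matrix(v, genes = rec$gene)
  expect_equal(unname(rowSums(mat)), rec$total_mutations)
  expect_equal(ncol(mat), length(unique(v$patient_id)))
})

test_that("neoantigen-encoding gene recurrence filters by patient count", {
  calls <- data.frame(
    patient_id = c("P1", "P2", "P3", "P1", "P2", "P1"),
    gene = c("X", "X", "X", "Y", "Y", "X"),
    peptide = c("AAAAAAAA", "CCCCCCCC", "DDDDDDDD", "EEEEEEEE",
                "FFFFFFFF", "AAAAAAAC"),
    allele = "A*02:01", stringsAsFactors = FALSE)
  mat <- neoantigen_gene_recurrence(calls, min_patients = 3)
  expect_equal(rownames(mat), "X")       # Y present in only 2 patients
  expect_equal(sum(mat["X", ]), 4L)      # row sum equals X's total calls
  expect_equal(attr(mat, "n_patients"), 3L)
  mat2 <- neoantigen_gene_recurrence(calls, min_patients = 2)
  expect_setequal(rownames(mat2), c("X", "Y"))
})
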