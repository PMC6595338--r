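test_that("config validation names the offending field", {
  expect_error(cohort_config(n_patients = 1), "n_patients")
  expect_error(cohort_config(spectrum_probs = c("C>A" = 1)), "spectrum_probs")
  expect_error(cohort_config(spectrum_probs = c("C>A" = 0.5, "C>G" = 0.5,
                                                "C>T" = 0.5, "T>A" = -0.5,
                                                "T>C" = 0, "T>G" = 0)),
               "spectrum_probs")
  expect_error(cohort_config(sex_prob_female = 1.5), "sex_prob_female")
  expect_error(cohort_config(hypermutator_scale = 0.5), "hypermutator_scale")
  expect_error(cohort_config(stage_effect = c(T1a = 1)), "stage_effect")
})

test_that("identical config and seed give byte-identical output files", {
  cfg <- fast_config(n_patients = 6, seed = 7)
  d1 <- tempfile(); d2 <- tempfile()
  c1 <- generate_cohort(cfg, out_dir = d1)
  c2 <- generate_cohort(cfg, out_dir = d2)
  for (f in names(c1$paths)) {
    expect_identical(readLines(c1$paths[[f]]), readLines(c2$paths[[f]]),
                     info = f)
  }
  # a different seed changes the data
  c3 <- generate_cohort(fast_config(n_patients = 6, seed = 8))
  expect_false(identical(c1$variants, c3$variants))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(100)
  before <- runif(1)
  set.seed(100)
  invisible(generate_cohort(fast_config(n_patients = 2, seed = 3)))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("generated cohorts satisfy the package's input invariants", {
  cohort <- generate_cohort(fast_config(n_patients = 8, seed = 19))
  d <- tempfile()
  dir.create(d)
  paths <- generate_cohort(fast_config(n_patients = 8, seed = 19),
                           out_dir = d)$paths
  v <- read_variant_table(paths$variants)   # re-validates every record
  expect_equal(nrow(v), nrow(cohort$variants))
  s <- spectrum_summary(v)
  expect_equal(s$n_skipped, sum(v$variant_class == "indel"))
  hla <- read_hla_table(paths$hla)
  expect_true(all(grepl("^[ABC]\\*[0-9]{2,3}:[0-9]{2,3}$", hla$allele)))
  expect_setequal(unique(hla$patient_id), cohort$clinical$patient_id)
  cl <- read_clinical_table(paths$clinical)
  expect_equal(cl$t_stage, cohort$clinical$t_stage)
  # missense records always carry both annotations
  mis <- v[v$variant_class == "missense", ]
  expect_false(anyNA(mis$ref_base))
  expect_false(anyNA(mis$protein_pos))
  # protein positions lie inside their protein and match the reference
  prot <- read_protein_fasta(paths$proteins)
  expect_true(all(mis$protein_pos <= nchar(prot[mis$gene])))
  expect_equal(substring(prot[mis$gene], mis$protein_pos, mis$protein_pos),
               mis$ref_aa, ignore_attr = TRUE)
})

test_that("without the hypermutator component no patient crosses the TMB boundary", {
  for (seed in 1:20) {
    cfg <- fast_config(seed = seed, hypermutator_prob = 0)
    cohort <- generate_cohort(cfg)
    s <- summarize_patients(cohort$variants, NULL, cohort$clinical)
    expect_true(all(s$tmb <= 40), info = paste("seed", seed))
  }
})

test_that("hypermutators appear at the configured rate and exceed the boundary", {
  cfg <- fast_config(n_patients = 200, seed = 41, hypermutator_prob = 0.25,
                     burden_log_mean = log(138))
  cohort <- generate_cohort(cfg)
  s <- summarize_patients(cohort$variants, NULL, cohort$clinical)
  frac <- mean(s$hypermutator)
  se <- sqrt(0.25 * 0.75 / 200)
  expect_lt(abs(frac - 0.25), 3 * se)
  expect_true(all(s$n_missense[s$hypermutator] > 1200))
})

test_that("an allele carried with probability one is recovered at 100%", {
  cfg <- fast_config(n_patients = 5, seed = 2,
                     allele_pool = c("A*11:01" = 1, "B*40:01" = 0.2))
  cohort <- generate_cohort(cfg)
  f <- hla_carrier_frequencies(cohort$hla)
  expect_equal(f$frequency[f$allele == "A*11:01"], 1)
})

test_that("the recovery suite passes on the default study-scale config", {
  rec <- parameter_recovery_suite(cohort_config())
  expect_true(all(rec$pass))
  expect_true(any(grepl("R-squared", rec$check)))
})

test_that("a minimal two-patient cohort runs end-to-end", {
  rec <- parameter_recovery_suite(fast_config(n_patients = 2, seed = 1,
                                              burden_log_mean = log(20)))
  expect_true(is.data.frame(rec))
  expect_true(all(c("check", "observed", "pass") %in% names(rec)))
})

test_that("a non-constant stage effect thins calls per stage", {
  cfg <- fast_config(n_patients = 40, seed = 55,
                     burden_log_mean = log(60), hypermutator_prob = 0,
                     stage_probs = c(T1a = 0.5, T2 = 0.5, T4a = 0, T4b = 0),
                     stage_effect = c(T1a = 1, T2 = 0.25, T4a = 1, T4b = 1))
  cohort <- generate_cohort(cfg)
  cand <- peptides_for_variants(cohort$variants, cohort$proteins)
  rate <- cfg$stage_effect / max(cfg$stage_effect)
  keep <- setNames(rate[cohort$clinical$t_stage],
                   cohort$clinical$patient_id)
  set.seed(56)
  calls <- call_neoantigens_cohort(cand, cohort$hla, mock_predictor(55),
                                   keep_prob = keep)
  s <- summarize_patients(cohort$variants, calls, cohort$clinical)
  per_mut <- s$n_neoantigen / pmax(s$n_missense, 1)
  m1 <- median(per_mut[s$t_stage == "T1a"])
  m2 <- median(per_mut[s$t_stage == "T2"])
  expect_gt(m1, m2)  # earlier stage retains a higher neoantigen rate
})
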