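test_that("mock predictor is deterministic and allele-sensitive", {
  p <- mock_predictor(3)
  x1 <- predict_ic50(p, "SIINFEKLM", "A*02:01")
  x2 <- predict_ic50(p, "SIINFEKLM", "A*02:01")
  expect_identical(x1, x2)
  # a fresh contract with the same seed reproduces the same surface
  expect_identical(predict_ic50(mock_predictor(3), "SIINFEKLM", "A*02:01"),
                   x1)
  # different seed, different surface (on a fixture peptide)
  expect_false(predict_ic50(mock_predictor(4), "SIINFEKLM", "A*02:01") == x1)

  set.seed(1)
  peps <- vapply(rep(9, 100), random_protein, "")
  a1 <- predict_ic50(p, peps, "A*02:01")
  a2 <- predict_ic50(p, peps, "B*58:01")
  expect_gt(sum(a1 != a2), 95)  # generally different across alleles
})

test_that("mock predictor spans both binding thresholds", {
  p <- mock_predictor(11)
  set.seed(2)
  peps <- vapply(sample(8:11, 10000, replace = TRUE), random_protein, "")
  alleles <- sample(c("A*02:01", "A*11:01", "B*15:01", "C*01:02"),
                    10000, replace = TRUE)
  ic50 <- predict_ic50(p, peps, alleles)
  expect_true(all(ic50 >= 1 & ic50 <= 50000))
  expect_gt(mean(ic50 < 100), 0)
  expect_gt(mean(ic50 > 500), 0)
})

test_that("affinity-table predictor looks up, refuses gaps, rejects conflicts", {
  tab <- data.frame(peptide = c("ACDEFGHI", "ACDEFGHI"),
                    allele = c("A*02:01", "B*15:01"),
                    ic50_nm = c(50, 700))
  p <- affinity_table_predictor(tab)
  expect_equal(predict_ic50(p, "ACDEFGHI", "A*02:01"), 50)
  expect_error(predict_ic50(p, "ACDEFGHI", "C*01:02"), "does not cover")
  expect_error(affinity_table_predictor(
    rbind(tab, data.frame(peptide = "ACDEFGHI", allele = "A*02:01",
                          ic50_nm = 60))), "conflicting")
  # exact duplicates are tolerated
  expect_silent(affinity_table_predictor(rbind(tab, tab[1, ])))
  expect_error(affinity_table_predictor(
    data.frame(peptide = "ACDEFGHI", allele = "A*02:01", ic50_nm = -1)),
    "positive")
})

test_that("neoantigen calling applies weak and strong thresholds", {
  tab <- data.frame(peptide = c("ACDEFGHI", "CDEFGHIK", "DEFGHIKL"),
                    allele = "A*02:01",
                    ic50_nm = c(50, 150, 600))
  p <- affinity_table_predictor(tab)
  cand <- data.frame(peptide = tab$peptide)
  calls <- call_neoantigens(cand, "A*02:01", p)
  expect_equal(nrow(calls), 2L)           # 600 exceeds weak 500
  expect_equal(sum(calls$is_strong), 1L)  # only 50 < 100
  expect_equal(calls$ic50_nm, sort(calls$ic50_nm))
  expect_equal(attr(calls, "weak_nm"), 500)

  all_calls <- call_neoantigens(cand, "A*02:01", p, weak_nm = Inf)
  expect_equal(nrow(all_calls), 3L)

  expect_error(call_neoantigens(cand, character(0), p), "empty HLA genotype")
})

test_that("calls over a genotype equal the brute-force filter of the table", {
  set.seed(5)
  prot <- random_protein(60)
  ref <- substr(prot, 30, 30)
  mut <- apply_missense(prot, 30, ref, setdiff(AA20, ref)[1])
  cand <- enumerate_mutant_peptides(mut, 30)   # 38 windows
  alleles <- c("A*02:01", "A*11:01", "B*15:01", "B*58:01", "C*01:02")
  tab <- expand.grid(peptide = cand$peptide, allele = alleles,
                     stringsAsFactors = FALSE)
  tab$ic50_nm <- round(exp(runif(nrow(tab), 0, log(20000))), 3)
  p <- affinity_table_predictor(tab)
  calls <- call_neoantigens(cand, alleles, p)
  expect_equal(nrow(calls), sum(tab$ic50_nm <= 500))
  expect_equal(sum(calls$is_strong), sum(tab$ic50_nm < 100))
})

test_that("lowering the weak threshold never adds calls; strong is a subset", {
  set.seed(6)
  prot <- random_protein(50)
  mut <- apply_missense(prot, 25, substr(prot, 25, 25),
                        setdiff(AA20, substr(prot, 25, 25))[1])
  cand <- enumerate_mutant_peptides(mut, 25)
  p <- mock_predictor(8)
  alleles <- c("A*02:01", "B*40:01")
  thresholds <- c(Inf, 5000, 500, 100, 50, 10)
  sizes <- vapply(thresholds, function(w) {
    nrow(call_neoantigens(cand, alleles, p, weak_nm = w))
  }, 1L)
  expect_true(all(diff(sizes) <= 0))
  for (w in c(5000, 500, 50)) {
    calls <- call_neoantigens(cand, alleles, p, weak_nm = w)
    expect_equal(calls$is_strong, calls$ic50_nm < 100)
    expect_true(all(calls$ic50_nm <= w))
  }
})

test_that("neoantigen burden is non-decreasing in missense burden", {
  # same genotype and predictor; nested variant sets per step
  set.seed(9)
  proteins <- setNames(vapply(rep(80, 30), random_protein, ""),
                       sprintf("G%02d", 1:30))
  pos <- sample(15:65, 30, replace = TRUE)
  refs <- substr(proteins, pos, pos)
  alts <- vapply(refs, function(r) setdiff(AA20, r)[1], "")
  v_all <- make_variants("P1", names(proteins), ref_aa = refs,
                         protein_pos = pos, alt_aa = alts)
  p <- mock_predictor(2)
  alleles <- c("A*11:01", "C*01:02")
  counts <- vapply(seq(5, 30, by = 5), function(k) {
    cand <- peptides_for_variants(v_all[1:k, ], proteins)
    calls <- call_neoantigens(cand, alleles, p)
    nrow(unique(calls[, c("peptide", "allele")]))
  }, 1L)
  expect_true(all(diff(counts) >= 0))
})
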