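test_that("identical groups give z = 0 and one-sided p = 0.5", {
  t <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(t$z, 0)
  expect_equal(t$p.value, 0.5)
})

test_that("degenerate all-identical data is rejected", {
  expect_error(rank_sum_test(c(2, 2), c(2, 2, 2)), "degenerate")
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("tie-free variance reduces to n_a n_b (n+1) / 12", {
  set.seed(31)
  a <- rnorm(8); b <- rnorm(11)   # continuous, ties impossible
  t <- rank_sum_test(a, b)
  n_a <- 8; n_b <- 11; n <- 19
  r <- rank(c(a, b))
  u <- sum(r[1:8]) - n_a * (n_a + 1) / 2
  z_manual <- (u - n_a * n_b / 2) / sqrt(n_a * n_b * (n + 1) / 12)
  expect_equal(t$z, z_manual)
  expect_equal(t$p.value, pnorm(z_manual, lower.tail = FALSE))
})

test_that("swapping groups with the mirrored alternative gives the same p", {
  set.seed(32)
  for (i in 1:20) {
    a <- sample(0:50, sample(2:10, 1), replace = TRUE)
    b <- sample(0:50, sample(2:10, 1), replace = TRUE)
    p1 <- rank_sum_test(a, b, "a_greater")$p.value
    p2 <- rank_sum_test(b, a, "a_less")$p.value
    expect_equal(p1, p2)
  }
})

test_that("normal approximation agrees with wilcox.test without continuity", {
  set.seed(33)
  for (i in 1:20) {
    a <- sample(0:30, sample(4:12, 1), replace = TRUE)  # ties likely
    b <- sample(0:30, sample(4:12, 1), replace = TRUE)
    ours <- rank_sum_test(a, b, "a_greater")$p.value
    ref <- suppressWarnings(
      wilcox.test(a, b, alternative = "greater", exact = FALSE,
                  correct = FALSE)$p.value)
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the permutation mid-p on small groups", {
  # the uncorrected normal tail estimates the permutation mid-p; on tie-free
  # groups of 3-6 the two agree within 0.02 (the inclusive exact p is
  # coarser by construction and is exposed via exact = TRUE instead)
  set.seed(34)
  for (i in 1:30) {
    n_a <- sample(3:6, 1); n_b <- sample(3:6, 1)
    vals <- sample(1:100, n_a + n_b)   # distinct values
    a <- vals[seq_len(n_a)]; b <- vals[-seq_len(n_a)]
    approx_p <- rank_sum_test(a, b, "a_greater")$p.value
    expect_lt(abs(approx_p - oracle_mid_p(a, b, "a_greater")), 0.02)
    # the exact flag reproduces the inclusive enumeration oracle, ties or not
    at <- sample(1:10, n_a, replace = TRUE)
    bt <- sample(1:10, n_b, replace = TRUE)
    if (length(unique(c(at, bt))) > 1L) {
      expect_equal(rank_sum_test(at, bt, "a_greater", exact = TRUE)$p.value,
                   oracle_exact_p(at, bt, "a_greater"))
    }
  }
})

test_that("the one-sided test holds its nominal size under the null", {
  set.seed(35)
  n_sim <- 10000
  rejections <- 0L
  for (i in seq_len(n_sim)) {
    a <- rnorm(20); b <- rnorm(20)
    if (rank_sum_test(a, b, "a_greater")$p.value < 0.05) {
      rejections <- rejections + 1L
    }
  }
  expect_equal(rejections / n_sim, 0.05, tolerance = 0.01 / 0.05)
})

test_that("OLS fit reports squared correlation and rejects degenerate x", {
  x <- c(1, 2, 3, 4); y <- 2 * x + 1
  f <- suppressWarnings(fit_linear(x, y))  # lm warns on a perfect fit
  expect_equal(f$r_squared, 1)
  expect_equal(f$slope, 2)
  set.seed(36)
  for (i in 1:100) {
    x <- rnorm(20); y <- rnorm(20) + 0.5 * x
    expect_equal(fit_linear(x, y)$r_squared, cor(x, y)^2)
  }
  expect_error(fit_linear(c(1, 1, 1), 1:3), "constant x")
  expect_error(fit_linear(1:2, 1:2), "at least 3")
})

test_that("subgroup comparisons use the documented directions and skip tiny groups", {
  fx <- load_cohort_fixtures()
  s <- fx$summaries

  sex <- subgroup_report(s, "sex")
  expect_equal(sex$group_a, "male")
  expect_gt(sex$median_a, sex$median_b)  # male median exceeds female

  age <- subgroup_report(s, "age45")
  expect_equal(age$n_b, 4L)  # age <= 45 includes the age-45 patient

  stage <- subgroup_report(s, "t_stage")
  expect_equal(nrow(stage), choose(4, 2))
  expect_true(all(stage$alternative == "a_greater"))
  # earlier stage is always group a
  expect_equal(stage$comparison[1], "T1a vs T2")

  # a 1-member group is skipped with a warning
  s1 <- s
  s1$t_stage[s1$t_stage == "T1a"][1] <- "T2"
  w <- capture_warnings(st <- subgroup_report(s1, "t_stage"))
  expect_length(w, 3L)  # the three comparisons involving the 1-member stage
  expect_true(all(grepl("fewer than", w)))
  expect_equal(nrow(st), choose(4, 2) - 3L)

  # multiple-testing adjustment is available but off by default
  expect_equal(stage$p, stage$p_adjusted)
  bh <- subgroup_report(s, "t_stage", p_adjust = "BH")
  expect_equal(bh$p_adjusted, p.adjust(bh$p, "BH"))
})
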