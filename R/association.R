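# Clinical association layer: one-sided rank-sum comparisons of neoantigen
# burden across subgroups, and the missense-versus-neoantigen least-squares
# fit. The rank-sum convention is fixed and documented: midranks for ties,
# tie-corrected variance, normal approximation WITHOUT continuity
# correction, one-sided tail per the stated alternative. Exact-permutation
# and continuity-corrected variants are available behind flags.

#' One-sided Wilcoxon rank-sum test (normal approximation)
#'
#' Compares two samples with the Mann-Whitney U statistic for group `a`.
#' Ties receive midranks; the null variance carries the tie correction
#' `(n_a n_b / 12) * [(n + 1) - sum(t^3 - t) / (n (n - 1))]`; the z score
#' is `(U - n_a n_b / 2) / sd` with no continuity correction unless
#' requested; the one-sided p-value is the corresponding normal tail.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param alternative `"a_greater"` (default) tests whether `a` is
#'   stochastically greater than `b`; `"a_less"` the reverse.
#' @param label_a,label_b Group labels for reporting.
#' @param exact Use the exact permutation distribution of U (full
#'   enumeration; intended for small groups) instead of the normal
#'   approximation.
#' @param continuity Apply the 0.5 continuity correction to the normal
#'   approximation (off by default; the package's fixed convention).
#' @return An object of class `rank_sum_test` with fields `u`, `z`,
#'   `p.value`, group sizes, medians, labels, `alternative`, `method`.
#' @examples
#' rank_sum_test(c(666, 334), c(134, 190, 220, 198, 211, 116, 306))
#' @export
rank_sum_test <- function(a, b, alternative = c("a_greater", "a_less"),
                          label_a = "a", label_b = "b",
                          exact = FALSE, continuity = FALSE) {
  alternative <- match.arg(alternative)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n_a <- length(a); n_b <- length(b); n <- n_a + n_b
  pooled <- c(a, b)
  r <- rank(pooled)  # midranks
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- (n_a * n_b / 12) * ((n + 1) - tie_term)
  if (v <= 0) {
    stop("degenerate data: zero rank variance (all values identical)",
         call. = FALSE)
  }
  mu <- n_a * n_b / 2
  if (exact) {
    p <- .exact_rank_sum_p(a, b, alternative)
    z <- (u - mu) / sqrt(v)
    method <- "rank-sum, exact permutation, midranks"
  } else {
    dev <- u - mu
    if (continuity) dev <- dev - sign(dev) * 0.5
    z <- dev / sqrt(v)
    p <- if (alternative == "a_greater") stats::pnorm(z, lower.tail = FALSE)
         else stats::pnorm(z)
    method <- paste0("rank-sum, normal approximation, ",
                     if (continuity) "continuity-corrected, " else
                       "no continuity correction, ",
                     "tie-corrected variance")
  }
  structure(list(u = u, z = z, p.value = p,
                 n_a = n_a, n_b = n_b,
                 median_a = stats::median(a), median_b = stats::median(b),
                 label_a = label_a, label_b = label_b,
                 values_a = a, values_b = b,
                 alternative = alternative, method = method),
            class = "rank_sum_test")
}

# Full enumeration of group-a assignments; p is the tail probability of U
# at least (or at most) as extreme as observed.
.exact_rank_sum_p <- function(a, b, alternative) {
  n_a <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combs <- utils::combn(length(pooled), n_a)
  u_all <- apply(combs, 2L, function(idx) sum(r[idx])) -
    n_a * (n_a + 1) / 2
  if (alternative == "a_greater") mean(u_all >= u_obs) else mean(u_all <= u_obs)
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("Rank-sum test: %s (n=%d, median=%g) vs %s (n=%d, median=%g)\n",
              x$label_a, x$n_a, x$median_a, x$label_b, x$n_b, x$median_b))
  cat(sprintf("  %s\n  alternative: %s; U=%g, z=%.4f, p=%.4f\n",
              x$method, x$alternative, x$u, x$z, x$p.value))
  invisible(x)
}

#' Ordinary least-squares fit with R-squared
#'
#' Fits `y ~ x` by OLS (via [stats::lm()]); `r_squared` equals the squared
#' Pearson correlation of the two variables.
#'
#' @param x,y Numeric vectors of equal length, at least 3 points, with
#'   non-constant `x`.
#' @return An object of class `linear_fit` with `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @export
fit_linear <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need at least 3 (x, y) pairs", call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop("constant x: slope undefined", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = summary(fit)$r.squared,
                 n = length(x)),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("OLS fit (n=%d): y = %.4g + %.4g x, R^2 = %.4f\n",
              x$n, x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' Subgroup comparisons of neoantigen burden
#'
#' Runs the package's one-sided rank-sum comparisons of per-patient
#' neoantigen counts across clinical subgroups:
#' \describe{
#'   \item{`age45`}{patients older than 45 vs at most 45 years, testing
#'     whether the older group is greater. (The cutoff is inclusive on the
#'     young side: age <= 45.)}
#'   \item{`sex`}{male vs female, testing whether males are greater.}
#'   \item{`t_stage`}{all pairwise stage comparisons, testing whether the
#'     earlier stage is greater.}
#' }
#' Comparisons in which either group has fewer than `min_group` members are
#' skipped with a warning.
#'
#' @param summaries Patient summary data.frame containing `n_neoantigen`
#'   and the covariates `sex`, `age`, `t_stage` (as from
#'   [summarize_patients()] or [load_cohort_fixtures()]).
#' @param grouping One of `"age45"`, `"sex"`, `"t_stage"`.
#' @param value Column to compare; default `"n_neoantigen"`.
#' @param min_group Minimum group size for a comparison to run (default 2).
#' @param p_adjust Multiple-testing adjustment method passed to
#'   [stats::p.adjust()] for the `p_adjusted` column; default `"none"`
#'   (raw p-values are reported).
#' @param ... Passed to [rank_sum_test()] (`exact`, `continuity`).
#' @return Data.frame with one row per comparison: labels, group sizes,
#'   medians, `z`, `p`, `p_adjusted`, `alternative`.
#' @export
subgroup_report <- function(summaries, grouping = c("age45", "sex", "t_stage"),
                            value = "n_neoantigen", min_group = 2,
                            p_adjust = "none", ...) {
  grouping <- match.arg(grouping)
  .require_columns(summaries, c(value, "sex", "age", "t_stage"),
                   "patient summaries")
  y <- summaries[[value]]
  pairs <- switch(grouping,
    age45 = list(list(a = y[summaries$age > 45], b = y[summaries$age <= 45],
                      label_a = "age>45", label_b = "age<=45")),
    sex = list(list(a = y[summaries$sex == "M"], b = y[summaries$sex == "F"],
                    label_a = "male", label_b = "female")),
    t_stage = {
      stages <- unique(summaries$t_stage)
      stages <- stages[order(.stage_rank(stages))]
      if (length(stages) < 2L) {
        stop("t_stage grouping needs at least two stages", call. = FALSE)
      }
      cmb <- utils::combn(stages, 2L, simplify = FALSE)
      lapply(cmb, function(st) {
        list(a = y[summaries$t_stage == st[1L]],
             b = y[summaries$t_stage == st[2L]],
             label_a = st[1L], label_b = st[2L])
      })
    })
  rows <- lapply(pairs, function(p) {
    if (length(p$a) < min_group || length(p$b) < min_group) {
      warning(sprintf("skipping %s vs %s: group with fewer than %d members",
                      p$label_a, p$label_b, min_group), call. = FALSE)
      return(NULL)
    }
    t <- rank_sum_test(p$a, p$b, alternative = "a_greater",
                       label_a = p$label_a, label_b = p$label_b, ...)
    data.frame(comparison = paste(p$label_a, "vs", p$label_b),
               group_a = p$label_a, group_b = p$label_b,
               n_a = t$n_a, n_b = t$n_b,
               median_a = t$median_a, median_b = t$median_b,
               z = t$z, p = t$p.value, alternative = t$alternative,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(comparison = character(0), group_a = character(0),
                      group_b = character(0), n_a = integer(0),
                      n_b = integer(0), median_a = numeric(0),
                      median_b = numeric(0), z = numeric(0), p = numeric(0),
                      alternative = character(0))
  }
  out$p_adjusted <- stats::p.adjust(out$p, method = p_adjust)
  rownames(out) <- NULL
  out
}
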