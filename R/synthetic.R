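# Seeded synthetic-cohort generator. Emulates the statistical structure the
# analysis assumes at cohort-summary level: log-normal missense burden with
# a rare hypermutator mixture component, a configurable six-class
# substitution spectrum, Poisson indels, random protein models, an HLA
# allele pool with skewed carrier frequencies, and clinical covariates.
# Every draw is governed by the config seed, so identical configs give
# byte-identical output files.

# run code under a local RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(state)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", state, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Synthetic cohort configuration
#'
#' Builds and validates the parameter set of the synthetic-cohort
#' generator. Defaults emulate a 32-patient gastric cancer whole-exome
#' cohort at summary level: median missense burden around 138 (about 4.6
#' mutations/Mb on a 30 Mb exome), about 6% hypermutators exceeding 40
#' mutations/Mb, the reported six-class substitution spectrum with C>A and
#' C>T dominant, an indel-per-missense rate of 0.087, and an HLA class-I
#' pool whose leading carrier frequencies mirror the cohort's
#' (A*11:01 ~ 47%, C*01:02 ~ 37.5%, ...).
#'
#' @param n_patients Cohort size (>= 2).
#' @param seed Integer seed governing every draw.
#' @param burden_log_mean,burden_log_sd Log-scale parameters of the
#'   non-hypermutator missense-count distribution (log-normal, truncated
#'   below the hypermutator boundary).
#' @param hypermutator_prob Probability that a patient is a hypermutator.
#' @param hypermutator_scale Multiplier applied to the burden draw of a
#'   hypermutator (the draw is truncated above the boundary).
#' @param hypermutator_tmb TMB boundary (mutations/Mb) separating the two
#'   mixture components; default 40.
#' @param exome_mb Exome size used to convert the TMB boundary to a
#'   missense count; default 30.
#' @param spectrum_probs Named probabilities over the six substitution
#'   classes, summing to 1.
#' @param indel_rate Expected indels per missense mutation.
#' @param allele_pool Named vector of per-allele carrier probabilities.
#' @param stage_probs Named distribution over T stages.
#' @param sex_prob_female Probability of sex `F`.
#' @param age_range Integer range of ages (inclusive).
#' @param stage_effect Named multiplicative neoantigen-rate factor per
#'   stage, consumed by the simulation harness; the default is constant
#'   (no stage effect).
#' @param protein_length_range Integer range of generated protein lengths.
#' @param n_genes Number of genes (random proteins) in the synthetic
#'   genome.
#' @return A validated object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 32,
                          seed = 1,
                          burden_log_mean = log(138),
                          burden_log_sd = 0.75,
                          hypermutator_prob = 2 / 32,
                          hypermutator_scale = 10,
                          hypermutator_tmb = 40,
                          exome_mb = 30,
                          spectrum_probs = c("C>A" = 0.3218, "C>G" = 0.0989,
                                             "C>T" = 0.2724, "T>A" = 0.0589,
                                             "T>C" = 0.1229, "T>G" = 0.1251),
                          indel_rate = 0.087,
                          allele_pool = c("A*11:01" = 0.469,
                                          "C*01:02" = 0.375,
                                          "A*02:01" = 0.300,
                                          "A*03:01" = 0.250,
                                          "A*24:02" = 0.250,
                                          "C*07:02" = 0.250,
                                          "B*40:01" = 0.219,
                                          "B*15:01" = 0.188,
                                          "C*03:02" = 0.156,
                                          "B*58:01" = 0.125,
                                          "A*33:03" = 0.125,
                                          "B*15:02" = 0.094),
                          stage_probs = c(T1a = 2, T2 = 7, T4a = 5,
                                          T4b = 18) / 32,
                          sex_prob_female = 11 / 32,
                          age_range = c(38, 80),
                          stage_effect = c(T1a = 1, T2 = 1, T4a = 1,
                                           T4b = 1),
                          protein_length_range = c(100, 800),
                          n_genes = 2000) {
  cfg <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
              burden_log_mean = burden_log_mean,
              burden_log_sd = burden_log_sd,
              hypermutator_prob = hypermutator_prob,
              hypermutator_scale = hypermutator_scale,
              hypermutator_tmb = hypermutator_tmb, exome_mb = exome_mb,
              spectrum_probs = spectrum_probs, indel_rate = indel_rate,
              allele_pool = allele_pool, stage_probs = stage_probs,
              sex_prob_female = sex_prob_female,
              age_range = as.integer(age_range),
              stage_effect = stage_effect,
              protein_length_range = as.integer(protein_length_range),
              n_genes = as.integer(n_genes))
  .validate_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

.validate_config <- function(cfg) {
  bad <- function(field, msg) {
    stop(sprintf("invalid cohort config: %s %s", field, msg), call. = FALSE)
  }
  if (is.na(cfg$n_patients) || cfg$n_patients < 2L) bad("n_patients", "must be >= 2")
  if (cfg$burden_log_sd <= 0) bad("burden_log_sd", "must be positive")
  probs <- c(hypermutator_prob = cfg$hypermutator_prob,
             sex_prob_female = cfg$sex_prob_female)
  for (nm in names(probs)) {
    if (probs[[nm]] < 0 || probs[[nm]] > 1) bad(nm, "must be in [0, 1]")
  }
  if (length(cfg$spectrum_probs) != 6L ||
      !setequal(names(cfg$spectrum_probs), SPECTRUM_CLASSES)) {
    bad("spectrum_probs", "must be named over the six substitution classes")
  }
  if (any(cfg$spectrum_probs < 0) ||
      abs(sum(cfg$spectrum_probs) - 1) > 1e-9) {
    bad("spectrum_probs", "must be non-negative and sum to 1")
  }
  if (any(cfg$allele_pool < 0) || any(cfg$allele_pool > 1) ||
      is.null(names(cfg$allele_pool))) {
    bad("allele_pool", "must be named probabilities in [0, 1]")
  }
  if (any(cfg$stage_probs < 0) || abs(sum(cfg$stage_probs) - 1) > 1e-9 ||
      is.null(names(cfg$stage_probs))) {
    bad("stage_probs", "must be named probabilities summing to 1")
  }
  if (!setequal(names(cfg$stage_effect), names(cfg$stage_probs)) ||
      any(cfg$stage_effect <= 0)) {
    bad("stage_effect", "must be positive and named per stage")
  }
  if (cfg$indel_rate < 0) bad("indel_rate", "must be >= 0")
  if (cfg$hypermutator_scale <= 1) bad("hypermutator_scale", "must exceed 1")
  if (length(cfg$age_range) != 2L || cfg$age_range[1L] > cfg$age_range[2L]) {
    bad("age_range", "must be an increasing pair")
  }
  if (length(cfg$protein_length_range) != 2L ||
      cfg$protein_length_range[1L] < 12L ||
      cfg$protein_length_range[1L] > cfg$protein_length_range[2L]) {
    bad("protein_length_range", "must be an increasing pair with minimum >= 12")
  }
  if (cfg$n_genes < 1L) bad("n_genes", "must be >= 1")
  invisible(cfg)
}

# truncated log-normal draws via resampling (bounded retries)
.rlnorm_trunc <- function(n, meanlog, sdlog, lower = 0, upper = Inf) {
  out <- numeric(n)
  todo <- seq_len(n)
  for (i in 1:1000) {
    draw <- stats::rlnorm(length(todo), meanlog, sdlog)
    ok <- draw > lower & draw < upper
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
    if (length(todo) == 0L) return(out)
  }
  stop("truncated log-normal sampling failed to converge", call. = FALSE)
}

#' Generate a synthetic cohort
#'
#' Draws a complete cohort from a [cohort_config()]: random protein models,
#' per-patient missense burden (log-normal with a hypermutator mixture),
#' substitution classes i.i.d. from the configured spectrum, Poisson indel
#' counts, independent-carrier HLA draws (guaranteeing at least one allele
#' per patient), and clinical covariates. Fully reproducible from the
#' config seed.
#'
#' @param config A `cohort_config`.
#' @param out_dir Optional directory; when given, the four standard files
#'   (`clinical.tsv`, `variants.tsv`, `proteins.fasta`, `hla.tsv`) are
#'   written there.
#' @return An object of class `synthetic_cohort`: list with `clinical`,
#'   `variants`, `proteins` (named character), `hla` (long data.frame),
#'   `config`, and `paths` when files were written.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 4, seed = 7,
#'                                         n_genes = 50))
#' table(cohort$variants$variant_class)
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  .validate_config(config)
  cohort <- .with_seed(config$seed, .generate_cohort_impl(config))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      clinical = file.path(out_dir, "clinical.tsv"),
      variants = file.path(out_dir, "variants.tsv"),
      proteins = file.path(out_dir, "proteins.fasta"),
      hla = file.path(out_dir, "hla.tsv"))
    .write_tsv(cohort$clinical, paths$clinical)
    write_variant_table(cohort$variants, paths$variants)
    write_protein_fasta(cohort$proteins, paths$proteins)
    hla_wide <- data.frame(
      patient_id = names(hla_genotypes(cohort$hla)),
      alleles = vapply(hla_genotypes(cohort$hla), paste, "",
                       collapse = ";"),
      stringsAsFactors = FALSE)
    .write_tsv(hla_wide, paths$hla)
    cohort$paths <- paths
  }
  cohort
}

.generate_cohort_impl <- function(config) {
  n <- config$n_patients
  patient_ids <- sprintf("SYN%04d", seq_len(n))

  # synthetic genome: random proteins keyed by gene symbol
  lens <- sample(seq(config$protein_length_range[1L],
                     config$protein_length_range[2L]),
                 config$n_genes, replace = TRUE)
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))
  proteins <- stats::setNames(vapply(lens, function(L) {
    paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
  }, ""), genes)

  # clinical covariates
  sex <- ifelse(stats::runif(n) < config$sex_prob_female, "F", "M")
  age <- sample(seq(config$age_range[1L], config$age_range[2L]), n,
                replace = TRUE)
  stage <- sample(names(config$stage_probs), n, replace = TRUE,
                  prob = config$stage_probs)
  tnm <- paste0(stage, "N", sample(0:3, n, replace = TRUE), "M0")
  neo_rate <- unname(config$stage_effect[stage])
  clinical <- data.frame(patient_id = patient_ids, sex = sex, age = age,
                         tnm = tnm, t_stage = stage, neo_rate = neo_rate,
                         stringsAsFactors = FALSE)

  # per-patient burden: disjoint mixture around the hypermutator boundary
  boundary <- config$hypermutator_tmb * config$exome_mb
  is_hyper <- stats::runif(n) < config$hypermutator_prob
  n_missense <- integer(n)
  for (i in seq_len(n)) {
    n_missense[i] <- if (is_hyper[i]) {
      round(.rlnorm_trunc(1, config$burden_log_mean +
                            log(config$hypermutator_scale),
                          config$burden_log_sd, lower = boundary))
    } else {
      max(1L, round(.rlnorm_trunc(1, config$burden_log_mean,
                                  config$burden_log_sd, upper = boundary)))
    }
  }

  # variants
  pyr_ref <- c("C>A" = "C", "C>G" = "C", "C>T" = "C",
               "T>A" = "T", "T>C" = "T", "T>G" = "T")
  pyr_alt <- c("C>A" = "A", "C>G" = "G", "C>T" = "T",
               "T>A" = "A", "T>C" = "C", "T>G" = "G")
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    m <- n_missense[i]
    gene <- sample(genes, m, replace = TRUE)
    plen <- nchar(proteins[gene])
    pos <- vapply(plen, function(L) sample.int(L, 1L), 1L)
    ref_aa <- substring(proteins[gene], pos, pos)
    alt_aa <- vapply(ref_aa, function(r) {
      sample(setdiff(AA_ALPHABET, r), 1L)
    }, "", USE.NAMES = FALSE)
    cls <- sample(SPECTRUM_CLASSES, m, replace = TRUE,
                  prob = config$spectrum_probs[SPECTRUM_CLASSES])
    flip <- stats::runif(m) < 0.5  # report on the purine strand half the time
    ref_base <- ifelse(flip, .COMPLEMENT[pyr_ref[cls]], pyr_ref[cls])
    alt_base <- ifelse(flip, .COMPLEMENT[pyr_alt[cls]], pyr_alt[cls])
    k <- stats::rpois(1L, config$indel_rate * m)
    mis <- data.frame(patient_id = patient_ids[i], gene = gene,
                      variant_class = "missense",
                      ref_base = unname(ref_base), alt_base = unname(alt_base),
                      ref_aa = unname(ref_aa), protein_pos = pos,
                      alt_aa = alt_aa, stringsAsFactors = FALSE)
    ind <- if (k > 0L) {
      data.frame(patient_id = patient_ids[i],
                 gene = sample(genes, k, replace = TRUE),
                 variant_class = "indel", ref_base = NA_character_,
                 alt_base = NA_character_, ref_aa = NA_character_,
                 protein_pos = NA_integer_, alt_aa = NA_character_,
                 stringsAsFactors = FALSE)
    } else NULL
    rows[[i]] <- rbind(mis, ind)
  }
  variants <- do.call(rbind, rows)
  rownames(variants) <- NULL
  variants$protein_change <- format_protein_change(variants$ref_aa,
                                                   variants$protein_pos,
                                                   variants$alt_aa)
  .validate_variants(variants)

  # HLA: independent carrier draws, at least one allele guaranteed
  pool <- config$allele_pool
  hla_rows <- lapply(seq_len(n), function(i) {
    carried <- names(pool)[stats::runif(length(pool)) < pool]
    if (length(carried) == 0L) {
      carried <- sample(names(pool), 1L, prob = pmax(pool, 1e-12))
    }
    data.frame(patient_id = patient_ids[i], allele = sort(carried),
               stringsAsFactors = FALSE)
  })
  hla <- do.call(rbind, hla_rows)
  rownames(hla) <- NULL

  structure(list(clinical = clinical, variants = variants,
                 proteins = proteins, hla = hla, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort: %d patients, %d variants (%d missense), %d genes, seed=%d>\n",
    nrow(x$clinical), nrow(x$variants),
    sum(x$variants$variant_class == "missense"), length(x$proteins),
    x$config$seed))
  invisible(x)
}

#' Parameter-recovery checks for the synthetic generator
#'
#' Generates a cohort, runs the full pipeline on it (peptide enumeration,
#' mock-predictor binding calls, per-patient summaries) and checks that the
#' configured parameters are recovered: the median missense burden within
#' three standard errors of the log-normal median, every configured carrier
#' frequency within three binomial standard errors, and — when the
#' configured stage effect is constant — an R-squared above 0.5 for the
#' missense-versus-neoantigen fit (the mechanism by which mutation burden
#' drives neoantigen burden).
#'
#' @param config A `cohort_config`.
#' @param weak_nm,strong_nm Thresholds for the mock-predictor calls.
#' @return Data.frame with columns `check`, `observed`, `expected`,
#'   `tolerance`, `pass`.
#' @export
parameter_recovery_suite <- function(config = cohort_config(),
                                     weak_nm = 500, strong_nm = 100) {
  cohort <- generate_cohort(config)
  candidates <- peptides_for_variants(cohort$variants, cohort$proteins)
  predictor <- mock_predictor(config$seed)
  keep_prob <- NULL
  constant_effect <- length(unique(config$stage_effect)) == 1L
  if (!constant_effect) {
    rate <- config$stage_effect / max(config$stage_effect)
    keep_prob <- stats::setNames(rate[cohort$clinical$t_stage],
                                 cohort$clinical$patient_id)
  }
  calls <- .with_seed(config$seed + 1L,
                      call_neoantigens_cohort(candidates, cohort$hla,
                                              predictor, weak_nm, strong_nm,
                                              keep_prob = keep_prob))
  summaries <- summarize_patients(cohort$variants, calls, cohort$clinical,
                                  exome_mb = config$exome_mb,
                                  hypermutator_tmb = config$hypermutator_tmb)

  n <- config$n_patients
  checks <- list()

  # median burden on the log scale; SE of a log-normal sample median
  obs_med <- stats::median(summaries$n_missense)
  tol_log <- 3 * 1.2533 * config$burden_log_sd / sqrt(n)
  checks[["median_missense"]] <- data.frame(
    check = "median missense (log scale)",
    observed = log(obs_med), expected = config$burden_log_mean,
    tolerance = tol_log,
    pass = abs(log(obs_med) - config$burden_log_mean) <= tol_log)

  # carrier frequencies within 3 binomial SEs
  freq <- hla_carrier_frequencies(cohort$hla)
  for (al in names(config$allele_pool)) {
    p <- config$allele_pool[[al]]
    obs <- if (al %in% freq$allele) freq$frequency[freq$allele == al] else 0
    se <- sqrt(p * (1 - p) / n)
    # the at-least-one-allele guarantee can only raise the rarest frequencies
    tol <- max(3 * se, 1 / n)
    checks[[al]] <- data.frame(
      check = paste("carrier frequency", al),
      observed = obs, expected = p, tolerance = tol,
      pass = abs(obs - p) <= tol)
  }

  if (constant_effect && n >= 3L) {
    fit <- fit_linear(summaries$n_missense, summaries$n_neoantigen)
    checks[["r_squared"]] <- data.frame(
      check = "missense vs neoantigen R-squared (constant stage effect)",
      observed = fit$r_squared, expected = 0.5, tolerance = NA_real_,
      pass = fit$r_squared > 0.5)
  }

  out <- do.call(rbind, checks)
  rownames(out) <- NULL
  out
}
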