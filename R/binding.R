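# Pluggable MHC class-I binding prediction and threshold-based neoantigen
# calling. The predictor contract abstracts whatever produces IC50 values:
# a deterministic mock for tests and simulations, or a lookup table built
# from the output of an external predictor run by the user. The mock is
# non-biological by construction and is labelled as such in every output;
# results intended for interpretation must come from a real predictor's
# affinities via the table-backed contract.

#' Construct a binding-predictor contract
#'
#' A predictor is a callable surface mapping (peptide, allele) pairs to
#' predicted IC50 (nM), together with a determinism declaration and the set
#' of alleles it covers (`NULL` = unrestricted).
#'
#' @param predict_fun Vectorized function `(peptides, alleles) -> numeric`
#'   IC50 in nM.
#' @param deterministic Logical; same pair always yields the same value.
#' @param alleles Character vector of supported alleles, or `NULL`.
#' @param label Short human-readable provenance label.
#' @return An object of class `binding_predictor`.
#' @export
binding_predictor <- function(predict_fun, deterministic = TRUE,
                              alleles = NULL, label = "custom") {
  stopifnot(is.function(predict_fun))
  structure(list(predict_fun = predict_fun,
                 deterministic = isTRUE(deterministic),
                 alleles = alleles, label = label),
            class = "binding_predictor")
}

#' @export
print.binding_predictor <- function(x, ...) {
  cat(sprintf("<binding_predictor: %s; deterministic=%s; alleles=%s>\n",
              x$label, x$deterministic,
              if (is.null(x$alleles)) "any" else length(x$alleles)))
  invisible(x)
}

#' Predict IC50 values through a predictor contract
#'
#' @param predictor A `binding_predictor`.
#' @param peptides,alleles Character vectors (recycled to common length).
#' @return Numeric vector of IC50 (nM).
#' @export
predict_ic50 <- function(predictor, peptides, alleles) {
  stopifnot(inherits(predictor, "binding_predictor"))
  n <- max(length(peptides), length(alleles))
  peptides <- rep_len(peptides, n)
  alleles <- rep_len(alleles, n)
  if (!is.null(predictor$alleles)) {
    missing <- setdiff(unique(alleles), predictor$alleles)
    if (length(missing) > 0L) {
      stop(sprintf("predictor '%s' does not cover allele(s): %s",
                   predictor$label, paste(missing, collapse = ", ")),
           call. = FALSE)
    }
  }
  out <- predictor$predict_fun(peptides, alleles)
  if (any(!is.finite(out)) || any(out <= 0)) {
    stop("predictor returned non-positive or non-finite IC50", call. = FALSE)
  }
  out
}

# Deterministic polynomial string hash onto [0, 1). Coefficients stay below
# 2^53 so double arithmetic is exact.
.MOD <- 2147483647
.HASH_POW <- local({
  w <- numeric(64)
  w[1] <- 1
  for (k in 2:64) w[k] <- (w[k - 1] * 131) %% .MOD
  w
})

.hash01 <- function(x) {
  vapply(x, function(s) {
    ints <- utf8ToInt(s)
    k <- length(ints)
    (sum(ints * .HASH_POW[seq_len(k)]) %% .MOD) / .MOD
  }, numeric(1), USE.NAMES = FALSE)
}

#' Deterministic mock binding predictor
#'
#' A seeded, fully reproducible stand-in for an external MHC-binding
#' predictor, intended for tests and synthetic-cohort simulation. The score
#' combines per-residue weights at the two classical anchor positions
#' (position 2 and the C-terminus) drawn once from the seed, with a
#' hash-derived peptide-allele perturbation, mapped onto an IC50 scale
#' spanning roughly 1-50,000 nM so that both the weak (500 nM) and strong
#' (100 nM) thresholds are exercised. Identical (seed, peptide, allele)
#' always yields the identical IC50. The scores carry no biology; outputs
#' are labelled accordingly.
#'
#' @param seed Integer seed.
#' @return A `binding_predictor`.
#' @examples
#' p <- mock_predictor(1)
#' predict_ic50(p, "SIINFEKL", "A*02:01")
#' @export
mock_predictor <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  weights <- local({
    state <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(state))
      assign(".Random.seed", state, envir = globalenv()))
    set.seed(as.integer(seed) %% .MOD)
    matrix(stats::rnorm(40), nrow = 20,
           dimnames = list(AA_ALPHABET, c("p2", "cterm")))
  })
  seed_tag <- sprintf("#%d#", as.integer(seed) %% .MOD)
  predict_fun <- function(peptides, alleles) {
    aa2 <- substr(peptides, 2L, 2L)
    aaC <- substr(peptides, nchar(peptides), nchar(peptides))
    base <- weights[aa2, "p2"] + weights[aaC, "cterm"]
    pert <- .hash01(paste0(seed_tag, peptides, "|", alleles))
    log10_ic50 <- 2.3 + 0.75 * base + 3 * (pert - 0.5)
    ic50 <- 10^pmin(pmax(log10_ic50, 0), log10(50000))
    pmax(ic50, 1)
  }
  binding_predictor(predict_fun, deterministic = TRUE, alleles = NULL,
                    label = sprintf("mock (non-biological, seed=%d)",
                                    as.integer(seed)))
}

#' Lookup-backed predictor from a precomputed affinity table
#'
#' Builds a predictor from affinities computed by a real external tool
#' (e.g. a neural MHC-binding predictor run outside this package). Input is
#' a TSV or data.frame with columns `peptide`, `allele`, `ic50_nm`. Queries
#' for pairs absent from the table raise an explicit not-covered error;
#' there is no silent default.
#'
#' @param x Path to a TSV file, or a data.frame.
#' @return A `binding_predictor` whose `alleles` field lists the table's
#'   alleles.
#' @export
affinity_table_predictor <- function(x) {
  df <- if (is.character(x)) {
    .assert_file(x, "affinity table")
    .read_tsv(x)
  } else as.data.frame(x, stringsAsFactors = FALSE)
  .require_columns(df, c("peptide", "allele", "ic50_nm"), "affinity table")
  df$peptide <- toupper(as.character(df$peptide))
  df$allele <- normalize_hla_allele(df$allele)
  df$ic50_nm <- as.numeric(df$ic50_nm)
  if (any(!is.finite(df$ic50_nm)) || any(df$ic50_nm <= 0)) {
    stop("affinity table: ic50_nm must be positive", call. = FALSE)
  }
  bad_len <- nchar(df$peptide) < 8L | nchar(df$peptide) > 11L
  bad_alpha <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")),
                     df$peptide)
  if (any(bad_len | bad_alpha)) {
    stop(sprintf("affinity table: invalid peptide(s): %s",
                 paste(unique(df$peptide[bad_len | bad_alpha]),
                       collapse = ", ")), call. = FALSE)
  }
  key <- paste(df$peptide, df$allele, sep = "|")
  dup <- duplicated(key)
  if (any(dup)) {
    conflict <- vapply(unique(key[dup]), function(k) {
      length(unique(df$ic50_nm[key == k])) > 1L
    }, TRUE)
    if (any(conflict)) {
      stop(sprintf("affinity table: conflicting duplicate pair(s): %s",
                   paste(unique(key[dup])[conflict], collapse = ", ")),
           call. = FALSE)
    }
    df <- df[!dup, , drop = FALSE]
    key <- key[!dup]
  }
  lut <- stats::setNames(df$ic50_nm, key)
  predict_fun <- function(peptides, alleles) {
    q <- paste(toupper(peptides), normalize_hla_allele(alleles), sep = "|")
    hit <- match(q, names(lut))
    if (anyNA(hit)) {
      stop(sprintf("affinity table does not cover pair(s): %s",
                   paste(unique(q[is.na(hit)]), collapse = ", ")),
           call. = FALSE)
    }
    unname(lut[hit])
  }
  binding_predictor(predict_fun, deterministic = TRUE,
                    alleles = sort(unique(df$allele)),
                    label = "affinity table")
}

#' Call neoantigens from peptide candidates and an HLA genotype
#'
#' Scores every (candidate peptide x genotype allele) pair through the
#' predictor and keeps pairs with IC50 at or below the weak-binder
#' threshold; pairs below the strong threshold are additionally flagged as
#' strong binders. The counting unit is the distinct (peptide, allele)
#' pair: the same mutation can therefore yield different neoantigen counts
#' in patients with different genotypes.
#'
#' @param candidates Data.frame with a `peptide` column (provenance columns
#'   such as `gene`, `protein_change`, `patient_id` are carried through),
#'   e.g. from [enumerate_mutant_peptides()] or [peptides_for_variants()].
#' @param alleles Character vector: the patient's class-I allele set.
#' @param predictor A `binding_predictor`.
#' @param weak_nm Weak-binder (neoantigen) cutoff in nM; calls satisfy
#'   `ic50 <= weak_nm`. Default 500 nM, the conventional binder cutoff.
#' @param strong_nm Strong-binder cutoff in nM; `ic50 < strong_nm`.
#' @return Data.frame of calls sorted by ascending IC50 with columns of
#'   `candidates` plus `allele`, `ic50_nm`, `is_strong`; thresholds and
#'   predictor label attached as attributes `weak_nm`, `strong_nm`,
#'   `predictor`.
#' @export
call_neoantigens <- function(candidates, alleles, predictor,
                             weak_nm = 500, strong_nm = 100) {
  stopifnot(weak_nm > 0, strong_nm > 0)
  alleles <- unique(normalize_hla_allele(alleles))
  if (length(alleles) == 0L) {
    stop("empty HLA genotype: a patient without typed alleles cannot be profiled",
         call. = FALSE)
  }
  candidates <- as.data.frame(candidates, stringsAsFactors = FALSE)
  if (!("peptide" %in% names(candidates))) {
    stop("candidates must have a 'peptide' column", call. = FALSE)
  }
  idx <- rep(seq_len(nrow(candidates)), times = length(alleles))
  pairs <- candidates[idx, , drop = FALSE]
  pairs$allele <- rep(alleles, each = nrow(candidates))
  if (nrow(pairs) > 0L) {
    pairs$ic50_nm <- predict_ic50(predictor, pairs$peptide, pairs$allele)
  } else {
    pairs$ic50_nm <- numeric(0)
  }
  keep <- pairs$ic50_nm <= weak_nm
  out <- pairs[keep, , drop = FALSE]
  out$is_strong <- out$ic50_nm < strong_nm
  out <- out[order(out$ic50_nm, out$peptide, out$allele), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "weak_nm") <- weak_nm
  attr(out, "strong_nm") <- strong_nm
  attr(out, "predictor") <- predictor$label
  out
}

#' Call neoantigens for every patient in a cohort
#'
#' Applies [call_neoantigens()] per patient, pairing each patient's
#' candidate peptides with their own genotype.
#'
#' @param candidates Candidate data.frame with a `patient_id` column.
#' @param hla Long HLA data.frame (`patient_id`, `allele`) from
#'   [read_hla_table()].
#' @param predictor,weak_nm,strong_nm See [call_neoantigens()].
#' @param keep_prob Optional named numeric vector (by patient) of call
#'   retention probabilities in `[0, 1]` used by the simulation harness to
#'   impose per-patient neoantigen-rate differences; sampling is driven by
#'   the current RNG state. Default `NULL` keeps every call.
#' @return Combined call data.frame across patients.
#' @export
call_neoantigens_cohort <- function(candidates, hla, predictor,
                                    weak_nm = 500, strong_nm = 100,
                                    keep_prob = NULL) {
  genotypes <- hla_genotypes(hla)
  patients <- intersect(unique(candidates$patient_id), names(genotypes))
  missing <- setdiff(unique(candidates$patient_id), names(genotypes))
  if (length(missing) > 0L) {
    stop(sprintf("no HLA genotype for patient(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  rows <- lapply(patients, function(pid) {
    calls <- call_neoantigens(
      candidates[candidates$patient_id == pid, , drop = FALSE],
      genotypes[[pid]], predictor, weak_nm, strong_nm)
    if (!is.null(keep_prob) && nrow(calls) > 0L) {
      p <- keep_prob[[pid]]
      if (!is.null(p) && is.finite(p) && p < 1) {
        calls <- calls[stats::runif(nrow(calls)) < p, , drop = FALSE]
      }
    }
    calls
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(patient_id = character(0), peptide = character(0),
                      allele = character(0), ic50_nm = numeric(0),
                      is_strong = logical(0))
  }
  rownames(out) <- NULL
  attr(out, "weak_nm") <- weak_nm
  attr(out, "strong_nm") <- strong_nm
  attr(out, "predictor") <- predictor$label
  out
}
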