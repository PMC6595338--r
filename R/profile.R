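# End-to-end orchestration: run every stage of the profiling analysis on a
# set of input files (or in-memory tables), write the report bundle, and
# record a manifest of thresholds, seed and input checksums. A
# "summaries precomputed" mode accepts a per-patient summary table directly
# and drives only the statistics layer — the route used when per-patient
# neoantigen counts come from an external predictor rather than from
# peptide scoring inside this package.

#' @importFrom tools md5sum
NULL

.maybe_read <- function(x, reader) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

#' Run the full cohort profiling analysis
#'
#' Executes the pipeline — per-patient summaries and TMB, substitution
#' spectrum, recurrent genes (optionally intersected with a cancer gene
#' census), HLA carrier frequencies, peptide enumeration and neoantigen
#' calling, and the clinical association report — and optionally writes
#' every result as TSV together with a run manifest.
#'
#' Two modes:
#' \describe{
#'   \item{full}{supply `variants`, `clinical`, `hla`, `proteins` and a
#'     `predictor` (or `affinity_table`); neoantigen counts are computed by
#'     scoring enumerated peptides.}
#'   \item{summaries precomputed}{supply `summaries` (with covariates and
#'     `n_missense`/`n_indel`/`n_neoantigen` columns); the binding stages
#'     are skipped and the statistics layer runs on the given counts.
#'     `variants` may still be supplied for spectrum/recurrence.}
#' }
#'
#' @param variants Variant table: path or data.frame.
#' @param clinical Clinical table: path or data.frame.
#' @param hla HLA genotype table: path or long data.frame.
#' @param proteins Protein FASTA path or named character vector.
#' @param census Optional cancer-gene list: path or character vector.
#' @param predictor Optional `binding_predictor`; defaults to
#'   `mock_predictor(seed)` when binding inputs are present and no
#'   `affinity_table` is given.
#' @param affinity_table Optional path/data.frame of precomputed
#'   affinities; takes precedence over `predictor`.
#' @param summaries Optional precomputed per-patient summary table (path
#'   or data.frame): activates the precomputed mode.
#' @param out_dir Optional output directory for the report bundle.
#' @param weak_nm,strong_nm IC50 thresholds in nM (defaults 500 / 100).
#' @param min_patients Recurrence threshold (default 3).
#' @param exome_mb Exome size for TMB (default 30).
#' @param seed Seed for the default mock predictor.
#' @return A list of class `cohort_profile` with elements `summaries`,
#'   `spectrum`, `recurrence`, `census_hits`, `hla_frequencies`, `calls`,
#'   `neoantigen_recurrence`, `association`, `fit`, `manifest` (absent
#'   stages are `NULL`).
#' @export
profile_cohort <- function(variants = NULL, clinical = NULL, hla = NULL,
                           proteins = NULL, census = NULL,
                           predictor = NULL, affinity_table = NULL,
                           summaries = NULL, out_dir = NULL,
                           weak_nm = 500, strong_nm = 100,
                           min_patients = 3, exome_mb = 30, seed = 1) {
  stopifnot(weak_nm > 0, strong_nm > 0, min_patients >= 1, exome_mb > 0)
  inputs <- list(variants = variants, clinical = clinical, hla = hla,
                 proteins = proteins, census = census,
                 affinity_table = affinity_table, summaries = summaries)

  variants <- .maybe_read(variants, read_variant_table)
  clinical <- .maybe_read(clinical, read_clinical_table)
  hla <- .maybe_read(hla, read_hla_table)
  proteins <- .maybe_read(proteins, read_protein_fasta)
  summaries <- .maybe_read(summaries, function(p) {
    df <- .read_tsv(p)
    for (cn in intersect(c("age", "n_missense", "n_indel", "n_neoantigen"),
                         names(df))) df[[cn]] <- as.integer(df[[cn]])
    if (!("t_stage" %in% names(df)) && "tnm" %in% names(df)) {
      df$t_stage <- parse_t_stage(df$tnm)
    }
    df
  })
  if (!is.null(affinity_table)) {
    predictor <- affinity_table_predictor(affinity_table)
  }

  res <- list()

  calls <- NULL
  if (is.null(summaries)) {
    if (is.null(variants) || is.null(clinical)) {
      stop("full mode requires 'variants' and 'clinical' ",
           "(or supply precomputed 'summaries')", call. = FALSE)
    }
    if (!is.null(hla) && !is.null(proteins)) {
      if (is.null(predictor)) predictor <- mock_predictor(seed)
      candidates <- peptides_for_variants(variants, proteins,
                                          on_mismatch = "skip")
      calls <- call_neoantigens_cohort(candidates, hla, predictor,
                                       weak_nm, strong_nm)
    }
    summaries <- summarize_patients(variants, calls, clinical,
                                    exome_mb = exome_mb)
  }
  res$summaries <- summaries
  res$calls <- calls

  if (!is.null(variants)) {
    res$spectrum <- spectrum_summary(variants)
    cohort_size <- if (!is.null(clinical)) nrow(clinical)
                   else length(unique(variants$patient_id))
    res$recurrence <- recurrent_genes(variants, min_patients,
                                      cohort_size = cohort_size)
    if (!is.null(census)) {
      res$census_hits <- intersect_census(res$recurrence, census)
    }
  }
  if (!is.null(hla)) {
    res$hla_frequencies <- hla_carrier_frequencies(hla)
  }
  if (!is.null(calls) && nrow(calls) > 0L && "gene" %in% names(calls)) {
    res$neoantigen_recurrence <- neoantigen_gene_recurrence(calls,
                                                            min_patients)
  }

  if (all(c("sex", "age", "t_stage", "n_neoantigen") %in% names(summaries)) &&
      !all(is.na(summaries$n_neoantigen))) {
    assoc <- do.call(rbind, lapply(c("age45", "sex", "t_stage"),
                                   function(g) subgroup_report(summaries, g)))
    res$association <- assoc
    res$fit <- fit_linear(summaries$n_missense, summaries$n_neoantigen)
  }

  res$manifest <- .run_manifest(inputs, weak_nm, strong_nm, min_patients,
                                exome_mb, seed,
                                if (is.null(predictor)) "none" else
                                  predictor$label)
  class(res) <- "cohort_profile"
  if (!is.null(out_dir)) .write_profile_bundle(res, out_dir)
  res
}

.run_manifest <- function(inputs, weak_nm, strong_nm, min_patients,
                          exome_mb, seed, predictor_label) {
  rows <- list(
    data.frame(key = "weak_nm", value = as.character(weak_nm)),
    data.frame(key = "strong_nm", value = as.character(strong_nm)),
    data.frame(key = "min_patients", value = as.character(min_patients)),
    data.frame(key = "exome_mb", value = as.character(exome_mb)),
    data.frame(key = "seed", value = as.character(seed)),
    data.frame(key = "predictor", value = predictor_label))
  for (nm in names(inputs)) {
    x <- inputs[[nm]]
    if (is.character(x) && length(x) == 1L && file.exists(x)) {
      rows[[length(rows) + 1L]] <-
        data.frame(key = paste0("md5_", nm), value = unname(md5sum(x)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.write_profile_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(df, file) {
    if (!is.null(df)) .write_tsv(df, file.path(out_dir, file))
  }
  emit(res$summaries, "patient_summaries.tsv")
  if (!is.null(res$spectrum)) {
    emit(as.data.frame(res$spectrum), "spectrum.tsv")
  }
  emit(res$recurrence, "gene_recurrence.tsv")
  emit(res$census_hits, "census_genes.tsv")
  emit(res$hla_frequencies, "hla_frequencies.tsv")
  emit(res$calls, "neoantigen_calls.tsv")
  if (!is.null(res$neoantigen_recurrence)) {
    mat <- res$neoantigen_recurrence
    df <- data.frame(gene = rownames(mat), as.data.frame(mat),
                     check.names = FALSE)
    emit(df, "neoantigen_gene_matrix.tsv")
  }
  emit(res$association, "association_report.tsv")
  if (!is.null(res$fit)) {
    emit(data.frame(slope = res$fit$slope, intercept = res$fit$intercept,
                    r_squared = res$fit$r_squared, n = res$fit$n),
         "linear_fit.tsv")
  }
  emit(res$manifest, "manifest.tsv")
  invisible(out_dir)
}

#' @export
print.cohort_profile <- function(x, ...) {
  cat("<cohort_profile>\n")
  cat(sprintf("  patients: %d\n", nrow(x$summaries)))
  if (!is.null(x$fit)) {
    cat(sprintf("  missense~neoantigen R^2: %.4f\n", x$fit$r_squared))
  }
  if (!is.null(x$association)) {
    cat(sprintf("  association comparisons: %d\n", nrow(x$association)))
  }
  invisible(x)
}

#' Materialize the packaged reference fixtures as TSV files
#'
#' Writes the two packaged reference-cohort tables (32-patient summary;
#' 25-row driver-mutation list) into a directory for inspection or reuse.
#' Output is byte-identical across reruns.
#'
#' @param out_dir Writable directory.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_fixture_tables <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  src <- c(patient_summary = "gc32_patient_summary.tsv",
           driver_mutations = "gc32_driver_mutations.tsv")
  out <- vapply(src, function(f) {
    from <- system.file("extdata", f, package = "neoprofiler",
                        mustWork = TRUE)
    to <- file.path(out_dir, f)
    if (!file.copy(from, to, overwrite = TRUE)) {
      stop(sprintf("cannot write %s", to), call. = FALSE)
    }
    to
  }, "")
  invisible(out)
}
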