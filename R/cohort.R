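# Cohort-level summaries: per-patient mutation and neoantigen counts with
# tumor mutation burden, recurrent-gene filtering, cancer-gene-census
# intersection, HLA carrier frequencies and gene-by-patient incidence
# matrices. Recurrence counts patients, not mutations: a gene hit eight
# times in one patient still contributes one carrier.

#' Per-patient mutation and neoantigen summaries
#'
#' Counts missense mutations, indels and distinct neoantigen calls per
#' patient, computes tumor mutation burden as missense count divided by the
#' interrogated exome size, and flags hypermutators (TMB above
#' `hypermutator_tmb`). Patients present in the clinical table but without
#' variants get zero counts; variants or calls for patients absent from the
#' clinical table are an error.
#'
#' @param variants Variant data.frame.
#' @param calls Neoantigen call data.frame with `patient_id`, `peptide`,
#'   `allele` (e.g. from [call_neoantigens_cohort()]), or `NULL` for
#'   mutation-only summaries.
#' @param clinical Clinical data.frame (see [read_clinical_table()]).
#' @param exome_mb Interrogated exome size in megabases. The default 30
#'   corresponds to a standard whole-exome capture under the convention
#'   that pairs a median of 138 missense mutations with a median TMB of
#'   4.6 mutations/Mb.
#' @param hypermutator_tmb TMB threshold (mutations/Mb) above which a
#'   patient is flagged as a hypermutator; default 40.
#' @return Data.frame with `patient_id`, clinical covariates, `n_missense`,
#'   `n_indel`, `n_neoantigen`, `tmb`, `hypermutator`.
#' @export
summarize_patients <- function(variants, calls = NULL, clinical,
                               exome_mb = 30, hypermutator_tmb = 40) {
  stopifnot(exome_mb > 0)
  ids <- clinical$patient_id
  orphans <- setdiff(unique(variants$patient_id), ids)
  if (!is.null(calls)) {
    orphans <- union(orphans, setdiff(unique(calls$patient_id), ids))
  }
  if (length(orphans) > 0L) {
    stop(sprintf("patient_id(s) absent from clinical table: %s",
                 paste(sort(orphans), collapse = ", ")), call. = FALSE)
  }
  fid <- function(x) factor(x, levels = ids)
  n_missense <- as.integer(table(fid(
    variants$patient_id[variants$variant_class == "missense"])))
  n_indel <- as.integer(table(fid(
    variants$patient_id[variants$variant_class == "indel"])))
  n_neo <- if (is.null(calls)) {
    rep(NA_integer_, length(ids))
  } else {
    key <- !duplicated(paste(calls$patient_id, calls$peptide, calls$allele,
                             sep = "\r"))
    as.integer(table(fid(calls$patient_id[key])))
  }
  out <- clinical
  out$n_missense <- n_missense
  out$n_indel <- n_indel
  out$n_neoantigen <- n_neo
  out$tmb <- n_missense / exome_mb
  out$hypermutator <- out$tmb > hypermutator_tmb
  out
}

#' Recurrently mutated genes
#'
#' Filters genes with at least one missense mutation in at least
#' `min_patients` distinct patients. `fraction` is the carrier fraction of
#' the cohort; `total_mutations` counts missense records.
#'
#' @param variants Variant data.frame.
#' @param min_patients Minimum number of distinct mutated patients
#'   (default 3).
#' @param cohort_size Number of patients in the cohort; defaults to the
#'   number of distinct patients in `variants`. Supply explicitly when some
#'   patients carry no variants.
#' @return Data.frame with `gene`, `n_patients`, `fraction`,
#'   `total_mutations`, sorted by `n_patients` descending then symbol.
#' @export
recurrent_genes <- function(variants, min_patients = 3,
                            cohort_size = length(unique(variants$patient_id))) {
  stopifnot(min_patients >= 1, cohort_size >= 1)
  v <- variants[variants$variant_class == "missense", , drop = FALSE]
  if (nrow(v) == 0L) {
    return(data.frame(gene = character(0), n_patients = integer(0),
                      fraction = numeric(0), total_mutations = integer(0)))
  }
  per_gene_patients <- tapply(v$patient_id, v$gene,
                              function(x) length(unique(x)))
  per_gene_total <- tapply(v$patient_id, v$gene, length)
  genes <- names(per_gene_patients)
  out <- data.frame(gene = genes,
                    n_patients = as.integer(per_gene_patients),
                    fraction = as.integer(per_gene_patients) / cohort_size,
                    total_mutations = as.integer(per_gene_total),
                    stringsAsFactors = FALSE)
  out <- out[out$n_patients >= min_patients, , drop = FALSE]
  out <- out[order(-out$n_patients, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect a recurrence table with a cancer gene census
#'
#' Keeps the recurrent genes present in the census list; symbol matching is
#' exact but case-insensitive.
#'
#' @param recurrence Data.frame from [recurrent_genes()].
#' @param census Character vector of census symbols, or a path readable by
#'   [read_gene_list()].
#' @return The subset of `recurrence` found in the census, with an
#'   `in_census` column set to `TRUE`.
#' @export
intersect_census <- function(recurrence, census) {
  if (is.character(census) && length(census) == 1L && file.exists(census)) {
    census <- read_gene_list(census)
  }
  census <- as.character(census)
  if (length(census) == 0L) {
    stop("empty cancer gene census", call. = FALSE)
  }
  hit <- toupper(recurrence$gene) %in% toupper(census)
  out <- recurrence[hit, , drop = FALSE]
  out$in_census <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' HLA allele carrier frequencies
#'
#' Fraction of patients carrying each allele at least once (set semantics;
#' homozygosity does not double-count).
#'
#' @param hla Long data.frame (`patient_id`, `allele`) or a named list of
#'   allele sets as from [hla_genotypes()].
#' @return Data.frame with `allele`, `n_carriers`, `frequency`, sorted by
#'   descending frequency then allele.
#' @export
hla_carrier_frequencies <- function(hla) {
  if (is.list(hla) && !is.data.frame(hla)) {
    hla <- data.frame(
      patient_id = rep(names(hla), lengths(hla)),
      allele = unlist(hla, use.names = FALSE),
      stringsAsFactors = FALSE)
  }
  n_patients <- length(unique(hla$patient_id))
  if (n_patients == 0L) {
    stop("need at least one genotype", call. = FALSE)
  }
  pairs <- unique(hla[, c("patient_id", "allele")])
  counts <- table(pairs$allele)
  out <- data.frame(allele = names(counts),
                    n_carriers = as.integer(counts),
                    frequency = as.integer(counts) / n_patients,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$allele), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene-by-patient incidence matrix
#'
#' Mutation counts (missense records) per gene per patient; row sums equal
#' each gene's `total_mutations` in [recurrent_genes()].
#'
#' @param variants Variant data.frame.
#' @param genes Genes to include (rows); default all mutated genes.
#' @param patients Patients to include (columns); default all patients in
#'   `variants`.
#' @return Integer matrix, genes by patients.
#' @export
incidence_matrix <- function(variants,
                             genes = NULL, patients = NULL) {
  v <- variants[variants$variant_class == "missense", , drop = FALSE]
  if (is.null(genes)) genes <- sort(unique(v$gene))
  if (is.null(patients)) patients <- sort(unique(variants$patient_id))
  tab <- table(factor(v$gene, levels = genes),
               factor(v$patient_id, levels = patients))
  mat <- matrix(as.integer(tab), nrow = length(genes),
                dimnames = list(genes, patients))
  mat
}

#' Recurrence of neoantigen-encoding genes
#'
#' Filters genes whose neoantigen-bearing mutations occur in at least
#' `min_patients` distinct patients, and returns the gene-by-patient matrix
#' of neoantigen call counts for the retained genes (heatmap-ready). Calls
#' must carry gene provenance (a `gene` column, as produced when candidates
#' come from [peptides_for_variants()]).
#'
#' @param calls Call data.frame with `patient_id`, `gene`, `peptide`,
#'   `allele`.
#' @param min_patients Minimum distinct patients per gene (default 3).
#' @return Integer matrix of call counts, one row per retained gene
#'   (ordered by carrier count descending then symbol), one column per
#'   patient present in `calls`; carrier counts attached as attribute
#'   `n_patients`.
#' @export
neoantigen_gene_recurrence <- function(calls, min_patients = 3) {
  .require_columns(calls, c("patient_id", "gene", "peptide", "allele"),
                   "neoantigen calls")
  key <- !duplicated(paste(calls$patient_id, calls$gene, calls$peptide,
                           calls$allele, sep = "\r"))
  u <- calls[key, , drop = FALSE]
  patients <- sort(unique(u$patient_id))
  carriers <- tapply(u$patient_id, u$gene, function(x) length(unique(x)))
  keep <- names(carriers)[carriers >= min_patients]
  keep <- keep[order(-carriers[keep], keep)]
  tab <- table(factor(u$gene, levels = keep),
               factor(u$patient_id, levels = patients))
  mat <- matrix(as.integer(tab), nrow = length(keep),
                dimnames = list(keep, patients))
  attr(mat, "n_patients") <- as.integer(carriers[keep])
  mat
}
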