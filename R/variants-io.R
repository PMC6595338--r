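# Readers, writers and validation for the tabular inputs: somatic variant
# tables, clinical covariates, HLA class-I genotypes, gene lists and protein
# FASTA. All tabular formats are tab-delimited UTF-8 with a header row.

#' @importFrom utils read.delim write.table
NULL

# The 20 canonical amino acids, single-letter code.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

VARIANT_CLASSES <- c("missense", "indel")

.assert_file <- function(path, what) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, paste(path, collapse = ", ")),
         call. = FALSE)
  }
  invisible(path)
}

.read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, colClasses = "character",
             na.strings = c("NA", ""))
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "", fileEncoding = "UTF-8")
  invisible(path)
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Parse compact protein-change notation
#'
#' Parses mutation strings such as `"T96S"` (reference residue, 1-based
#' position, alternate residue) into their components. This compact form is
#' the canonical interchange notation for missense changes throughout the
#' package.
#'
#' @param x Character vector of protein changes; `NA` entries propagate.
#' @return A data.frame with columns `ref_aa`, `protein_pos` (integer,
#'   1-based) and `alt_aa`, one row per element of `x`.
#' @examples
#' parse_protein_change(c("T96S", "H1047Y"))
#' @export
parse_protein_change <- function(x) {
  x <- as.character(x)
  out <- data.frame(ref_aa = NA_character_, protein_pos = NA_integer_,
                    alt_aa = NA_character_)[rep(1L, length(x)), , drop = FALSE]
  rownames(out) <- NULL
  ok <- !is.na(x)
  m <- regmatches(x[ok], regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", x[ok]))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop(sprintf("malformed protein change: %s",
                 paste(sQuote(x[ok][bad]), collapse = ", ")), call. = FALSE)
  }
  ref <- toupper(vapply(m, `[`, "", 2L))
  pos <- as.integer(vapply(m, `[`, "", 3L))
  alt <- toupper(vapply(m, `[`, "", 4L))
  bad_aa <- !(ref %in% AA_ALPHABET) | !(alt %in% AA_ALPHABET) | pos < 1L
  if (any(bad_aa)) {
    stop(sprintf("invalid protein change (non-canonical residue or position): %s",
                 paste(sQuote(x[ok][bad_aa]), collapse = ", ")), call. = FALSE)
  }
  out$ref_aa[ok] <- ref
  out$protein_pos[ok] <- pos
  out$alt_aa[ok] <- alt
  out
}

#' Format a protein change in compact notation
#'
#' Inverse of [parse_protein_change()]: `"T96S"` from (`"T"`, `96`, `"S"`).
#' Rows with any missing component yield `NA`.
#'
#' @param ref_aa,alt_aa Single-letter amino acids.
#' @param protein_pos 1-based residue positions.
#' @return Character vector.
#' @export
format_protein_change <- function(ref_aa, protein_pos, alt_aa) {
  out <- paste0(ref_aa, protein_pos, alt_aa)
  out[is.na(ref_aa) | is.na(protein_pos) | is.na(alt_aa)] <- NA_character_
  out
}

.validate_variants <- function(v) {
  bad_class <- !(v$variant_class %in% VARIANT_CLASSES)
  if (any(bad_class)) {
    stop(sprintf("unknown variant_class: %s",
                 paste(unique(v$variant_class[bad_class]), collapse = ", ")),
         call. = FALSE)
  }
  mis <- v$variant_class == "missense"
  has_nt <- !is.na(v$ref_base) & !is.na(v$alt_base)
  has_aa <- !is.na(v$ref_aa) & !is.na(v$protein_pos) & !is.na(v$alt_aa)
  nt_given <- !is.na(v$ref_base) | !is.na(v$alt_base)
  if (any(nt_given & !has_nt)) {
    stop("ref_base/alt_base must be given together", call. = FALSE)
  }
  bad_base <- has_nt & (!(v$ref_base %in% c("A", "C", "G", "T")) |
                          !(v$alt_base %in% c("A", "C", "G", "T")))
  if (any(bad_base)) {
    stop(sprintf("non-ACGT base in row(s): %s",
                 paste(which(bad_base), collapse = ", ")), call. = FALSE)
  }
  same_base <- mis & has_nt & v$ref_base == v$alt_base
  if (any(same_base)) {
    stop(sprintf("missense record with ref_base == alt_base in row(s): %s",
                 paste(which(same_base), collapse = ", ")), call. = FALSE)
  }
  same_aa <- mis & has_aa & v$ref_aa == v$alt_aa
  if (any(same_aa)) {
    stop(sprintf("missense record with ref_aa == alt_aa in row(s): %s",
                 paste(which(same_aa), collapse = ", ")), call. = FALSE)
  }
  no_annot <- mis & !has_nt & !has_aa
  if (any(no_annot)) {
    stop(sprintf(
      "missense record with neither nucleotide nor protein annotation in row(s): %s",
      paste(which(no_annot), collapse = ", ")), call. = FALSE)
  }
  bad_pos <- has_aa & v$protein_pos < 1L
  if (any(bad_pos)) stop("protein_pos must be >= 1", call. = FALSE)
  invisible(v)
}

#' Read an annotated somatic variant table
#'
#' Reads a MAF-like tab-delimited table of somatic variants. Required
#' columns: `patient_id`, `gene`, `variant_class` (one of `missense`,
#' `indel`). Optional columns: `ref_base`/`alt_base` (genomic substitution),
#' and either `protein_change` in compact notation (`"T96S"`) or the three
#' columns `ref_aa`/`protein_pos`/`alt_aa`. Indel records may omit all
#' nucleotide and protein fields; missense records need at least one of the
#' two annotations. Operations that need the missing annotation skip such
#' records and report how many were skipped.
#'
#' @param path Path to a TSV file.
#' @return A validated data.frame with columns `patient_id`, `gene`,
#'   `variant_class`, `ref_base`, `alt_base`, `ref_aa`, `protein_pos`,
#'   `alt_aa`, `protein_change`.
#' @seealso [write_variant_table()]
#' @export
read_variant_table <- function(path) {
  .assert_file(path, "variant table")
  df <- .read_tsv(path)
  .require_columns(df, c("patient_id", "gene", "variant_class"),
                   "variant table")
  n <- nrow(df)
  v <- data.frame(
    patient_id = as.character(df$patient_id),
    gene = as.character(df$gene),
    variant_class = tolower(as.character(df$variant_class)),
    ref_base = if ("ref_base" %in% names(df)) toupper(df$ref_base)
               else rep(NA_character_, n),
    alt_base = if ("alt_base" %in% names(df)) toupper(df$alt_base)
               else rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  if (all(c("ref_aa", "protein_pos", "alt_aa") %in% names(df))) {
    v$ref_aa <- toupper(df$ref_aa)
    v$protein_pos <- as.integer(df$protein_pos)
    v$alt_aa <- toupper(df$alt_aa)
  } else if ("protein_change" %in% names(df)) {
    parsed <- tryCatch(parse_protein_change(df$protein_change),
                       error = function(e) {
                         stop(conditionMessage(e), " (see data line numbers: ",
                              paste(which(!is.na(df$protein_change)), collapse = ","),
                              ")", call. = FALSE)
                       })
    v$ref_aa <- parsed$ref_aa
    v$protein_pos <- parsed$protein_pos
    v$alt_aa <- parsed$alt_aa
  } else {
    v$ref_aa <- rep(NA_character_, n)
    v$protein_pos <- rep(NA_integer_, n)
    v$alt_aa <- rep(NA_character_, n)
  }
  v$protein_change <- format_protein_change(v$ref_aa, v$protein_pos, v$alt_aa)
  .validate_variants(v)
  v
}

#' Write a somatic variant table
#'
#' Writes the canonical TSV dialect read by [read_variant_table()]; protein
#' annotation is emitted in compact notation so that a write/read round trip
#' reproduces every field.
#'
#' @param variants Data.frame as returned by [read_variant_table()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  out <- data.frame(
    patient_id = variants$patient_id,
    gene = variants$gene,
    variant_class = variants$variant_class,
    ref_base = variants$ref_base,
    alt_base = variants$alt_base,
    protein_change = format_protein_change(variants$ref_aa,
                                           variants$protein_pos,
                                           variants$alt_aa),
    stringsAsFactors = FALSE
  )
  .write_tsv(out, path)
}

#' Extract the T component of a TNM string
#'
#' Lenient, case-insensitive parsing of the tumor-extent stage from a TNM
#' string: `"T4Bn3aM0"` yields `"T4b"`. Published staging tables are often
#' inconsistent in case, so the match is forgiving.
#'
#' @param tnm Character vector of TNM strings (or bare stages like `"T2"`).
#' @return Character vector of normalized stages (`"T1a"`, `"T2"`, ...).
#' @export
parse_t_stage <- function(tnm) {
  tnm <- as.character(tnm)
  out <- rep(NA_character_, length(tnm))
  pos <- regexpr("^[Tt][0-9]+[AaBb]?", tnm)
  hit <- !is.na(tnm) & pos > 0L
  if (any(!hit & !is.na(tnm))) {
    stop(sprintf("cannot parse T stage from: %s",
                 paste(sQuote(tnm[!hit & !is.na(tnm)]), collapse = ", ")),
         call. = FALSE)
  }
  m <- regmatches(tnm, pos)
  norm <- paste0("T", sub("^T", "", toupper(m)))
  norm <- sub("([AB])$", "\\L\\1", norm, perl = TRUE)
  out[hit] <- norm
  out
}

# Stages ordered by invasion depth; used to direct one-sided comparisons.
.stage_rank <- function(stage) {
  num <- as.numeric(sub("^T([0-9]+).*$", "\\1", stage))
  sub <- match(sub("^T[0-9]+", "", stage), c("", "a", "b")) - 1L
  num + sub / 10
}

#' Read a clinical covariate table
#'
#' Required columns: `patient_id`, `sex` (`F`/`M`), `age` (years), `tnm`.
#' The T stage is derived from the TNM string with [parse_t_stage()] (an
#' explicit `t_stage` column, if present, is ignored in favor of the parsed
#' value unless the TNM column is absent). Extra columns are carried
#' through.
#'
#' @param path Path to a TSV file.
#' @return Data.frame with at least `patient_id`, `sex`, `age`, `tnm`,
#'   `t_stage`.
#' @export
read_clinical_table <- function(path) {
  .assert_file(path, "clinical table")
  df <- .read_tsv(path)
  .require_columns(df, c("patient_id", "sex", "age"), "clinical table")
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id)) {
    stop(sprintf("duplicate patient_id in clinical table: %s",
                 paste(unique(df$patient_id[duplicated(df$patient_id)]),
                       collapse = ", ")), call. = FALSE)
  }
  df$sex <- toupper(as.character(df$sex))
  if (!all(df$sex %in% c("F", "M"))) {
    stop("sex must be F or M", call. = FALSE)
  }
  df$age <- as.integer(df$age)
  if ("tnm" %in% names(df)) {
    df$t_stage <- parse_t_stage(df$tnm)
  } else if (!("t_stage" %in% names(df))) {
    stop("clinical table: missing required column(s): tnm", call. = FALSE)
  } else {
    df$t_stage <- parse_t_stage(df$t_stage)
  }
  df
}

#' Normalize HLA class-I allele names
#'
#' Normalizes 4-digit (two-field) class-I allele names to the canonical
#' `"A*11:01"` form: the separator `*` is inserted if missing and each field
#' is zero-padded to two digits (`"A*2:1"` becomes `"A*02:01"`).
#'
#' @param x Character vector of allele names.
#' @return Character vector of normalized allele names.
#' @export
normalize_hla_allele <- function(x) {
  x <- toupper(trimws(as.character(x)))
  m <- regexec("^(HLA-?)?([ABC])\\*?([0-9]{1,3}):([0-9]{1,3})$", x)
  parts <- regmatches(x, m)
  bad <- vapply(parts, length, 1L) != 5L & !is.na(x)
  if (any(bad)) {
    stop(sprintf("unparseable HLA allele: %s",
                 paste(sQuote(x[bad]), collapse = ", ")), call. = FALSE)
  }
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  out[ok] <- vapply(parts[ok], function(p) {
    sprintf("%s*%s:%s", p[3L],
            formatC(as.integer(p[4L]), width = 2, flag = "0"),
            formatC(as.integer(p[5L]), width = 2, flag = "0"))
  }, "")
  out
}

# Split a cell that may hold one or many alleles, delimited or concatenated
# ("B58:01C03:02C08:01" as printed in some supplementary tables).
.split_allele_cell <- function(cell) {
  if (is.na(cell) || !nzchar(cell)) return(character(0))
  tokens <- unlist(strsplit(cell, "[;,/| ]+"))
  tokens <- tokens[nzchar(tokens)]
  unlist(lapply(tokens, function(tok) {
    stripped <- gsub("HLA-?", "", tok, ignore.case = TRUE)
    hits <- regmatches(stripped,
                       gregexpr("[ABCabc]\\*?[0-9]{1,3}:[0-9]{1,3}",
                                stripped))[[1L]]
    leftover <- gsub("[ABCabc]\\*?[0-9]{1,3}:[0-9]{1,3}", "", stripped)
    if (length(hits) == 0L || nzchar(leftover)) {
      stop(sprintf("unparseable HLA allele token: %s", sQuote(tok)),
           call. = FALSE)
    }
    hits
  }))
}

#' Read an HLA class-I genotype table
#'
#' One row per patient. Alleles may be given in a single delimited column
#' (`alleles`, separated by `;`, `,`, `/` or spaces, or concatenated) or in
#' several per-locus columns; every non-`patient_id` column is scanned for
#' allele tokens. Alleles are normalized with [normalize_hla_allele()] and
#' stored with set semantics: a homozygous locus appears once.
#'
#' @param path Path to a TSV file.
#' @return A long data.frame with columns `patient_id`, `allele`, one row
#'   per distinct patient-allele pair.
#' @export
read_hla_table <- function(path) {
  .assert_file(path, "HLA table")
  df <- .read_tsv(path)
  .require_columns(df, "patient_id", "HLA table")
  allele_cols <- setdiff(names(df), "patient_id")
  if (length(allele_cols) == 0L) {
    stop("HLA table: no allele columns found", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(df)), function(i) {
    raw <- unlist(lapply(allele_cols,
                         function(cn) .split_allele_cell(df[[cn]][i])))
    alleles <- sort(unique(normalize_hla_allele(raw)))
    if (length(alleles) == 0L) return(NULL)
    data.frame(patient_id = as.character(df$patient_id[i]), allele = alleles,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(data.frame(patient_id = character(0),
                                                allele = character(0)))))
  rownames(out) <- NULL
  out
}

#' Split a long HLA table into per-patient genotypes
#'
#' @param hla Long data.frame from [read_hla_table()].
#' @return Named list of character vectors (allele sets), one per patient.
#' @export
hla_genotypes <- function(hla) {
  split(hla$allele, hla$patient_id)
}

#' Read a cancer gene list
#'
#' Plain text, one gene symbol per line (Cancer Gene Census style); blank
#' lines and surrounding whitespace are ignored.
#'
#' @param path Path to the list.
#' @return Character vector of symbols.
#' @export
read_gene_list <- function(path) {
  .assert_file(path, "gene list")
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file of amino-acid sequences keyed by gene or
#'   transcript identifier.
#' @return Named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  .assert_file(path, "protein FASTA")
  seqs <- Biostrings::readAAStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write protein sequences to FASTA
#'
#' @param proteins Named character vector of amino-acid sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(proteins)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Load the packaged reference-cohort fixtures
#'
#' Returns the summary tables of a published 32-patient gastric cancer
#' whole-exome cohort that this package uses as its reference fixture: the
#' per-patient characteristics table (sex, age, TNM, missense/indel/
#' neoantigen counts) and the mutation list of the six recurrently mutated
#' driver genes (protein change, patients affected, restricting HLA
#' alleles, predicted neoantigen count, and the count of matching donors in
#' the ICGC gastric datasets, carried as fixture data only).
#'
#' @return A list with elements `patients` (clinical covariates),
#'   `summaries` (per-patient counts, joined with covariates) and
#'   `driver_mutations` (per-mutation table with parsed `hla_alleles`
#'   list-column).
#' @examples
#' fx <- load_cohort_fixtures()
#' nrow(fx$summaries)    # 32 patients
#' @export
load_cohort_fixtures <- function() {
  p1 <- system.file("extdata", "gc32_patient_summary.tsv",
                    package = "neoprofiler", mustWork = TRUE)
  p2 <- system.file("extdata", "gc32_driver_mutations.tsv",
                    package = "neoprofiler", mustWork = TRUE)
  tab <- .read_tsv(p1)
  tab$age <- as.integer(tab$age)
  for (cn in c("n_missense", "n_indel", "n_neoantigen")) {
    tab[[cn]] <- as.integer(tab[[cn]])
  }
  tab$t_stage <- parse_t_stage(tab$tnm)
  patients <- tab[, c("patient_id", "sex", "age", "tnm", "t_stage")]
  summaries <- tab
  drv <- .read_tsv(p2)
  drv$n_patients <- as.integer(drv$n_patients)
  drv$n_neoantigens <- as.integer(drv$n_neoantigens)
  drv$n_icgc <- as.integer(drv$n_icgc)
  drv$hla_alleles <- lapply(drv$hla_alleles,
                            function(s) normalize_hla_allele(.split_allele_cell(s)))
  list(patients = patients, summaries = summaries, driver_mutations = drv)
}
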