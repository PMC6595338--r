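# Mutant-protein construction and enumeration of the 8-11mer peptide
# windows that cover the mutated residue. These windows are the candidate
# set handed to the MHC class-I binding predictor: ligands are contiguous,
# so windows truncated by a protein terminus are dropped, never padded.

#' Apply a missense change to a protein sequence
#'
#' Substitutes `alt_aa` at 1-based position `protein_pos`, first checking
#' that the sequence carries `ref_aa` there. The check guards against
#' transcript or annotation drift between the variant table and the
#' supplied protein model.
#'
#' @param protein_seq Amino-acid string.
#' @param protein_pos 1-based residue index.
#' @param ref_aa,alt_aa Single-letter reference and alternate residues.
#' @return The mutant sequence.
#' @examples
#' apply_missense("ACDEFG", 3, "D", "Y")  # "ACYEFG"
#' @export
apply_missense <- function(protein_seq, protein_pos, ref_aa, alt_aa) {
  stopifnot(length(protein_seq) == 1L, length(protein_pos) == 1L)
  n <- nchar(protein_seq)
  if (protein_pos < 1L || protein_pos > n) {
    stop(sprintf("protein_pos %d outside sequence of length %d",
                 protein_pos, n), call. = FALSE)
  }
  observed <- substr(protein_seq, protein_pos, protein_pos)
  if (observed != ref_aa) {
    stop(sprintf(
      "reference mismatch at position %d: expected %s, observed %s",
      protein_pos, ref_aa, observed), call. = FALSE)
  }
  substr(protein_seq, protein_pos, protein_pos) <- alt_aa
  protein_seq
}

#' Enumerate mutant peptide windows covering the mutated residue
#'
#' For each requested length L, emits every window of the mutant protein
#' that lies fully within the sequence and covers the mutated position,
#' ordered by ascending length then ascending start. Windows with identical
#' sequence (possible in repeat regions) are emitted once per mutation.
#'
#' @param mutant_seq Mutant protein sequence (after [apply_missense()]).
#' @param protein_pos 1-based index of the mutated residue.
#' @param lengths Integer vector of window lengths; the default `8:11`
#'   spans the class-I ligand range. Lengths outside 8-11 are rejected
#'   unless `allow_any_length = TRUE`.
#' @param allow_any_length Permit lengths outside the 8-11 class-I range.
#' @return Data.frame with columns `peptide`, `length`, `start` (1-based in
#'   the protein) and `mutation_offset` (0-based index of the mutated
#'   residue within the peptide).
#' @examples
#' mut <- apply_missense(strrep("A", 30), 15, "A", "W")
#' nrow(enumerate_mutant_peptides(mut, 15))  # 38 windows
#' @export
enumerate_mutant_peptides <- function(mutant_seq, protein_pos,
                                      lengths = 8:11,
                                      allow_any_length = FALSE) {
  lengths <- sort(unique(as.integer(lengths)))
  if (!allow_any_length && (any(lengths < 8L) || any(lengths > 11L))) {
    stop("peptide lengths outside 8-11 are rejected by default; ",
         "set allow_any_length = TRUE to override", call. = FALSE)
  }
  n <- nchar(mutant_seq)
  if (protein_pos < 1L || protein_pos > n) {
    stop("protein_pos outside sequence", call. = FALSE)
  }
  rows <- lapply(lengths, function(L) {
    lo <- max(1L, protein_pos - L + 1L)
    hi <- min(protein_pos, n - L + 1L)
    if (hi < lo) return(NULL)
    start <- lo:hi
    data.frame(
      peptide = substring(mutant_seq, start, start + L - 1L),
      length = L,
      start = start,
      mutation_offset = protein_pos - start,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(peptide = character(0), length = integer(0),
                      start = integer(0), mutation_offset = integer(0))
  }
  out <- out[!duplicated(out$peptide), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate candidate peptides for a table of missense variants
#'
#' Maps each missense variant onto its protein (keyed by gene symbol),
#' applies the substitution and enumerates the covering windows. Indel
#' records and missense records without protein annotation are skipped;
#' variants whose gene has no sequence, or whose reference residue does not
#' match the protein, raise an error unless `on_mismatch = "skip"`.
#'
#' @param variants Variant data.frame (see [read_variant_table()]).
#' @param proteins Named character vector of protein sequences.
#' @param lengths Window lengths, default `8:11`.
#' @param on_mismatch `"error"` (default) or `"skip"` for reference
#'   mismatches and missing proteins.
#' @return Data.frame of candidates with provenance columns `patient_id`,
#'   `gene`, `protein_change` plus the columns of
#'   [enumerate_mutant_peptides()]; the number of skipped variant records
#'   is attached as attribute `n_skipped`.
#' @export
peptides_for_variants <- function(variants, proteins, lengths = 8:11,
                                  on_mismatch = c("error", "skip")) {
  on_mismatch <- match.arg(on_mismatch)
  usable <- variants$variant_class == "missense" &
    !is.na(variants$protein_pos) & !is.na(variants$ref_aa) &
    !is.na(variants$alt_aa)
  n_skipped <- sum(!usable)
  v <- variants[usable, , drop = FALSE]
  rows <- vector("list", nrow(v))
  for (i in seq_len(nrow(v))) {
    gene <- v$gene[i]
    seq <- if (gene %in% names(proteins)) proteins[[gene]] else NULL
    fail <- function(msg) {
      if (on_mismatch == "error") stop(msg, call. = FALSE)
      NULL
    }
    if (is.null(seq)) {
      res <- fail(sprintf("no protein sequence for gene %s", gene))
    } else {
      res <- tryCatch({
        mut <- apply_missense(seq, v$protein_pos[i], v$ref_aa[i], v$alt_aa[i])
        pep <- enumerate_mutant_peptides(mut, v$protein_pos[i], lengths)
        if (nrow(pep) > 0L) {
          cbind(data.frame(patient_id = v$patient_id[i], gene = gene,
                           protein_change = v$protein_change[i],
                           stringsAsFactors = FALSE),
                pep)
        } else NULL
      }, error = function(e) fail(conditionMessage(e)))
    }
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(patient_id = character(0), gene = character(0),
                      protein_change = character(0), peptide = character(0),
                      length = integer(0), start = integer(0),
                      mutation_offset = integer(0))
  }
  # deduplicate identical (peptide, mutation) pairs per gene but keep the
  # same peptide when it arises from distinct mutations
  key <- paste(out$patient_id, out$gene, out$protein_change, out$peptide,
               sep = "\r")
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped + sum(vapply(rows, is.null, TRUE))
  out
}
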