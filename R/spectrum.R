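# Six-class somatic substitution spectrum. Single-base substitutions are
# reported on the pyrimidine-referenced strand (the convention under which
# exactly six classes exist): a purine reference base is complemented
# together with its alternate, so G>T becomes C>A and A>G becomes T>C.
# Transitions are C>T and T>C; the other four classes are transversions.

SPECTRUM_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify a single-base substitution
#'
#' Maps an ordered (ref, alt) base pair onto the six pyrimidine-referenced
#' substitution classes and flags transitions. The 12 ordered pairs map
#' two-to-one onto the six classes.
#'
#' @param ref_base,alt_base Character vectors over `{A,C,G,T}` with
#'   `ref_base != alt_base` elementwise.
#' @return Data.frame with columns `class` (factor over the six classes)
#'   and `is_transition`.
#' @examples
#' classify_substitution("G", "T")  # C>A, transversion
#' @export
classify_substitution <- function(ref_base, alt_base) {
  ref_base <- toupper(as.character(ref_base))
  alt_base <- toupper(as.character(alt_base))
  n <- max(length(ref_base), length(alt_base))
  ref_base <- rep_len(ref_base, n)
  alt_base <- rep_len(alt_base, n)
  bad <- !(ref_base %in% names(.COMPLEMENT)) |
    !(alt_base %in% names(.COMPLEMENT)) | ref_base == alt_base
  if (any(bad)) {
    stop(sprintf("cannot classify substitution(s): %s",
                 paste(unique(paste0(ref_base[bad], ">", alt_base[bad])),
                       collapse = ", ")), call. = FALSE)
  }
  purine <- ref_base %in% c("A", "G")
  r <- ifelse(purine, .COMPLEMENT[ref_base], ref_base)
  a <- ifelse(purine, .COMPLEMENT[alt_base], alt_base)
  cls <- paste0(r, ">", a)
  data.frame(class = factor(cls, levels = SPECTRUM_CLASSES),
             is_transition = cls %in% c("C>T", "T>C"))
}

#' Summarize the substitution spectrum of a variant table
#'
#' Computes class fractions and the transition/transversion split over the
#' missense records that carry nucleotide annotation. Indels and
#' nucleotide-free records are counted in `n_skipped` and excluded.
#'
#' @param variants Variant data.frame (see [read_variant_table()]).
#' @return An object of class `spectrum_summary`: a list with `fractions`
#'   (named over the six classes), `counts`, `ti_fraction`, `tv_fraction`,
#'   `n_classified`, `n_skipped`. With no classifiable record the fractions
#'   are `NA` and `n_classified` is 0.
#' @export
spectrum_summary <- function(variants) {
  usable <- variants$variant_class == "missense" &
    !is.na(variants$ref_base) & !is.na(variants$alt_base)
  n_skipped <- sum(!usable)
  v <- variants[usable, , drop = FALSE]
  if (nrow(v) == 0L) {
    out <- list(fractions = stats::setNames(rep(NA_real_, 6), SPECTRUM_CLASSES),
                counts = stats::setNames(rep(0L, 6), SPECTRUM_CLASSES),
                ti_fraction = NA_real_, tv_fraction = NA_real_,
                n_classified = 0L, n_skipped = n_skipped)
    class(out) <- "spectrum_summary"
    return(out)
  }
  cls <- classify_substitution(v$ref_base, v$alt_base)
  counts <- table(cls$class)
  fractions <- as.numeric(counts) / nrow(v)
  names(fractions) <- SPECTRUM_CLASSES
  ti <- unname(fractions["C>T"] + fractions["T>C"])
  out <- list(fractions = fractions,
              counts = stats::setNames(as.integer(counts), SPECTRUM_CLASSES),
              ti_fraction = ti, tv_fraction = 1 - ti,
              n_classified = nrow(v), n_skipped = n_skipped)
  class(out) <- "spectrum_summary"
  out
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("Substitution spectrum over %d classified missense variants (%d skipped)\n",
              x$n_classified, x$n_skipped))
  if (x$n_classified > 0L) {
    for (cl in SPECTRUM_CLASSES) {
      cat(sprintf("  %s  %6.2f%%  (n=%d)\n", cl, 100 * x$fractions[[cl]],
                  x$counts[[cl]]))
    }
    cat(sprintf("  transitions %.2f%%, transversions %.2f%%\n",
                100 * x$ti_fraction, 100 * x$tv_fraction))
  }
  invisible(x)
}

#' Export a spectrum summary as a data.frame
#'
#' @param x A `spectrum_summary`.
#' @param ... Unused.
#' @return Data.frame with columns `class`, `count`, `fraction`.
#' @export
as.data.frame.spectrum_summary <- function(x, ...) {
  data.frame(class = SPECTRUM_CLASSES,
             count = unname(x$counts),
             fraction = unname(x$fractions),
             stringsAsFactors = FALSE)
}

#' Per-patient substitution-class count matrix
#'
#' Class-by-patient counts for stacked-bar style spectrum displays.
#'
#' @param variants Variant data.frame.
#' @return Integer matrix, six class rows by one column per patient.
#' @export
spectrum_by_patient <- function(variants) {
  usable <- variants$variant_class == "missense" &
    !is.na(variants$ref_base) & !is.na(variants$alt_base)
  v <- variants[usable, , drop = FALSE]
  patients <- sort(unique(variants$patient_id))
  mat <- matrix(0L, nrow = length(SPECTRUM_CLASSES), ncol = length(patients),
                dimnames = list(SPECTRUM_CLASSES, patients))
  if (nrow(v) > 0L) {
    cls <- classify_substitution(v$ref_base, v$alt_base)
    tab <- table(cls$class, factor(v$patient_id, levels = patients))
    mat[rownames(tab), colnames(tab)] <- as.integer(tab)
  }
  mat
}
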