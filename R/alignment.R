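#' Codon alignment container
#'
#' An equal-length, frame-aligned set of coding sequences with sample IDs,
#' breed labels and the gene boundaries of the concatenation. Sequences are
#' stored as upper-case nucleotide strings.
#'
#' @param sequences character vector of equal-length nucleotide strings
#' @param sample_ids unique identifiers, parallel to `sequences`
#' @param breeds breed labels, parallel (NA allowed)
#' @param gene_boundaries tibble with `gene`, `start` (1-based offset into
#'   the concatenation) and `length` (nt, multiple of 3); optional
#' @return object of class `codon_alignment`
#' @export
codon_alignment <- function(sequences, sample_ids = names(sequences),
                            breeds = NA_character_,
                            gene_boundaries = NULL) {
  force(sample_ids)
  sequences <- toupper(unname(sequences))
  n <- length(sequences)
  if (is.null(sample_ids)) sample_ids <- paste0("seq", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (length(sample_ids) != n) stop("sample_ids not parallel to sequences")
  len <- unique(nchar(sequences))
  if (length(len) != 1L) {
    stop("sequences must be equal length (got lengths ",
         paste(sort(len), collapse = ", "), ")")
  }
  if (len %% 3L != 0L) stop("alignment length ", len, " is not a multiple of 3")
  breeds <- rep_len(as.character(breeds), n)
  if (!is.null(gene_boundaries)) {
    gene_boundaries <- tibble::as_tibble(gene_boundaries)
    stopifnot(all(c("gene", "start", "length") %in% names(gene_boundaries)))
    if (any(gene_boundaries$length %% 3L != 0L)) {
      stop("gene lengths must be multiples of 3")
    }
  }
  structure(
    list(sequences = sequences,
         samples = tibble::tibble(sample_id = sample_ids, breed = breeds),
         gene_boundaries = gene_boundaries),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("<codon_alignment>", length(x$sequences), "sequences x",
      nchar(x$sequences[1]), "nt (", nchar(x$sequences[1]) %/% 3L, "codons)\n")
  br <- x$samples$breed
  if (any(!is.na(br))) {
    tb <- sort(table(br), decreasing = TRUE)
    cat("  breeds:", paste0(names(tb), " (", tb, ")", collapse = ", "), "\n")
  }
  if (!is.null(x$gene_boundaries)) {
    cat("  genes:", nrow(x$gene_boundaries), "concatenated\n")
  }
  invisible(x)
}

#' @export
as_tibble.codon_alignment <- function(x, ...) {
  dplyr::mutate(x$samples, sequence = x$sequences)
}

#' Subset a codon alignment by sample
#'
#' @param alignment a [codon_alignment()]
#' @param keep logical/integer/character index into the samples
#' @return a [codon_alignment()] with the selected rows
#' @export
subset_samples <- function(alignment, keep) {
  stopifnot(inherits(alignment, "codon_alignment"))
  if (is.character(keep)) keep <- match(keep, alignment$samples$sample_id)
  codon_alignment(alignment$sequences[keep],
                  alignment$samples$sample_id[keep],
                  alignment$samples$breed[keep],
                  alignment$gene_boundaries)
}

.aln_ncodons <- function(alignment) nchar(alignment$sequences[1]) %/% 3L
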