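# Reading GenBank flat files and FASTA, extracting the 13 mitochondrial
# protein-coding CDS, and building concatenated codon alignments. No
# alignment is performed here: bovine mito CDS are length-conserved, so
# equal length is enforced and violations are delegated to an external
# aligner.

#' Canonical mitochondrial protein-coding genes, in genome order
#' @export
MITO_GENES <- c("ND1", "ND2", "COX1", "COX2", "ATP8", "ATP6", "COX3",
                "ND3", "ND4L", "ND4", "ND5", "ND6", "CYTB")

# Name normalisation: exact table of known synonyms after squashing case,
# spaces, hyphens, underscores and an MT- prefix. Unmatched names are left
# as-is and fail loudly downstream rather than fuzzy-matching.
.GENE_SYNONYMS <- local({
  syn <- list(
    ND1 = c("ND1", "NADHDEHYDROGENASESUBUNIT1", "NADH1", "ND1PROTEIN"),
    ND2 = c("ND2", "NADHDEHYDROGENASESUBUNIT2", "NADH2"),
    ND3 = c("ND3", "NADHDEHYDROGENASESUBUNIT3", "NADH3"),
    ND4 = c("ND4", "NADHDEHYDROGENASESUBUNIT4", "NADH4"),
    ND4L = c("ND4L", "NADHDEHYDROGENASESUBUNIT4L", "NADH4L"),
    ND5 = c("ND5", "NADHDEHYDROGENASESUBUNIT5", "NADH5"),
    ND6 = c("ND6", "NADHDEHYDROGENASESUBUNIT6", "NADH6"),
    COX1 = c("COX1", "COXI", "COI", "CO1", "COX1GENE",
             "CYTOCHROMECOXIDASESUBUNIT1", "CYTOCHROMECOXIDASESUBUNITI",
             "CYTOCHROMEOXIDASESUBUNIT1", "CYTOCHROMEOXIDASESUBUNITI"),
    COX2 = c("COX2", "COXII", "COII", "CO2",
             "CYTOCHROMECOXIDASESUBUNIT2", "CYTOCHROMECOXIDASESUBUNITII",
             "CYTOCHROMEOXIDASESUBUNIT2", "CYTOCHROMEOXIDASESUBUNITII"),
    COX3 = c("COX3", "COXIII", "COIII", "CO3",
             "CYTOCHROMECOXIDASESUBUNIT3", "CYTOCHROMECOXIDASESUBUNITIII",
             "CYTOCHROMEOXIDASESUBUNIT3", "CYTOCHROMEOXIDASESUBUNITIII"),
    ATP6 = c("ATP6", "ATPASE6", "ATPASESUBUNIT6", "ATPSYNTHASEF0SUBUNIT6",
             "ATPSYNTHASESUBUNIT6", "ATP6GENE"),
    ATP8 = c("ATP8", "ATPASE8", "ATPASESUBUNIT8", "ATPSYNTHASEF0SUBUNIT8",
             "ATPSYNTHASESUBUNIT8"),
    CYTB = c("CYTB", "CYB", "COB", "CYTOCHROMEB", "CYTOCHROMEBGENE")
  )
  out <- unlist(lapply(names(syn), function(g) {
    stats::setNames(rep(g, length(syn[[g]])), syn[[g]])
  }))
  out
})

#' Normalise a mitochondrial gene name
#'
#' Maps common /gene and /product spellings (COI, COXI, ATPase6,
#' "NADH dehydrogenase subunit 4L", cytb, ...) onto the canonical
#' [MITO_GENES] symbols. Unknown names come back unchanged so callers can
#' fail loudly: silent misassignment would corrupt the concatenation.
#'
#' @param name character vector of raw gene or product names
#' @return character vector of canonical names (or the squashed input where
#'   no synonym matches)
#' @export
normalize_gene_name <- function(name) {
  key <- toupper(gsub("[ _-]", "", name))
  key <- sub("^MT", "", key)
  hit <- .GENE_SYNONYMS[key]
  unname(ifelse(is.na(hit), key, hit))
}

# ---- GenBank flat files -----------------------------------------------

.parse_gb_location <- function(loc) {
  strand <- "+"
  x <- gsub("[<>]", "", trimws(loc))
  if (grepl("^complement\\(", x)) {
    strand <- "-"
    x <- sub("^complement\\((.*)\\)$", "\\1", x)
  }
  if (!grepl("^[0-9]+\\.\\.[0-9]+$", x)) return(NULL)  # join() etc: skip
  se <- as.integer(strsplit(x, "..", fixed = TRUE)[[1]])
  list(start = se[1], end = se[2], strand = strand)
}

.parse_gb_record <- function(lines) {
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) != 1L) {
    stop("malformed GenBank record (expected one LOCUS line): ",
         substr(paste(lines[1], collapse = " "), 1, 60))
  }
  name <- strsplit(trimws(sub("^LOCUS", "", lines[locus_i])), "\\s+")[[1]][1]
  acc_i <- grep("^ACCESSION", lines)
  accession <- if (length(acc_i)) {
    strsplit(trimws(sub("^ACCESSION", "", lines[acc_i[1]])), "\\s+")[[1]][1]
  } else name

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (length(orig_i) != 1L) {
    stop("malformed GenBank record ", accession, ": missing ORIGIN")
  }
  seq_lines <- lines[(orig_i + 1L):length(lines)]
  genome_seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(genome_seq)) {
    stop("malformed GenBank record ", accession, ": empty sequence")
  }

  organism <- NA_character_
  breed <- NA_character_
  cds <- list()
  if (length(feat_i) == 1L && feat_i < orig_i) {
    flines <- lines[(feat_i + 1L):(orig_i - 1L)]
    # split the feature table into features (key at col 6) + qualifier lines
    is_key <- grepl("^\\s{1,10}\\S", flines) & !grepl("^\\s*/", flines)
    grp <- cumsum(is_key)
    for (g in unique(grp[grp > 0])) {
      block <- flines[grp == g]
      hdr <- strsplit(trimws(block[1]), "\\s+")[[1]]
      key <- hdr[1]
      loc_str <- paste0(hdr[-1], collapse = "")
      quals <- block[-1]
      # continuation lines of a multi-line location
      contin <- !grepl("^\\s*/", quals)
      if (any(contin) && length(quals)) {
        loc_str <- paste0(loc_str,
                          paste0(trimws(quals[cumsum(!contin) == 0 & contin]),
                                 collapse = ""))
      }
      qget <- function(q) {
        m <- grep(paste0("^\\s*/", q, "="), quals, value = TRUE)
        if (!length(m)) return(NA_character_)
        gsub('^[^=]*="?|"$', "", trimws(m[1]))
      }
      if (key == "source") {
        organism <- qget("organism")
        breed <- qget("breed")
        if (is.na(breed)) {
          note <- qget("note")
          if (!is.na(note) && grepl("breed[:=]", note, ignore.case = TRUE)) {
            breed <- trimws(sub(".*breed[:=]\\s*", "", note,
                                ignore.case = TRUE))
          }
        }
      } else if (key == "CDS") {
        loc <- .parse_gb_location(loc_str)
        gene <- qget("gene")
        if (is.na(gene)) gene <- qget("product")
        if (is.null(loc)) {
          warning("record ", accession,
                  ": CDS without locatable coordinates (", loc_str,
                  ") skipped", call. = FALSE)
          next
        }
        cds[[length(cds) + 1L]] <- tibble::tibble(
          gene_raw = gene, gene = normalize_gene_name(gene),
          start = loc$start, end = loc$end, strand = loc$strand)
      }
    }
  }
  cds_tbl <- if (length(cds)) dplyr::bind_rows(cds) else
    tibble::tibble(gene_raw = character(), gene = character(),
                   start = integer(), end = integer(), strand = character())
  if (nrow(cds_tbl) && any(cds_tbl$end > nchar(genome_seq))) {
    stop("malformed GenBank record ", accession,
         ": CDS interval beyond sequence end")
  }
  tibble::tibble(accession = accession, organism = organism, breed = breed,
                 sequence = genome_seq, cds = list(cds_tbl))
}

#' Read a (multi-record) GenBank flat file
#'
#' Parses the subset of the flat-file grammar needed for annotated
#' mitogenomes: LOCUS/ACCESSION, the source feature's organism and breed
#' qualifiers (falling back to a `breed:` note), CDS features with
#' `start..end` or `complement(start..end)` locations, and the ORIGIN
#' sequence. CDS features whose location cannot be resolved (e.g. `join`)
#' are skipped with a warning. Coordinates are 1-based inclusive as in the
#' format.
#'
#' @param path one or more GenBank flat files (`.gb`/`.gbk`)
#' @return tibble with one row per record: `accession`, `organism`, `breed`
#'   (NA when absent), `sequence`, and a `cds` list-column of feature tables
#'   (`gene_raw`, `gene`, `start`, `end`, `strand`)
#' @export
read_genbank <- function(path) {
  purrr::map_dfr(path, function(p) {
    lines <- readr::read_lines(p)
    ends <- grep("^//", lines)
    if (!length(ends)) stop("no GenBank record terminator '//' in ", p)
    starts <- c(1L, utils::head(ends, -1) + 1L)
    purrr::map_dfr(seq_along(ends), function(k) {
      chunk <- lines[starts[k]:(ends[k] - 1L)]
      chunk <- chunk[nzchar(trimws(chunk))]
      if (!length(chunk)) return(NULL)
      .parse_gb_record(chunk)
    })
  })
}

#' Extract the mitochondrial protein-coding genes from one record
#'
#' Slices each requested CDS out of the genome sequence, reverse-complements
#' minus-strand features, and trims the terminal stop codon: a complete
#' stop (length 0 mod 3 ending in a stop codon) loses its final codon, an
#' incomplete stop (length 1 or 2 mod 3, completed by polyadenylation in
#' mito transcripts) loses the overhang. Output order is the canonical gene
#' order regardless of annotation order.
#'
#' @param record one row of a [read_genbank()] tibble (or an equivalent
#'   named list with `sequence` and `cds`)
#' @param gene_set canonical gene names to extract (default [MITO_GENES])
#' @param code [genetic_code()] used to recognise terminal stops
#' @return tibble with `gene` and `seq` (in-frame, multiple of 3)
#' @export
extract_cds <- function(record, gene_set = MITO_GENES,
                        code = genetic_code(2)) {
  rec <- as.list(record)
  cds <- rec$cds
  if (is.list(cds) && !is.data.frame(cds)) cds <- cds[[1]]
  genome <- toupper(rec$sequence)
  acc <- rec$accession %||% "<record>"
  hits <- match(gene_set, cds$gene)
  if (anyNA(hits)) {
    stop("record ", acc, ": missing gene(s) ",
         paste(gene_set[is.na(hits)], collapse = ", "))
  }
  if (anyDuplicated(cds$gene[stats::na.omit(hits)])) {
    stop("record ", acc, ": duplicated gene annotation after normalization")
  }
  seqs <- purrr::map_chr(hits, function(i) {
    s <- substr(genome, cds$start[i], cds$end[i])
    if (cds$strand[i] == "-") s <- revcomp(s)
    .trim_stop(s, code, acc, cds$gene[i])
  })
  tibble::tibble(gene = gene_set, seq = seqs)
}

.trim_stop <- function(s, code, acc, gene) {
  r <- nchar(s) %% 3L
  if (r > 0L) s <- substr(s, 1L, nchar(s) - r)   # incomplete terminal stop
  else {
    last <- substr(s, nchar(s) - 2L, nchar(s))
    li <- match(last, .ALL_CODONS)
    if (!is.na(li) && !code$is_sense[li]) s <- substr(s, 1L, nchar(s) - 3L)
  }
  if (nchar(s) < 3L) {
    stop("record ", acc, ", gene ", gene, ": no coding frame left after ",
         "stop trimming")
  }
  s
}

#' Reverse complement of a nucleotide string
#' @param x character vector of A/C/G/T (and N) strings
#' @return reverse-complemented strings
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgtN", "TGCAtgcaN",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Concatenate per-record CDS into a codon alignment
#'
#' Runs [extract_cds()] on every record, checks that each gene has one
#' length across records (the no-indel assumption for bovine mito CDS;
#' disagreement is an error naming the gene and records, signalling that an
#' external aligner is required), drops records that fail extraction, and
#' concatenates genes in canonical order. The extraction report is attached
#' as the `"report"` attribute (accession, genes_found, included, reason).
#'
#' @param records tibble from [read_genbank()]
#' @param gene_set canonical gene names (default [MITO_GENES])
#' @param code [genetic_code()]
#' @return a [codon_alignment()] with `gene_boundaries` filled in
#' @export
concatenate_cds <- function(records, gene_set = MITO_GENES,
                            code = genetic_code(2)) {
  rows <- seq_len(nrow(records))
  ext <- purrr::map(rows, function(i) {
    tryCatch(extract_cds(records[i, ], gene_set, code),
             error = function(e) conditionMessage(e))
  })
  ok <- purrr::map_lgl(ext, is.data.frame)
  report <- tibble::tibble(
    accession = records$accession,
    genes_found = purrr::map_int(rows, function(i) {
      cds <- records$cds[[i]]
      sum(gene_set %in% cds$gene)
    }),
    included = ok,
    reason = purrr::map2_chr(ext, ok, function(e, k) if (k) "" else e)
  )
  if (!any(ok)) stop("no record yielded all requested genes")
  if (any(!ok)) {
    message(sum(!ok), " record(s) dropped during extraction; see report")
  }
  kept <- which(ok)
  # enforce one length per gene across records
  for (g in gene_set) {
    lens <- purrr::map_int(ext[kept], function(tb) {
      nchar(tb$seq[tb$gene == g])
    })
    if (length(unique(lens)) > 1L) {
      bad <- records$accession[kept][lens != stats::median(lens)]
      stop("gene ", g, " has unequal lengths across records (",
           paste(unique(lens), collapse = ", "), "); offending record(s): ",
           paste(bad, collapse = ", "),
           " - sequences must be aligned externally")
    }
  }
  glen <- purrr::map_int(gene_set, function(g) {
    nchar(ext[[kept[1]]]$seq[ext[[kept[1]]]$gene == g])
  })
  bounds <- tibble::tibble(gene = gene_set,
                           start = cumsum(c(1L, utils::head(glen, -1))),
                           length = glen)
  seqs <- purrr::map_chr(ext[kept], function(tb) {
    paste(tb$seq[match(gene_set, tb$gene)], collapse = "")
  })
  aln <- codon_alignment(seqs, records$accession[kept],
                         records$breed[kept], bounds)
  attr(aln, "report") <- report
  aln
}

# ---- FASTA ------------------------------------------------------------

#' Read a codon alignment from multi-FASTA
#'
#' Sequences must be equal length and in frame (length a multiple of 3).
#' Breed labels are joined from `breed_table` when given (2-column TSV or
#' data frame: `sample_id`, `breed`), else parsed from a `breed=...` token
#' in the FASTA headers, else left NA.
#'
#' @param path FASTA file
#' @param breed_table optional path to a TSV or a data frame mapping
#'   `sample_id` to `breed`
#' @return a [codon_alignment()]
#' @export
read_fasta_alignment <- function(path, breed_table = NULL) {
  dna <- ape::read.FASTA(path)
  if (!length(dna)) stop("no sequences in ", path)
  seqs <- toupper(vapply(as.character(dna), paste, character(1),
                         collapse = ""))
  headers <- names(dna)
  ids <- sub("\\s.*$", "", headers)
  breeds <- rep(NA_character_, length(ids))
  m <- regmatches(headers, regexpr("breed=\\S+", headers))
  has <- grepl("breed=", headers)
  breeds[has] <- sub("^breed=", "", m)
  if (!is.null(breed_table)) {
    tb <- if (is.character(breed_table)) {
      readr::read_tsv(breed_table, col_types = "cc")
    } else tibble::as_tibble(breed_table)
    stopifnot(all(c("sample_id", "breed") %in% names(tb)))
    breeds <- tb$breed[match(ids, tb$sample_id)]
  }
  codon_alignment(seqs, ids, breeds)
}

#' Write a codon alignment as FASTA
#'
#' Headers carry the sample id plus a `breed=` token so that
#' [read_fasta_alignment()] round-trips labels exactly.
#'
#' @param alignment a [codon_alignment()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fasta_alignment <- function(alignment, path) {
  stopifnot(inherits(alignment, "codon_alignment"))
  hdr <- alignment$samples$sample_id
  br <- alignment$samples$breed
  hdr <- ifelse(is.na(br), hdr, paste0(hdr, " breed=", br))
  out <- rbind(paste0(">", hdr), alignment$sequences)
  readr::write_lines(as.vector(out), path)
  invisible(path)
}
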