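make_gb_fixture <- function(n = 2, n_codons_per_gene = c(4, 5), dir = NULL) {
  # tiny 2-gene alignment written as GenBank records
  genes <- tibble::tibble(gene = c("ND1", "CYTB"),
                          start = c(1L, 3L * n_codons_per_gene[1] + 1L),
                          length = 3L * n_codons_per_gene)
  set.seed(99)
  seqs <- vapply(seq_len(n), function(i) {
    random_root_sequence(sum(n_codons_per_gene), seed = 100 + i)
  }, character(1))
  aln <- codon_alignment(seqs, sprintf("ACC%03d", seq_len(n)),
                         breeds = rep("Testbreed", n),
                         gene_boundaries = genes)
  if (is.null(dir)) dir <- withr::local_tempdir(.local_envir = parent.frame())
  files <- write_genbank_fixtures(aln, dir)
  list(alignment = aln, files = files, dir = dir)
}

test_that("GenBank fixtures round-trip through read_genbank and concatenate_cds", {
  fx <- make_gb_fixture()
  recs <- read_genbank(fx$files)
  expect_equal(nrow(recs), 2)
  expect_equal(recs$breed, rep("Testbreed", 2))
  expect_equal(recs$organism, rep("Bos taurus", 2))
  expect_equal(nrow(recs$cds[[1]]), 2)
  aln <- concatenate_cds(recs, gene_set = c("ND1", "CYTB"))
  expect_identical(aln$sequences, fx$alignment$sequences)
  expect_identical(aln$samples, fx$alignment$samples)
  expect_equal(aln$gene_boundaries$length,
               fx$alignment$gene_boundaries$length)
})

test_that("a full 13-gene simulated cohort round-trips byte-for-byte", {
  sim <- small_study()
  sub <- subset_samples(sim$alignment, 1:5)
  # attach the 13-gene boundary table scaled to the test alignment
  glen <- rep(3L * 23L, 13)
  glen[13] <- 3L * 300L - sum(glen[-13])
  sub$gene_boundaries <- tibble::tibble(
    gene = MITO_GENES, start = cumsum(c(1L, head(glen, -1))), length = glen)
  dir <- withr::local_tempdir()
  files <- write_genbank_fixtures(sub, dir)
  recs <- read_genbank(files)
  expect_equal(nrow(recs$cds[[1]]), 13)
  aln <- concatenate_cds(recs)
  expect_identical(aln$sequences, sub$sequences)
  expect_identical(aln$samples$breed, sub$samples$breed)
})

test_that("records without breed qualifiers give NA breed", {
  fx <- make_gb_fixture()
  lines <- readr::read_lines(fx$files[1])
  lines <- lines[!grepl("/breed=", lines)]
  f <- file.path(fx$dir, "nobreed.gb")
  readr::write_lines(lines, f)
  rec <- read_genbank(f)
  expect_true(is.na(rec$breed))
})

test_that("a record with a missing gene is dropped with a named reason", {
  fx <- make_gb_fixture()
  lines <- readr::read_lines(fx$files[1])
  i <- grep('/gene="CYTB"', lines)
  lines <- lines[-c(i - 1, i)]  # delete the CDS feature + qualifier
  f <- file.path(fx$dir, "missing.gb")
  readr::write_lines(lines, f)
  recs <- read_genbank(c(f, fx$files[2]))
  expect_error(extract_cds(recs[1, ], gene_set = c("ND1", "CYTB")),
               "CYTB")
  expect_message(aln <- concatenate_cds(recs, gene_set = c("ND1", "CYTB")),
                 "dropped")
  rep <- attr(aln, "report")
  expect_false(rep$included[1])
  expect_match(rep$reason[1], "CYTB")
  expect_equal(length(aln$sequences), 1)
})

test_that("minus-strand CDS are reverse-complemented on extraction", {
  rec <- tibble::tibble(
    accession = "X1", organism = "Bos taurus", breed = NA_character_,
    sequence = paste0("AAAAAA", revcomp("ATGGCCTAA"), "TTTTTT"),
    cds = list(tibble::tibble(gene_raw = "ND6", gene = "ND6",
                              start = 7L, end = 15L, strand = "-")))
  out <- extract_cds(rec, gene_set = "ND6")
  expect_identical(out$seq, "ATGGCC")  # TAA stop trimmed
})

test_that("terminal stops, complete and incomplete, are trimmed to frame", {
  base <- strrep("ATG", 318)
  rec <- function(s) tibble::tibble(
    accession = "X1", organism = "o", breed = NA_character_, sequence = s,
    cds = list(tibble::tibble(gene_raw = "ND1", gene = "ND1", start = 1L,
                              end = nchar(s), strand = "+")))
  # complete TAA stop: 957 -> 954
  s <- paste0(substr(base, 1, 954), "TAA")
  expect_equal(nchar(extract_cds(rec(s), "ND1")$seq), 954)
  # incomplete stop TA: 956 -> 954
  s <- paste0(substr(base, 1, 954), "TA")
  expect_equal(nchar(extract_cds(rec(s), "ND1")$seq), 954)
  # AGA is a stop under the mito code
  s <- paste0(substr(base, 1, 954), "AGA")
  expect_equal(nchar(extract_cds(rec(s), "ND1")$seq), 954)
})

test_that("gene-name synonyms normalize; unknown names fail loudly", {
  expect_equal(normalize_gene_name(c("COI", "COXI", "cox1")),
               rep("COX1", 3))
  expect_equal(normalize_gene_name("ATPase6"), "ATP6")
  expect_equal(normalize_gene_name("NADH dehydrogenase subunit 4L"), "ND4L")
  expect_equal(normalize_gene_name("cytochrome b"), "CYTB")
  expect_equal(normalize_gene_name("MT-ND2"), "ND2")
  # unknown stays unmatched -> extraction errors rather than fuzzy-matching
  expect_equal(normalize_gene_name("mystery gene"), "MYSTERYGENE")
})

test_that("concatenation errors when a gene length disagrees across records", {
  fx <- make_gb_fixture()
  recs <- read_genbank(fx$files)
  # shorten ND1 by one codon in record 2
  cds2 <- recs$cds[[2]]
  seq2 <- recs$sequence[2]
  recs$sequence[2] <- substr(seq2, 4, nchar(seq2))
  cds2$end <- cds2$end - 3L
  cds2$start[cds2$gene == "CYTB"] <- cds2$start[cds2$gene == "CYTB"] - 3L
  recs$cds[[2]] <- cds2
  expect_error(concatenate_cds(recs, gene_set = c("ND1", "CYTB")), "ND1")
})

test_that("concatenate is order-stable: shuffling rows only reorders samples", {
  fx <- make_gb_fixture(n = 4, n_codons_per_gene = c(4, 5))
  recs <- read_genbank(fx$files)
  a1 <- concatenate_cds(recs, gene_set = c("ND1", "CYTB"))
  a2 <- concatenate_cds(recs[c(3, 1, 4, 2), ], gene_set = c("ND1", "CYTB"))
  m1 <- setNames(a1$sequences, a1$samples$sample_id)
  m2 <- setNames(a2$sequences, a2$samples$sample_id)
  expect_identical(m1[sort(names(m1))], m2[sort(names(m2))])
})

test_that("FASTA alignment IO round-trips sequences and breed labels", {
  sim <- small_study()
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_alignment(sim$alignment, f)
  back <- read_fasta_alignment(f)
  expect_identical(back$sequences, sim$alignment$sequences)
  expect_identical(back$samples, sim$alignment$samples)
})

test_that("FASTA reader enforces frame and equal lengths, joins breed tables", {
  f <- withr::local_tempfile(fileext = ".fasta")
  readr::write_lines(c(">a", "ATGATGATGATGATGATGATGATGATGATG",
                       ">b", "ATGATGATGATGATGATGATGATGATGATG",
                       ">c", "ATGATGATGATGATGATGATGATGATGATG"), f)
  aln <- read_fasta_alignment(f)
  expect_equal(nchar(aln$sequences[1]) / 3, 10)
  tb <- tibble::tibble(sample_id = c("a", "b", "c"), breed = c("X", "X", "Y"))
  aln <- read_fasta_alignment(f, tb)
  expect_equal(aln$samples$breed, c("X", "X", "Y"))
  readr::write_lines(c(">a", "ATGATGATGA", ">b", "ATGATGATGA"), f)
  expect_error(read_fasta_alignment(f), "multiple of 3")
  readr::write_lines(c(">a", "ATGATG", ">b", "ATGATGATG"), f)
  expect_error(read_fasta_alignment(f), "equal length")
})
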