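# Stage-wise pipeline with plain TSV hand-offs: extract -> load -> age ->
# correlate, plus simulate. Every output file carries a header comment with
# the package version, a config hash and the seed, so reruns with an
# identical config are byte-identical.

.pipeline_header <- function(config) {
  cfg <- config[order(names(config))]
  hash <- rlang::hash(cfg)
  c(sprintf("# mitoload %s",
            as.character(utils::packageVersion("mitoload"))),
    sprintf("# config_hash=%s seed=%s", hash,
            config$seed %||% "NA"))
}

.write_stage_tsv <- function(tbl, path, config) {
  readr::write_lines(.pipeline_header(config), path)
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a pipeline stage TSV (skipping header comments)
#' @param path TSV written by a `pipeline_*` function
#' @return tibble
#' @export
read_stage_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' Stage 1: extract and concatenate CDS from GenBank files
#'
#' @param genbank_paths GenBank flat files (each possibly multi-record)
#' @param out_dir output directory; writes `alignment.fasta` and
#'   `extraction_report.tsv`
#' @param gene_set canonical genes (default [MITO_GENES])
#' @param code_table NCBI translation table (default 2)
#' @return the [codon_alignment()], invisibly
#' @export
pipeline_extract <- function(genbank_paths, out_dir,
                             gene_set = MITO_GENES, code_table = 2) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_genbank(genbank_paths)
  aln <- concatenate_cds(records, gene_set, genetic_code(code_table))
  write_fasta_alignment(aln, file.path(out_dir, "alignment.fasta"))
  cfg <- list(stage = "extract", code_table = code_table,
              gene_set = gene_set, seed = NA)
  .write_stage_tsv(attr(aln, "report"),
                   file.path(out_dir, "extraction_report.tsv"), cfg)
  invisible(aln)
}

#' Stage 2: per-breed load table
#'
#' @param alignment_fasta FASTA from [pipeline_extract()] (or any in-frame
#'   alignment); alternatively pass a [codon_alignment()] directly
#' @param outgroup_fasta FASTA with the outgroup coding sequence(s)
#' @param out_dir output directory; writes `breed_load.tsv` and
#'   `breed_filter.tsv`
#' @param breed_table optional sample-to-breed TSV (see
#'   [read_fasta_alignment()])
#' @param n_boot,seed,code_table,omega_s_mode passed to
#'   [estimate_breed_load()]
#' @return the `breed_load` tibble, invisibly
#' @export
pipeline_load <- function(alignment_fasta, outgroup_fasta, out_dir,
                          breed_table = NULL, n_boot = 100L, seed = 1L,
                          code_table = 2,
                          omega_s_mode = "pooled") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  aln <- if (inherits(alignment_fasta, "codon_alignment")) {
    alignment_fasta
  } else read_fasta_alignment(alignment_fasta, breed_table)
  outgroup <- if (is.character(outgroup_fasta) &&
                  !file.exists(outgroup_fasta[1])) {
    outgroup_fasta
  } else read_fasta_alignment(outgroup_fasta)$sequences
  load <- estimate_breed_load(aln, outgroup, genetic_code(code_table),
                              n_boot = n_boot, seed = seed,
                              omega_s_mode = omega_s_mode)
  cfg <- list(stage = "load", code_table = code_table, n_boot = n_boot,
              seed = seed, omega_s_mode = omega_s_mode)
  .write_stage_tsv(tibble::as_tibble(load),
                   file.path(out_dir, "breed_load.tsv"), cfg)
  .write_stage_tsv(attr(load, "filter"),
                   file.path(out_dir, "breed_filter.tsv"), cfg)
  invisible(load)
}

#' Stage 3: per-breed coalescence ages
#'
#' @param alignment_fasta FASTA (or a [codon_alignment()])
#' @param out_dir output directory; writes `breed_age.tsv`
#' @param breed_table optional sample-to-breed TSV
#' @param mu mutation rate per site per year (default [MITO_MU])
#' @param method passed to [coalescence_distance()]
#' @return the `breed_age` tibble, invisibly
#' @export
pipeline_age <- function(alignment_fasta, out_dir, breed_table = NULL,
                         mu = MITO_MU, method = "upgma_root") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  aln <- if (inherits(alignment_fasta, "codon_alignment")) {
    alignment_fasta
  } else read_fasta_alignment(alignment_fasta, breed_table)
  age <- estimate_breed_age(aln, mu = mu, method = method)
  cfg <- list(stage = "age", mu = mu, method = method, seed = NA)
  .write_stage_tsv(tibble::as_tibble(age),
                   file.path(out_dir, "breed_age.tsv"), cfg)
  invisible(age)
}

#' Stage 4: age-load association
#'
#' @param load_tsv path to `breed_load.tsv` (or a `breed_load` tibble)
#' @param age_tsv path to `breed_age.tsv` (or a `breed_age` tibble)
#' @param out_dir output directory; writes `correlation.tsv` and
#'   `age_delta_scatter.tsv`
#' @return the `age_load_cor` object, invisibly
#' @export
pipeline_correlate <- function(load_tsv, age_tsv, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  load <- if (is.character(load_tsv)) read_stage_tsv(load_tsv) else load_tsv
  age <- if (is.character(age_tsv)) read_stage_tsv(age_tsv) else age_tsv
  cor <- correlate_age_load(load, age)
  cfg <- list(stage = "correlate", seed = NA)
  .write_stage_tsv(cor$results, file.path(out_dir, "correlation.tsv"), cfg)
  .write_stage_tsv(cor$scatter,
                   file.path(out_dir, "age_delta_scatter.tsv"), cfg)
  invisible(cor)
}

#' Stage 0: simulate a study dataset to disk
#'
#' Writes the concatenated alignment (FASTA), the outgroup (FASTA), the
#' ground-truth table (TSV), per-breed genealogies (newick) and, when gene
#' boundaries are present, GenBank fixtures.
#'
#' @param config a [sim_config()]
#' @param out_dir output directory
#' @param genbank also write per-sample GenBank fixtures (default TRUE)
#' @return the [simulate_study()] result, invisibly
#' @export
pipeline_simulate <- function(config = sim_config(), out_dir,
                              genbank = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_study(config)
  write_fasta_alignment(sim$alignment, file.path(out_dir, "alignment.fasta"))
  readr::write_lines(c(">outgroup", unname(sim$outgroup)),
                     file.path(out_dir, "outgroup.fasta"))
  cfg <- unclass(config)
  .write_stage_tsv(sim$truth, file.path(out_dir, "truth.tsv"), cfg)
  ape::write.tree(do.call(c, unname(sim$trees)),
                  file.path(out_dir, "genealogies.nwk"))
  if (genbank && !is.null(sim$alignment$gene_boundaries)) {
    write_genbank_fixtures(sim$alignment, file.path(out_dir, "genbank"))
  }
  invisible(sim)
}
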