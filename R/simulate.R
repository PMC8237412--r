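# Coalescent codon simulator. Each breed gets an independent Kingman
# genealogy rescaled to a chosen root height (substitutions per site);
# codons evolve along branches under a K2P-biased mutation process in which
# synonymous changes are accepted at relative rate 1, nonsynonymous changes
# at relative rate omega, transitions carry weight kappa, and mutations to
# stop codons are rejected. Branch lengths are realized substitutions per
# nucleotide site (the number of accepted events on a branch is Poisson
# with mean length x sites), so distance-based estimators see the intended
# depths. Polymorphism-level omega (omega_poly, per breed) and
# divergence-level omega (omega_div, outgroup branch) are separately
# tunable, which is exactly the omega_P > omega_S situation the load
# estimator is built to detect. Ground truth (realized synonymous and
# nonsynonymous counts, genealogy heights, implied delta) is emitted with
# every dataset.

#' Simulation configuration
#'
#' Defaults mirror the scale of the cattle mitogenome study: 18 breeds,
#' 10 samples each, 3,743 codons (11,229 bp), breed root heights spanning
#' 1.7e-4 to 7e-3 substitutions per site (8.3 Kyr to 340 Kyr at
#' mu = 2.043e-8), polymorphism omega decaying from 0.6 to 0.12 with breed
#' depth, divergence omega 0.1 at an outgroup depth of 0.05 subs/site
#' (cow-bison scale), transition/transversion rate ratio 10.
#'
#' @param n_breeds number of breeds
#' @param samples_per_breed sampled mitogenomes per breed (>= 2)
#' @param n_codons codons in the concatenated alignment
#' @param root_height_per_breed numeric vector (recycled to `n_breeds`):
#'   genealogy root height, substitutions per site
#' @param omega_poly_per_breed numeric vector (recycled): within-breed
#'   nonsynonymous/synonymous rate ratio
#' @param omega_div divergence omega on the outgroup lineage
#' @param outgroup_depth outgroup branch length, substitutions per site
#' @param kappa transition/transversion rate ratio
#' @param mu_per_year mutation rate used for age bookkeeping
#' @param seed integer RNG seed
#' @return a `sim_config` list
#' @export
sim_config <- function(n_breeds = 18L,
                       samples_per_breed = 10L,
                       n_codons = 3743L,
                       root_height_per_breed =
                         exp(seq(log(1.7e-4), log(7e-3),
                                 length.out = n_breeds)),
                       omega_poly_per_breed =
                         exp(seq(log(0.6), log(0.12),
                                 length.out = n_breeds)),
                       omega_div = 0.1,
                       outgroup_depth = 0.05,
                       kappa = 10,
                       mu_per_year = MITO_MU,
                       seed = 1L) {
  cfg <- list(n_breeds = as.integer(n_breeds),
              samples_per_breed = as.integer(samples_per_breed),
              n_codons = as.integer(n_codons),
              root_height_per_breed = rep_len(root_height_per_breed,
                                              n_breeds),
              omega_poly_per_breed = rep_len(omega_poly_per_breed, n_breeds),
              omega_div = omega_div,
              outgroup_depth = outgroup_depth,
              kappa = kappa,
              mu_per_year = mu_per_year,
              seed = as.integer(seed))
  stopifnot(cfg$samples_per_breed >= 2L, cfg$n_codons >= 1L,
            all(cfg$root_height_per_breed > 0),
            all(cfg$omega_poly_per_breed >= 0),
            cfg$omega_div >= 0, cfg$outgroup_depth > 0, cfg$kappa > 0,
            cfg$mu_per_year > 0)
  structure(cfg, class = "sim_config")
}

#' Simulate an ultrametric coalescent genealogy
#'
#' Kingman-coalescent topology (via [ape::rcoal()]) with all edge lengths
#' rescaled so the root-to-tip height equals `root_height` exactly.
#'
#' @param n_samples number of tips (>= 2)
#' @param root_height target height, substitutions per site
#' @param seed integer RNG seed
#' @return an [ape::rcoal()] `phylo` tree, ultrametric, height
#'   `root_height`
#' @export
simulate_genealogy <- function(n_samples, root_height, seed = 1L) {
  stopifnot(n_samples >= 2L, root_height >= 0)
  set.seed(seed)
  tr <- ape::rcoal(n_samples)
  h <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * (root_height / h)
  tr
}

# Per-codon mutation weight tables for a code/omega/kappa combination:
# w[c, m] is the rate weight of the m-th of the 9 single-base mutations of
# codon c (3 positions x 3 alternative bases); mutations to stops get 0.
.mutation_weights <- function(code, omega, kappa) {
  W <- matrix(0, 64, 9)
  target <- matrix(0L, 64, 9)  # resulting codon index
  m <- 0L
  for (p in 1:3) {
    for (boff in 1:3) {
      m <- m + 1L
      cur <- .CODON_BASE[, p]
      tgt_base <- ((cur - 1L + boff) %% 4L) + 1L
      mut <- .mutate_codon_idx(1:64, p, tgt_base)
      ts <- .IS_TRANSITION[cbind(cur, tgt_base)]
      syn <- code$syn[cbind(1:64, rep(p, 64), tgt_base)]
      w <- ifelse(ts, kappa, 1) * ifelse(syn, 1, omega)
      w[!code$is_sense | !code$is_sense[mut]] <- 0  # reject stops
      W[, m] <- w
      target[, m] <- mut
    }
  }
  # syn flag per mutation slot, for truth bookkeeping
  synm <- matrix(FALSE, 64, 9)
  m <- 0L
  for (p in 1:3) {
    for (boff in 1:3) {
      m <- m + 1L
      tgt_base <- ((.CODON_BASE[, p] - 1L + boff) %% 4L) + 1L
      synm[, m] <- code$syn[cbind(1:64, rep(p, 64), tgt_base)]
    }
  }
  list(W = W, target = target, syn = synm)
}

# Evolve codon-index vector `idx` along one branch of length t (subs per
# nucleotide site). The number of accepted substitutions is Poisson with
# mean t * 3 * n_codons; each event lands on a codon/mutation slot with
# probability proportional to its current weight. Returns the evolved
# vector plus realized synonymous/nonsynonymous counts.
.evolve_branch <- function(idx, t, mw) {
  n_events <- stats::rpois(1L, t * 3 * length(idx))
  n_syn <- 0L; n_non <- 0L
  if (n_events > 0L) {
    for (e in seq_len(n_events)) {
      w <- mw$W[idx, , drop = FALSE]          # n_codons x 9
      slot <- sample.int(length(w), 1L, prob = as.vector(w))
      codon_i <- (slot - 1L) %% nrow(w) + 1L
      mut_j <- (slot - 1L) %/% nrow(w) + 1L
      if (mw$syn[idx[codon_i], mut_j]) n_syn <- n_syn + 1L
      else n_non <- n_non + 1L
      idx[codon_i] <- mw$target[idx[codon_i], mut_j]
    }
  }
  list(idx = idx, n_syn = n_syn, n_non = n_non)
}

#' Evolve codon sequences down a genealogy
#'
#' Continuous-time codon substitution along each branch of `tree` starting
#' from `root_sequence`: transitions weighted `kappa`, nonsynonymous
#' changes weighted `omega`, mutations to stop codons rejected. Tip
#' sequences are stop-free and equal length by construction.
#'
#' @param tree a `phylo` with branch lengths in substitutions per site
#' @param root_sequence in-frame, stop-free nucleotide string
#' @param omega nonsynonymous/synonymous rate ratio
#' @param kappa transition/transversion rate ratio
#' @param seed integer RNG seed
#' @param code a [genetic_code()]
#' @return list: `tips` (named character vector of tip sequences, in tip
#'   label order), `n_syn`, `n_non` (realized substitution counts over the
#'   whole tree)
#' @export
evolve_codons <- function(tree, root_sequence, omega, kappa = 10,
                          seed = 1L, code = genetic_code(2)) {
  idx0 <- .encode_codons(toupper(root_sequence))
  if (anyNA(idx0) || any(!code$is_sense[idx0])) {
    stop("root sequence must be unambiguous and stop-free")
  }
  mw <- .mutation_weights(code, omega, kappa)
  set.seed(seed)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- idx0
  n_syn <- 0L; n_non <- 0L
  # cladewise (preorder) edge order guarantees parents precede children
  ord <- if (nrow(tree$edge) > 1L) stats::reorder(tree, "cladewise") else tree
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1]; child <- ord$edge[k, 2]
    ev <- .evolve_branch(seqs[[par]], ord$edge.length[k], mw)
    seqs[[child]] <- ev$idx
    n_syn <- n_syn + ev$n_syn
    n_non <- n_non + ev$n_non
  }
  tips <- vapply(seqs[seq_len(ntip)], .decode_codons, character(1))
  names(tips) <- tree$tip.label
  list(tips = tips, n_syn = n_syn, n_non = n_non)
}

#' Draw a random stop-free root codon sequence
#'
#' @param n_codons length in codons
#' @param seed integer RNG seed
#' @param code a [genetic_code()]
#' @return nucleotide string of length `3 * n_codons`
#' @export
random_root_sequence <- function(n_codons, seed = 1L,
                                 code = genetic_code(2)) {
  set.seed(seed)
  sense <- which(code$is_sense)
  .decode_codons(sample(sense, n_codons, replace = TRUE))
}

#' Simulate a full breed-panel study
#'
#' Per-breed alignments from independent genealogies sharing one root
#' sequence, evolved with the breed's `omega_poly`; one outgroup sequence
#' evolved from the same root at `outgroup_depth` with `omega_div`. Ground
#' truth (realized counts, heights, implied delta
#' `1 - omega_div / omega_poly`) is returned alongside.
#'
#' @param config a [sim_config()]
#' @param gene_table optional tibble (`gene`, `n_codons`) used to label
#'   gene boundaries; default [mito_gene_table()] when `n_codons` matches
#'   its total, else a single synthetic gene
#' @return list: `alignment` (a [codon_alignment()] with breed labels
#'   breed01..), `outgroup` (named character), `truth` (per-breed tibble),
#'   `trees` (named list of `phylo`), `root_sequence`, `config`
#' @export
simulate_study <- function(config = sim_config(), gene_table = NULL) {
  stopifnot(inherits(config, "sim_config"))
  code <- genetic_code(2)
  if (is.null(gene_table) &&
      config$n_codons == sum(mito_gene_table()$n_codons)) {
    gene_table <- mito_gene_table()
  }
  root <- random_root_sequence(config$n_codons, seed = config$seed,
                               code = code)
  breeds <- sprintf("breed%02d", seq_len(config$n_breeds))
  seqs <- character(0); ids <- character(0); labs <- character(0)
  trees <- list()
  truth <- purrr::map_dfr(seq_len(config$n_breeds), function(b) {
    tr <- simulate_genealogy(config$samples_per_breed,
                             config$root_height_per_breed[b],
                             seed = config$seed + 1000L + b)
    tr$tip.label <- sprintf("%s_s%02d", breeds[b],
                            seq_len(config$samples_per_breed))
    ev <- evolve_codons(tr, root, config$omega_poly_per_breed[b],
                        config$kappa, seed = config$seed + 2000L + b,
                        code = code)
    trees[[breeds[b]]] <<- tr
    seqs <<- c(seqs, unname(ev$tips))
    ids <<- c(ids, names(ev$tips))
    labs <<- c(labs, rep(breeds[b], length(ev$tips)))
    tibble::tibble(
      breed = breeds[b],
      root_height = config$root_height_per_breed[b],
      age_years = config$root_height_per_breed[b] / config$mu_per_year,
      omega_poly = config$omega_poly_per_breed[b],
      omega_div = config$omega_div,
      true_delta = ifelse(config$omega_poly_per_breed[b] > 0,
                          1 - config$omega_div /
                            config$omega_poly_per_breed[b], NA_real_),
      n_syn_subs = ev$n_syn, n_non_subs = ev$n_non)
  })
  # outgroup: a single branch from the shared root
  og_tree <- list(edge = matrix(c(2L, 1L), 1, 2),
                  edge.length = config$outgroup_depth,
                  tip.label = "outgroup", Nnode = 1L)
  class(og_tree) <- "phylo"
  og <- evolve_codons(og_tree, root, config$omega_div, config$kappa,
                      seed = config$seed + 3000L, code = code)
  bounds <- if (!is.null(gene_table)) {
    glen <- 3L * gene_table$n_codons
    tibble::tibble(gene = gene_table$gene,
                   start = cumsum(c(1L, utils::head(glen, -1))),
                   length = glen)
  } else NULL
  aln <- codon_alignment(seqs, ids, labs, bounds)
  list(alignment = aln, outgroup = og$tips,
       truth = dplyr::mutate(truth,
                             outgroup_n_syn = og$n_syn,
                             outgroup_n_non = og$n_non),
       trees = trees, root_sequence = root, config = config)
}

#' Representative bovine mitochondrial gene sizes (synthetic)
#'
#' Thirteen protein-coding genes with codon counts approximating real
#' bovine mito CDS sizes and summing to 3,743 codons (11,229 bp after
#' concatenation). Used by the simulator's fixture writer; the sizes are
#' representative, not copied from any single accession.
#'
#' @return tibble with `gene` (canonical order) and `n_codons`
#' @export
mito_gene_table <- function() {
  tibble::tibble(
    gene = MITO_GENES,
    n_codons = c(318L, 347L, 514L, 227L, 66L, 226L, 261L,
                 115L, 98L, 459L, 606L, 175L, 331L)
  )
}

# ---- GenBank fixture writer -------------------------------------------

.wrap_origin <- function(seq) {
  starts <- seq(1L, nchar(seq), by = 60L)
  vapply(starts, function(s) {
    chunk <- substr(seq, s, min(s + 59L, nchar(seq)))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    sprintf("%9d %s", s, paste(blocks, collapse = " "))
  }, character(1))
}

#' Write minimal GenBank flat-file fixtures for an alignment
#'
#' One record per sample with a source feature carrying the breed
#' qualifier and one CDS feature per gene boundary; [read_genbank()] and
#' [concatenate_cds()] round-trip these files to the identical alignment.
#' A terminal TAA stop is appended to each gene (the concatenated
#' alignment stores stop-trimmed CDS), so extraction re-trims to the input.
#'
#' @param alignment a [codon_alignment()] with `gene_boundaries`
#' @param out_dir output directory (created if needed)
#' @param organism organism name written to the source feature
#' @return invisible character vector of the files written
#' @export
write_genbank_fixtures <- function(alignment, out_dir,
                                   organism = "Bos taurus") {
  stopifnot(inherits(alignment, "codon_alignment"),
            !is.null(alignment$gene_boundaries))
  gb <- alignment$gene_boundaries
  if (sum(gb$length) != nchar(alignment$sequences[1])) {
    stop("gene boundaries must cover the alignment")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- purrr::map_chr(seq_along(alignment$sequences), function(i) {
    id <- alignment$samples$sample_id[i]
    breed <- alignment$samples$breed[i]
    genome <- ""
    feats <- character(0)
    pos <- 0L
    for (g in seq_len(nrow(gb))) {
      gseq <- substr(alignment$sequences[i], gb$start[g],
                     gb$start[g] + gb$length[g] - 1L)
      gseq <- paste0(gseq, "TAA")  # terminal stop, re-trimmed on extraction
      feats <- c(feats,
                 sprintf("     CDS             %d..%d", pos + 1L,
                         pos + nchar(gseq)),
                 sprintf("                     /gene=\"%s\"", gb$gene[g]))
      genome <- paste0(genome, gseq)
      pos <- pos + nchar(gseq)
    }
    src <- c(sprintf("     source          1..%d", nchar(genome)),
             sprintf("                     /organism=\"%s\"", organism))
    if (!is.na(breed)) {
      src <- c(src, sprintf("                     /breed=\"%s\"", breed))
    }
    lines <- c(
      sprintf("LOCUS       %s %d bp    DNA     circular     01-JAN-2026",
              id, nchar(genome)),
      sprintf("DEFINITION  %s mitochondrion, synthetic fixture.", organism),
      sprintf("ACCESSION   %s", id),
      "FEATURES             Location/Qualifiers",
      src, feats,
      "ORIGIN",
      .wrap_origin(tolower(genome)),
      "//")
    f <- file.path(out_dir, paste0(id, ".gb"))
    readr::write_lines(lines, f)
    f
  })
  invisible(files)
}
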