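#' Default condition-to-category map for the time-course design
#'
#' Twenty differential-expression contrasts from a desiccation time-course
#' design: heat and oxidative exposures ("stress"), mannitol/NaCl/trehalose
#' exposures ("osmotic"), and the preconditioning/rehydration series
#' ("anhydrobiosis").
#'
#' @return Named character vector `condition -> category`.
#' @export
default_condition_categories <- function() {
  c(
    Heat42_T1 = "stress", Heat42_T24 = "stress",
    Paraquat_T1 = "stress", Paraquat_T24 = "stress",
    Mannitol_T3 = "osmotic", Mannitol_T24 = "osmotic",
    NaCl_T1 = "osmotic", NaCl_T3 = "osmotic", NaCl_T24 = "osmotic",
    Trehalose_T1 = "osmotic", Trehalose_T3 = "osmotic",
    PreCondTre_T0vsT12 = "anhydrobiosis",
    PreCondTre_T12vsT24 = "anhydrobiosis",
    PreCondTre_T24vsT36 = "anhydrobiosis",
    PreCondTre_T36vsT48 = "anhydrobiosis",
    PreCondTre_T48vsRehyT0 = "anhydrobiosis",
    Rehydration_T0vsT3 = "anhydrobiosis",
    Rehydration_T3vsT12 = "anhydrobiosis",
    Rehydration_T12vsT24 = "anhydrobiosis",
    Rehydration_T24vsT72 = "anhydrobiosis"
  )
}

#' Configuration for the synthetic sandbox-genome generator
#'
#' Defaults emulate the study conditions of a four-chromosome midge genome
#' whose smallest chromosome is a "sandbox": depressed genomic and coding
#' GC, a high-diversity sub-region, transversion excess, depleted
#' essential/conserved genes, an excess of lineage-specific genes, a large
#' silent multicopy family, and a tandem paralog island whose blocks differ
#' in regulation signature, protein pI and upstream HSE presence. Chromosome
#' length ratios, gene densities, coding-GC targets, expressed fractions and
#' the family copy numbers follow the published per-chromosome table; the
#' total is scaled to ~4 Mb so all of those counts coexist at desk scale.
#'
#' @param seed Mandatory integer seed; the bundle is a deterministic
#'   function of the full configuration.
#' @param total_length Total genome size in bases (default 4e6).
#' @param genes_per_mb Per-chromosome gene densities (genes/Mb).
#' @param coding_gc Per-chromosome coding-sequence GC targets.
#' @param background_gc Per-chromosome intergenic GC (sandbox 0.03 below).
#' @param noncoding_fraction Per-chromosome non-coding gene fraction.
#' @param expressed_fraction Per-chromosome expressed-gene fraction for
#'   ordinary genes.
#' @param snv_density Baseline segregating sites per base (default 0.005).
#' @param pi_region Fractional (start, end) of the sandbox chromosome with
#'   elevated diversity (default the 3-12 Mb analog, c(0.214, 0.856)).
#' @param pi_multiplier Site-density multiplier inside the region (3).
#' @param depth Pooled read depth per site (50).
#' @param tstv_target Per-chromosome transition/transversion targets.
#' @param lineage_fraction Per-chromosome fraction of ordinary coding genes
#'   that are focal- or genus-specific.
#' @param essential_size,essential_sandbox_odds Size of each conserved gene
#'   set and the relative odds of drawing a sandbox gene into it.
#' @param family_copies,family_sandbox,family_silent Multicopy-family copy
#'   number, copies on the sandbox, and silent copies (117, 45, 115).
#' @param island_blocks,island_genes_per_block Tandem-island block layout.
#' @param island_pi_targets,island_pi_sd Per-block protein pI targets
#'   (6.87, 5.18, 4.74) and within-block SD.
#' @param island_signatures Per-block regulation signatures (categories
#'   joined with `+`).
#' @param hse_block,hse_prob Which block receives upstream heat-shock
#'   elements and with what probability (block 1, 4/5).
#' @param n_samples Expression samples (6).
#' @param gene_length,noncoding_length CDS span of coding genes (multiple
#'   of 3) and span of non-coding genes.
#' @return A validated `sandbox_sim_config` list.
#' @export
simulation_config <- function(
    seed,
    total_length = 4e6,
    genes_per_mb = c(143.0, 139.5, 133.5, 231.2),
    coding_gc = c(0.342, 0.346, 0.342, 0.315),
    background_gc = c(0.28, 0.28, 0.28, 0.25),
    noncoding_fraction = c(0.07, 0.07, 0.07, 0.03),
    expressed_fraction = c(0.57, 0.56, 0.53, 0.36),
    snv_density = 0.005,
    pi_region = c(3 / 14.02, 12 / 14.02),
    pi_multiplier = 3,
    depth = 50,
    tstv_target = c(2, 2, 2, 1),
    lineage_fraction = c(0.3, 0.3, 0.3, 0.6),
    essential_size = 150,
    essential_sandbox_odds = 0.25,
    family_copies = 117,
    family_sandbox = 45,
    family_silent = 115,
    island_blocks = 3,
    island_genes_per_block = 5,
    island_pi_targets = c(6.87, 5.18, 4.74),
    island_pi_sd = 0.3,
    island_signatures = c("anhydrobiosis+osmotic", "osmotic",
                          "anhydrobiosis"),
    hse_block = 1,
    hse_prob = 4 / 5,
    n_samples = 6,
    gene_length = 900,
    noncoding_length = 400) {
  if (missing(seed)) abort("seed is mandatory")
  ref_lengths <- c(36877143, 35209052, 31432203, 14019908)
  chrom_lengths <- as.integer(round(ref_lengths / sum(ref_lengths) *
                                      total_length))
  cfg <- list(
    seed = as.integer(seed),
    chrom = paste0("chr_", 1:4),
    sandbox = 4L,
    chrom_lengths = chrom_lengths,
    genes_per_mb = genes_per_mb,
    coding_gc = coding_gc,
    background_gc = background_gc,
    noncoding_fraction = noncoding_fraction,
    expressed_fraction = expressed_fraction,
    snv_density = snv_density,
    pi_region = pi_region,
    pi_multiplier = pi_multiplier,
    depth = as.integer(depth),
    tstv_target = tstv_target,
    lineage_fraction = lineage_fraction,
    essential_size = as.integer(essential_size),
    essential_sandbox_odds = essential_sandbox_odds,
    family_copies = as.integer(family_copies),
    family_sandbox = as.integer(family_sandbox),
    family_silent = as.integer(family_silent),
    island_blocks = as.integer(island_blocks),
    island_genes_per_block = as.integer(island_genes_per_block),
    island_pi_targets = island_pi_targets,
    island_pi_sd = island_pi_sd,
    island_signatures = island_signatures,
    hse_block = as.integer(hse_block),
    hse_prob = hse_prob,
    n_samples = as.integer(n_samples),
    gene_length = as.integer(gene_length),
    noncoding_length = as.integer(noncoding_length)
  )
  stopifnot(cfg$gene_length %% 3 == 0,
            all(cfg$chrom_lengths > 0),
            all(cfg$lineage_fraction >= 0 & cfg$lineage_fraction <= 1),
            cfg$family_sandbox <= cfg$family_copies,
            cfg$family_silent <= cfg$family_copies,
            length(cfg$island_pi_targets) == cfg$island_blocks,
            length(cfg$island_signatures) == cfg$island_blocks)
  structure(cfg, class = "sandbox_sim_config")
}

# ---- low-level sequence builders -------------------------------------------

# random sequence of length n with an exact count of G+C bases
random_seq_exact_gc <- function(n, gc) {
  k <- round(gc * n)
  out <- character(n)
  gc_pos <- sample.int(n, k)
  at_pos <- setdiff(seq_len(n), gc_pos)
  out[gc_pos] <- sample(c("G", "C"), k, replace = TRUE)
  out[at_pos] <- sample(c("A", "T"), n - k, replace = TRUE)
  out
}

STOPS <- c("TAA", "TAG", "TGA")
# GC-preserving permutation into a sense codon
unstop <- c(TAA = "ATA", TAG = "ATG", TGA = "GTA")

# coding sequence with exact GC count and no stop codons
random_cds_exact_gc <- function(n_codons, gc) {
  s <- random_seq_exact_gc(3L * n_codons, gc)
  cds <- paste0(s[c(TRUE, FALSE, FALSE)], s[c(FALSE, TRUE, FALSE)],
                s[c(FALSE, FALSE, TRUE)])
  bad <- cds %in% STOPS
  cds[bad] <- unstop[cds[bad]]
  paste(cds, collapse = "")
}

translate_cds <- function(cds) {
  paste(Biostrings::GENETIC_CODE[split_codons(cds)], collapse = "")
}

# protein of length n_aa with pI within tol of target, by accept-reject over
# single charged-residue substitutions (restarts on the rare stuck walk)
protein_with_pi <- function(n_aa, target, tol = 0.1, max_iter = 2000,
                            restarts = 5) {
  alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (r in seq_len(restarts)) {
    aa <- sample(alphabet, n_aa, replace = TRUE)
    cur <- isoelectric_point(paste(aa, collapse = ""))
    for (iter in seq_len(max_iter)) {
      if (abs(cur - target) <= tol) return(paste(aa, collapse = ""))
      cand <- aa
      i <- sample.int(n_aa, 1)
      cand[i] <- if (cur < target) sample(c("K", "R"), 1) else
        sample(c("D", "E"), 1)
      new <- isoelectric_point(paste(cand, collapse = ""))
      # accept only moves that do not overshoot further than we started
      if (abs(new - target) < abs(cur - target)) {
        aa <- cand
        cur <- new
      }
    }
  }
  abort("protein_with_pi failed to reach target; widen tol or lengthen")
}

# synonymous-choice back-translation steering cumulative GC toward target
backtranslate_gc <- function(protein, gc_target) {
  aa <- strsplit(protein, "")[[1]]
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), unname(code))
  gc_count <- function(codon) {
    vapply(strsplit(codon, ""), function(b) sum(b %in% c("G", "C")), 0)
  }
  total_gc <- 0
  out <- character(length(aa))
  for (i in seq_along(aa)) {
    cands <- by_aa[[aa[i]]]
    want <- gc_target * 3 * i - total_gc
    gcs <- gc_count(cands)
    pick <- cands[which.min(abs(gcs - want))]
    out[i] <- pick
    total_gc <- total_gc + gc_count(pick)
  }
  paste(out, collapse = "")
}

# mutated copy of a CDS: per-codon substitution probability, never creating
# stops
mutate_cds <- function(cds, rate = 0.06) {
  codons <- split_codons(cds)
  for (i in seq_along(codons)) {
    if (runif(1) >= rate) next
    repeat {
      pos <- sample.int(3, 1)
      b <- sample(setdiff(BASES, substring(codons[i], pos, pos)), 1)
      cand <- codons[i]
      substring(cand, pos, pos) <- b
      if (!cand %in% STOPS) {
        codons[i] <- cand
        break
      }
    }
  }
  paste(codons, collapse = "")
}

hse_motif <- function(units = 3) {
  n <- function() sample(BASES, 1)
  cores <- rep(c("GAA", "TTC"), length.out = units)
  paste(vapply(cores, function(x) paste0(n(), x, n()), ""), collapse = "")
}

# ---- the generator ----------------------------------------------------------

#' Simulate a complete sandbox-genome input bundle
#'
#' Emits an internally consistent file bundle — genome FASTA, gene GFF3,
#' protein FASTA, expression and DE-call TSVs, pooled-variant VCF, forward
#' and reverse hit tables against five other species, orthogroup TSV, clade
#' map, conserved gene sets, aligned ortholog CDS pairs — plus a JSON truth
#' manifest of every sampled latent value. Two runs with the same config
#' produce byte-identical bundles.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return Invisible list: `dir`, named `paths`, `truth` (list of tibbles),
#'   `config`.
#' @export
simulate_bundle <- function(config, dir) {
  stopifnot(inherits(config, "sandbox_sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  layout <- sim_gene_layout(config)
  genes <- layout$genes
  seqs <- sim_sequences(config, genes)
  genes <- seqs$genes
  truth_chrom <- seqs$truth_chrom

  ann <- genome_annotation(
    tibble(chrom = config$chrom, length = config$chrom_lengths,
           sequence = seqs$sequences),
    select(genes, "gene_id", "chrom", "start", "end", "strand", "biotype",
           "family", "protein")
  )

  expr <- sim_expression(config, genes)
  genes$expressed <- attr(expr, "expressed_truth")
  de <- sim_de_calls(config, genes)
  sites <- sim_sites(config, seqs$sequences)
  homology <- sim_homology(config, genes)
  gene_sets <- sim_gene_sets(config, genes)
  pairs <- sim_cds_pairs(genes)

  paths <- list(
    fasta = file.path(dir, "genome.fasta"),
    gff3 = file.path(dir, "genes.gff3"),
    proteins = file.path(dir, "proteins.fasta"),
    expression = file.path(dir, "expression.tsv"),
    de_calls = file.path(dir, "de_calls.tsv"),
    condition_categories = file.path(dir, "condition_categories.tsv"),
    vcf = file.path(dir, "variants.vcf"),
    orthogroups = file.path(dir, "orthogroups.tsv"),
    clade_map = file.path(dir, "clade_map.tsv"),
    cds_pairs = file.path(dir, "ortholog_cds_pairs.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_genome_fasta(ann, paths$fasta)
  write_genes_gff3(ann, paths$gff3)
  prot <- setNames(genes$protein, genes$gene_id)
  write_protein_fasta(prot[!is.na(prot)], paths$proteins)
  write_matrix_tsv(expr, paths$expression)
  write_matrix_tsv(de$wide, paths$de_calls)
  write_matrix_tsv(tibble(condition = names(default_condition_categories()),
                          category = unname(default_condition_categories())),
                   paths$condition_categories)
  write_allele_counts_vcf(sites$table, paths$vcf,
                          contigs = setNames(config$chrom_lengths,
                                             config$chrom))
  write_orthogroups(homology$groups, paths$orthogroups,
                    species = homology$species_order)
  write_clade_map(homology$clade_map, paths$clade_map)
  write_matrix_tsv(pairs, paths$cds_pairs)

  hit_dir <- file.path(dir, "hits")
  if (!dir.exists(hit_dir)) dir.create(hit_dir)
  for (sp in names(homology$hits)) {
    fwd_path <- file.path(hit_dir, paste0("Pvan_vs_", sp, ".tsv"))
    rev_path <- file.path(hit_dir, paste0(sp, "_vs_Pvan.tsv"))
    write_hits(homology$hits[[sp]]$fwd, fwd_path)
    write_hits(homology$hits[[sp]]$rev, rev_path)
    paths[[paste0("hits_fwd_", sp)]] <- fwd_path
    paths[[paste0("hits_rev_", sp)]] <- rev_path
  }
  set_dir <- file.path(dir, "gene_sets")
  if (!dir.exists(set_dir)) dir.create(set_dir)
  for (sid in names(gene_sets)) {
    p <- file.path(set_dir, paste0(sid, ".txt"))
    writeLines(gene_sets[[sid]], p)
    paths[[paste0("set_", sid)]] <- p
  }

  truth <- list(
    config = unclass(config),
    chromosomes = truth_chrom,
    genes = select(genes, -"protein", -"cds"),
    sites = sites$truth_summary,
    n_sites = nrow(sites$table),
    species = homology$clade_map$species,
    gene_sets = gene_sets
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)

  invisible(list(dir = dir, paths = paths, truth = truth, config = config,
                 annotation = ann))
}

# gene coordinates, biotypes, families, clade labels, island layout
sim_gene_layout <- function(config) {
  n_chrom <- length(config$chrom)
  sandbox <- config$sandbox
  island_n <- config$island_blocks * config$island_genes_per_block
  fam_per_other <- config$family_copies - config$family_sandbox
  margin <- 300L  # upstream margin per gene; promoter edits never collide

  all_genes <- purrr::map_dfr(seq_len(n_chrom), function(ci) {
    len <- config$chrom_lengths[ci]
    n_genes <- round(len / 1e6 * config$genes_per_mb[ci])
    n_noncoding <- round(n_genes * config$noncoding_fraction[ci])
    biotype <- sample(rep(c("noncoding", "coding"),
                          c(n_noncoding, n_genes - n_noncoding)))
    role <- rep("normal", n_genes)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    if (ci == sandbox) {
      # tandem island: consecutive gene slots past halfway, same strand
      i0 <- ceiling(n_genes / 2)
      if (i0 + island_n - 1L > n_genes) {
        abort("infeasible config: sandbox cannot host the tandem island")
      }
      island_idx <- i0:(i0 + island_n - 1L)
      biotype[island_idx] <- "coding"
      role[island_idx] <- "island"
      strand[island_idx] <- "+"
    }
    span <- ifelse(biotype == "noncoding", config$noncoding_length,
                   config$gene_length)
    slack <- len - sum(span) - (n_genes + 1L) * margin
    if (slack < 0) abort("infeasible config: genes do not fit")
    gaps <- c(stats::rmultinom(1, slack, rep(1, n_genes + 1L)))
    starts <- cumsum(gaps[seq_len(n_genes)] + margin) +
      cumsum(c(0L, span[-n_genes])) + 1L
    tibble(chrom = config$chrom[ci],
           start = as.integer(starts), span = span,
           end = as.integer(starts) + span - 1L,
           biotype = biotype, role = role, strand = strand)
  })
  all_genes <- all_genes |>
    mutate(gene_id = sprintf("pv_g%05d", row_number()),
           family = ifelse(.data$role == "island", "Lea", NA_character_),
           block = NA_integer_, pi_target = NA_real_)

  ci_idx <- match(all_genes$chrom, config$chrom)
  island_rows <- which(all_genes$role == "island")
  all_genes$block[island_rows] <-
    rep(seq_len(config$island_blocks),
        each = config$island_genes_per_block)
  all_genes$pi_target[island_rows] <-
    config$island_pi_targets[all_genes$block[island_rows]]

  # multicopy family: scattered coding genes, family_sandbox on the sandbox
  free_sb <- which(all_genes$biotype == "coding" & ci_idx == sandbox &
                     all_genes$role == "normal")
  if (length(free_sb) < config$family_sandbox + 2L) {
    abort("infeasible config: sandbox cannot host family + island")
  }
  fam_sb <- sample(free_sb, config$family_sandbox)
  free_other <- which(all_genes$biotype == "coding" & ci_idx != sandbox)
  fam_other <- sample(free_other, fam_per_other)
  fam_rows <- c(fam_sb, fam_other)
  all_genes$family[fam_rows] <- "IRfam"
  all_genes$role[fam_rows] <- "family"

  # clade labels: family and island are genus-specific; noncoding genes are
  # focal singletons; ordinary coding genes follow the per-chromosome
  # lineage-specific fraction (split evenly focal vs genus)
  lab <- rep(NA_character_, nrow(all_genes))
  lab[all_genes$role %in% c("family", "island")] <- "genus_specific"
  lab[all_genes$biotype == "noncoding"] <- "focal_specific"
  open <- which(is.na(lab))
  f <- config$lineage_fraction[ci_idx[open]]
  u <- runif(length(open))
  lab[open] <- ifelse(u < f / 2, "focal_specific",
                      ifelse(u < f, "genus_specific", "conserved"))
  all_genes$clade_label <- lab

  list(genes = all_genes)
}

# chromosome sequences, per-gene CDS/protein, HSE insertion
sim_sequences <- function(config, genes) {
  ci_idx <- match(genes$chrom, config$chrom)
  genes$cds <- NA_character_
  genes$protein <- NA_character_
  genes$has_hse <- FALSE

  # island proteins hit per-block pI targets
  isl <- which(genes$role == "island")
  for (i in isl) {
    target <- rnorm(1, genes$pi_target[i], config$island_pi_sd)
    p <- protein_with_pi(config$gene_length / 3 - 1, target, tol = 0.1)
    genes$protein[i] <- p
    genes$cds[i] <- paste0(backtranslate_gc(p, config$coding_gc[ci_idx[i]]),
                           "ATG")  # pad to the declared span
  }
  # ordinary + family coding genes: exact-GC CDS, protein by translation
  cod <- which(genes$biotype == "coding" & genes$role != "island")
  for (i in cod) {
    cds <- random_cds_exact_gc(config$gene_length / 3,
                               config$coding_gc[ci_idx[i]])
    genes$cds[i] <- cds
    genes$protein[i] <- translate_cds(cds)
  }

  # which island genes get upstream HSEs
  hse_rows <- isl[genes$block[isl] == config$hse_block]
  genes$has_hse[hse_rows] <- runif(length(hse_rows)) < config$hse_prob

  sequences <- character(length(config$chrom))
  truth_chrom <- tibble(chrom = config$chrom,
                        length = config$chrom_lengths,
                        background_gc = config$background_gc,
                        coding_gc_target = config$coding_gc,
                        intended_gc = NA_real_)
  for (ci in seq_along(config$chrom)) {
    len <- config$chrom_lengths[ci]
    s <- random_seq_exact_gc(len, config$background_gc[ci])
    g <- genes[ci_idx == ci, ]
    for (j in seq_len(nrow(g))) {
      body <- if (g$biotype[j] == "coding") g$cds[j] else
        paste(random_seq_exact_gc(g$end[j] - g$start[j] + 1L,
                                  config$background_gc[ci]), collapse = "")
      stopifnot(nchar(body) == g$end[j] - g$start[j] + 1L)
      s[g$start[j]:g$end[j]] <- strsplit(body, "")[[1]]
      if (isTRUE(g$has_hse[j])) {
        motif <- hse_motif(3)
        off <- sample(30:150, 1)
        ins_from <- if (g$strand[j] == "+") g$start[j] - off - nchar(motif)
        else g$end[j] + off
        m <- strsplit(motif, "")[[1]]
        if (g$strand[j] == "-") {
          m <- rev(chartr("ACGT", "TGCA", m))
        }
        s[ins_from + seq_along(m)] <- m
      }
    }
    sequences[ci] <- paste(s, collapse = "")
    truth_chrom$intended_gc[ci] <-
      sum(s %in% c("G", "C")) / len
  }
  list(sequences = sequences, genes = genes, truth_chrom = truth_chrom)
}

sim_expression <- function(config, genes) {
  ci_idx <- match(genes$chrom, config$chrom)
  expressed <- logical(nrow(genes))
  normal <- genes$role == "normal"
  expressed[normal] <- runif(sum(normal)) <
    config$expressed_fraction[ci_idx[normal]]
  expressed[genes$role == "island"] <- TRUE
  fam <- which(genes$role == "family")
  n_expr_fam <- config$family_copies - config$family_silent
  expressed[sample(fam, n_expr_fam)] <- TRUE

  mat <- matrix(runif(nrow(genes) * config$n_samples, 0, 0.3),
                nrow = nrow(genes))
  n_on <- sum(expressed)
  mat[expressed, ] <- 2 + rlnorm(n_on * config$n_samples,
                                 meanlog = log(20), sdlog = 1)
  colnames(mat) <- sprintf("S%02d", seq_len(config$n_samples))
  out <- bind_cols(tibble(gene_id = genes$gene_id), as_tibble(mat))
  attr(out, "expressed_truth") <- expressed
  out
}

sim_de_calls <- function(config, genes) {
  cats <- default_condition_categories()
  conditions <- names(cats)
  m <- matrix("ns", nrow = nrow(genes), ncol = length(conditions),
              dimnames = list(genes$gene_id, conditions))
  # island genes: >= 1 call in every category of their block signature
  isl <- which(genes$role == "island")
  for (i in isl) {
    sig_cats <- strsplit(config$island_signatures[genes$block[i]],
                         "\\+")[[1]]
    for (cc in sig_cats) {
      cand <- conditions[cats == cc]
      chosen <- sample(cand, sample(1:2, 1))
      m[i, chosen] <- sample(c("up", "down"), length(chosen),
                             replace = TRUE, prob = c(0.7, 0.3))
    }
  }
  # ordinary expressed genes: sparse random calls, but never in the island's
  # home categories for silent genes
  exp_normal <- which(genes$role != "island" & genes$expressed)
  for (i in exp_normal) {
    if (runif(1) < 0.3) {
      chosen <- sample(conditions, sample(1:3, 1))
      m[i, chosen] <- sample(c("up", "down"), length(chosen),
                             replace = TRUE)
    }
  }
  wide <- bind_cols(tibble(gene_id = genes$gene_id),
                    as_tibble(m))
  list(wide = wide, categories = cats)
}

sim_sites <- function(config, sequences) {
  out <- list()
  truth_rows <- list()
  for (ci in seq_along(config$chrom)) {
    len <- config$chrom_lengths[ci]
    segments <- if (ci == config$sandbox) {
      reg <- as.integer(round(config$pi_region * len))
      tibble(from = c(1L, reg[1] + 1L, reg[2] + 1L),
             to = c(reg[1], reg[2], len),
             dens = config$snv_density * c(1, config$pi_multiplier, 1))
    } else {
      tibble(from = 1L, to = len, dens = config$snv_density)
    }
    chrom_seq <- strsplit(sequences[ci], "")[[1]]
    ts_p <- config$tstv_target[ci] / (1 + config$tstv_target[ci])
    for (si in seq_len(nrow(segments))) {
      seg_len <- segments$to[si] - segments$from[si] + 1L
      n_sites <- round(seg_len * segments$dens[si])
      pos <- sort(sample.int(seg_len, n_sites)) + segments$from[si] - 1L
      ref <- chrom_seq[pos]
      transition_of <- c(A = "G", G = "A", C = "T", T = "C")
      is_ts <- runif(n_sites) < ts_p
      alt <- ifelse(is_ts, transition_of[ref],
                    vapply(ref, function(r)
                      sample(setdiff(BASES, c(r, transition_of[r])), 1), ""))
      p_alt <- runif(n_sites, 0.1, 0.5)
      alt_count <- rbinom(n_sites, config$depth, p_alt)
      out[[length(out) + 1L]] <- tibble(
        chrom = config$chrom[ci], pos = pos, ref = ref, alt = unname(alt),
        ref_count = config$depth - alt_count, alt_count = alt_count,
        p_alt = p_alt)
      truth_rows[[length(truth_rows) + 1L]] <- tibble(
        chrom = config$chrom[ci], from = segments$from[si],
        to = segments$to[si], density = segments$dens[si],
        ts_probability = ts_p, n_sites = n_sites)
    }
  }
  tab <- bind_rows(out) |> arrange(.data$chrom, .data$pos)
  # drop rare duplicate/zero-alt artefacts: keep genuinely biallelic records
  tab <- filter(tab, .data$alt_count > 0, .data$alt_count < config$depth)
  list(table = select(tab, -"p_alt"),
       truth_summary = bind_rows(truth_rows))
}

sim_homology <- function(config, genes) {
  species <- c("Pvan", "Ppem", "Pnub", "Cripa", "Dmel", "Agam")
  clade_map <- tibble(
    species = species,
    focal = species == "Pvan",
    clades = list(
      c("Pvan", "Polypedilum", "Chironomidae", "Diptera"),
      c("Ppem", "Polypedilum", "Chironomidae", "Diptera"),
      c("Pnub", "Polypedilum", "Chironomidae", "Diptera"),
      c("Cripa", "Chironomidae", "Diptera"),
      c("Dmel", "Drosophilidae", "Diptera"),
      c("Agam", "Culicidae", "Diptera")
    )
  )
  targets <- setdiff(species, "Pvan")
  congeners <- c("Ppem", "Pnub")
  outgroups <- setdiff(targets, congeners)

  coding <- filter(genes, .data$biotype == "coding")
  counter <- new.env()
  for (sp in targets) assign(sp, 0L, envir = counter)
  new_partner <- function(sp) {
    k <- get(sp, envir = counter) + 1L
    assign(sp, k, envir = counter)
    sprintf("%s_g%05d", sp, k)
  }

  rows <- list()
  membership <- list()  # per gene: named partner list
  gid <- 0L
  for (i in seq_len(nrow(coding))) {
    g <- coding[i, ]
    if (g$role == "family" || g$role == "island") next
    if (g$clade_label == "conserved") {
      sp_in <- c("Ppem",
                 congeners[-1][runif(length(congeners) - 1) < 0.8],
                 outgroups[runif(length(outgroups)) < 0.75])
      if (!any(sp_in %in% outgroups)) sp_in <- c(sp_in, sample(outgroups, 1))
    } else if (g$clade_label == "genus_specific") {
      sp_in <- congeners[runif(2) < 0.8]
      if (!length(sp_in)) sp_in <- sample(congeners, 1)
    } else {
      # focal-specific: half solo groups, half singletons (absent)
      if (runif(1) < 0.5) next
      sp_in <- character(0)
    }
    gid <- gid + 1L
    group <- sprintf("OG%06d", gid)
    partners <- setNames(lapply(sp_in, new_partner), sp_in)
    rows[[length(rows) + 1L]] <- bind_rows(
      tibble(group_id = group, species = "Pvan", gene_id = g$gene_id),
      if (length(sp_in))
        tibble(group_id = group, species = sp_in,
               gene_id = unlist(partners, use.names = FALSE))
    )
    membership[[g$gene_id]] <- partners
  }
  # one big genus-specific group for the multicopy family (a few congener
  # copies), one for the island (congener orthologs)
  fam_ids <- genes$gene_id[genes$role == "family"]
  fam_partners <- c(replicate(3, new_partner("Ppem")), new_partner("Pnub"))
  rows[[length(rows) + 1L]] <- bind_rows(
    tibble(group_id = "OG_family", species = "Pvan", gene_id = fam_ids),
    tibble(group_id = "OG_family", species = c(rep("Ppem", 3), "Pnub"),
           gene_id = fam_partners)
  )
  isl_ids <- genes$gene_id[genes$role == "island"]
  isl_partners <- vapply(isl_ids, function(x) new_partner("Ppem"), "")
  rows[[length(rows) + 1L]] <- bind_rows(
    tibble(group_id = "OG_island", species = "Pvan", gene_id = isl_ids),
    tibble(group_id = "OG_island", species = "Ppem",
           gene_id = unname(isl_partners))
  )
  for (k in seq_along(isl_ids)) {
    membership[[isl_ids[k]]] <- list(Ppem = unname(isl_partners[k]))
  }

  groups <- bind_rows(rows)

  # hit tables: reciprocal hits for every (gene, partner) pair; plus a
  # sprinkle of unreciprocated forward hits
  hits <- list()
  for (sp in targets) {
    fwd <- list(); rev <- list()
    for (gene in names(membership)) {
      partner <- membership[[gene]][[sp]]
      if (is.null(partner)) next
      bs <- runif(1, 200, 500)
      fwd[[length(fwd) + 1L]] <- tibble(
        query = gene, target = partner, evalue = 10^-runif(1, 20, 80),
        bitscore = bs)
      rev[[length(rev) + 1L]] <- tibble(
        query = partner, target = gene, evalue = 10^-runif(1, 20, 80),
        bitscore = bs + runif(1, -5, 5))
    }
    # noise: unreciprocated weak forward hits from non-conserved genes
    lonely <- sample(setdiff(coding$gene_id, names(membership)),
                     min(10L, length(setdiff(coding$gene_id,
                                             names(membership)))))
    for (gene in lonely) {
      fwd[[length(fwd) + 1L]] <- tibble(
        query = gene, target = new_partner(sp),
        evalue = 10^-runif(1, 6, 10), bitscore = runif(1, 60, 90))
    }
    ft <- bind_rows(fwd); rt <- bind_rows(rev)
    attr(ft, "query_species") <- "Pvan"; attr(ft, "target_species") <- sp
    attr(rt, "query_species") <- sp; attr(rt, "target_species") <- "Pvan"
    hits[[sp]] <- list(fwd = ft, rev = rt)
  }
  list(groups = groups, clade_map = clade_map, hits = hits,
       species_order = species)
}

sim_gene_sets <- function(config, genes) {
  pool <- filter(genes, .data$clade_label == "conserved",
                 .data$biotype == "coding")
  sandbox_chrom <- config$chrom[config$sandbox]
  w <- ifelse(pool$chrom == sandbox_chrom,
              config$essential_sandbox_odds, 1)
  n <- min(config$essential_size, nrow(pool) - 1L)
  list(
    essential = sort(sample(pool$gene_id, n, prob = w)),
    busco = sort(sample(pool$gene_id, n, prob = w))
  )
}

sim_cds_pairs <- function(genes) {
  isl <- filter(genes, .data$role == "island")
  if (nrow(isl) == 0) return(tibble(pair_id = character(),
                                    gene_id = character(),
                                    cds_a = character(),
                                    cds_b = character()))
  tibble(
    pair_id = paste0(isl$gene_id, "_vs_Ppem"),
    gene_id = isl$gene_id,
    cds_a = isl$cds,
    cds_b = vapply(isl$cds, mutate_cds, "", rate = 0.06)
  )
}
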