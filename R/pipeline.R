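#' Read a complete input bundle from a directory
#'
#' Loads the file layout emitted by [simulate_bundle()] (or assembled by
#' hand to the same dialects): `genome.fasta`, `genes.gff3`,
#' `proteins.fasta`, `expression.tsv`, `de_calls.tsv`,
#' `condition_categories.tsv`, `variants.vcf`, `orthogroups.tsv`,
#' `clade_map.tsv`, `ortholog_cds_pairs.tsv`, `hits/<A>_vs_<B>.tsv` and
#' `gene_sets/<id>.txt`.
#'
#' @param dir Bundle directory.
#' @param evalue_ceiling E-value ceiling applied when reading hit tables.
#' @return List: `annotation`, `expression`, `de_calls`, `sites`, `hits`
#'   (per target species, `$fwd`/`$rev`), `orthogroups`, `clade_map`,
#'   `gene_sets`, `cds_pairs`.
#' @export
read_bundle <- function(dir, evalue_ceiling = 1e-5) {
  pth <- function(...) file.path(dir, ...)
  ann <- read_genome(pth("genes.gff3"), fasta_path = pth("genome.fasta"),
                     protein_fasta = pth("proteins.fasta"))
  cats <- readr::read_tsv(pth("condition_categories.tsv"),
                          show_col_types = FALSE)
  clade_map <- read_clade_map(pth("clade_map.tsv"))
  focal <- clade_map$species[clade_map$focal]
  hit_files <- list.files(pth("hits"), pattern = "\\.tsv$")
  targets <- unique(sub(paste0("^", focal, "_vs_(.*)\\.tsv$"), "\\1",
                        grep(paste0("^", focal, "_vs_"), hit_files,
                             value = TRUE)))
  hits <- setNames(lapply(targets, function(sp) {
    list(
      fwd = read_hits(pth("hits", paste0(focal, "_vs_", sp, ".tsv")),
                      focal, sp, evalue_ceiling),
      rev = read_hits(pth("hits", paste0(sp, "_vs_", focal, ".tsv")),
                      sp, focal, evalue_ceiling)
    )
  }), targets)
  set_files <- list.files(pth("gene_sets"), pattern = "\\.txt$")
  gene_sets <- setNames(
    lapply(set_files, function(f) readLines(pth("gene_sets", f))),
    sub("\\.txt$", "", set_files))
  list(
    annotation = ann,
    expression = read_expression(pth("expression.tsv"), annotation = ann),
    de_calls = read_de_calls(pth("de_calls.tsv"),
                             setNames(cats$category, cats$condition)),
    sites = read_allele_counts(pth("variants.vcf")),
    hits = hits,
    orthogroups = read_orthogroups(pth("orthogroups.tsv")),
    clade_map = clade_map,
    gene_sets = gene_sets,
    cds_pairs = if (file.exists(pth("ortholog_cds_pairs.tsv")))
      readr::read_tsv(pth("ortholog_cds_pairs.tsv"), show_col_types = FALSE)
  )
}

outgroup_species <- function(clade_map) {
  genus <- clade_map$clades[[which(clade_map$focal)]][2]
  in_genus <- vapply(clade_map$clades, function(p) genus %in% p, TRUE)
  clade_map$species[!in_genus & !clade_map$focal]
}

#' Rank chromosomes by each sandbox indicator
#'
#' A sandbox chromosome is expected to rank first on: lowest mean windowed
#' GC, highest mean windowed pi, lowest mean outgroup conservation ratio,
#' highest lineage-specific gene share, smallest essential-set depletion
#' p-value, and highest non-expressed gene share. Rank 1 = most
#' sandbox-like.
#'
#' @param indicators Tibble with one row per chromosome and columns
#'   `chrom`, `gc_mean`, `pi_mean`, `conservation_mean`, `specific_share`,
#'   `depletion_p`, `nonexpressed_share`.
#' @return Long tibble (`indicator`, `chrom`, `value`, `rank`).
#' @export
rank_sandbox_indicators <- function(indicators) {
  direction <- c(gc_mean = 1, pi_mean = -1, conservation_mean = 1,
                 specific_share = -1, depletion_p = 1,
                 nonexpressed_share = -1)
  indicators |>
    tidyr::pivot_longer(dplyr::all_of(names(direction)),
                        names_to = "indicator", values_to = "value") |>
    group_by(.data$indicator) |>
    mutate(rank = rank(direction[.data$indicator[1]] * .data$value,
                       ties.method = "min")) |>
    ungroup() |>
    select("indicator", "chrom", "value", "rank")
}

#' Run the full sandbox characterization pipeline
#'
#' Chains every stage over a bundle: chromosome summary, windowed GC and
#' pi, Ts/Tv, reciprocal-hit conservation profiles, clade-specificity
#' classification, gene-set enrichment/depletion, pseudogene flagging,
#' tandem-array detection with block grouping, block-pI comparison, HSE
#' scanning, and dN/dS on supplied ortholog CDS pairs — then ranks
#' chromosomes by the six sandbox indicators.
#'
#' @param bundle A bundle list from [read_bundle()] (or the directory path).
#' @param gc_window,pi_window Window sizes in bases for the GC and pi
#'   tracks.
#' @param tpm_threshold Mean-TPM expression cutoff.
#' @param depletion_set Name of the gene set whose depletion p-value is the
#'   ranking indicator (default `"essential"`, else the first set).
#' @param out_dir Optional directory to write TSV outputs and the JSON
#'   report into.
#' @return Object of class `sandbox_report`: list with `summary`, `tracks`,
#'   `conservation`, `specificity`, `enrichment`, `blocks`, `block_pi`,
#'   `hse`, `dnds`, `indicators`, `ranking`, `top_counts`,
#'   `sandbox_candidate`.
#' @export
run_sandbox_pipeline <- function(bundle, gc_window = 1e5, pi_window = 5e4,
                                 tpm_threshold = 1,
                                 depletion_set = "essential",
                                 out_dir = NULL) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  ann <- bundle$annotation

  summary_tab <- summarize_chromosomes(ann, bundle$expression,
                                       tpm_threshold = tpm_threshold)
  gc <- gc_track(ann, window_size = gc_window)
  pi <- pi_track(bundle$sites, ann, window_size = pi_window)
  tstv_tab <- tstv(bundle$sites, scope = "chromosome")

  conserved_sets <- purrr::map(bundle$hits,
                               ~ conserved_genes(.x$fwd, .x$rev))
  cons <- conservation_profile(ann, conserved_sets)
  outg <- outgroup_species(bundle$clade_map)

  assignment <- classify_clades(bundle$orthogroups, bundle$clade_map, ann)
  spec_tot <- specificity_totals(assignment, ann)

  enr <- enrich_sets(ann, bundle$gene_sets)
  if (!depletion_set %in% names(bundle$gene_sets)) {
    depletion_set <- names(bundle$gene_sets)[1]
  }

  flags <- flag_nonexpressed(bundle$expression, threshold = tpm_threshold,
                             annotation = ann)

  arrays <- detect_tandem_arrays(ann)
  blocks <- NULL; block_pi <- NULL; hse <- NULL
  if (nrow(arrays)) {
    main <- arrays[which.max(arrays$n_genes), ]
    sig <- regulation_signature(bundle$de_calls)
    blocks <- group_blocks(main$genes[[1]], sig, array_id = main$array_id)
    if (dplyr::n_distinct(blocks$block) >= 2) {
      block_pi <- tryCatch(compare_block_pi(blocks, ann),
                           error = function(e) NULL)
    }
    hse <- scan_hse_upstream(ann, gene_ids = main$genes[[1]])
  }
  dnds <- if (!is.null(bundle$cds_pairs) && nrow(bundle$cds_pairs)) {
    ng86_dnds_pairs(bundle$cds_pairs)
  }

  chroms <- placed_chromosomes(ann)$chrom
  genes <- placed_genes(ann)
  per_chrom_mean <- function(track) {
    track |>
      group_by(.data$chrom) |>
      summarise(v = mean(.data$value, na.rm = TRUE), .groups = "drop")
  }
  spec_share <- assignment |>
    filter(.data$chrom %in% chroms) |>
    group_by(.data$chrom) |>
    summarise(specific_share = mean(.data$label %in%
                                      c("focal_specific",
                                        "genus_specific")),
              .groups = "drop")
  cons_mean <- cons |>
    filter(.data$target_species %in% outg, .data$chrom %in% chroms) |>
    group_by(.data$chrom) |>
    summarise(conservation_mean = mean(.data$ratio), .groups = "drop")
  depl <- enr |>
    filter(.data$set_id == depletion_set) |>
    select("chrom", depletion_p = "p_deplete")
  indicators <- tibble(chrom = chroms) |>
    left_join(rename(per_chrom_mean(gc), gc_mean = "v"), by = "chrom") |>
    left_join(rename(per_chrom_mean(pi), pi_mean = "v"), by = "chrom") |>
    left_join(cons_mean, by = "chrom") |>
    left_join(spec_share, by = "chrom") |>
    left_join(depl, by = "chrom") |>
    left_join(summary_tab |>
                mutate(nonexpressed_share =
                         .data$nonexpressed / .data$total) |>
                select("chrom", "nonexpressed_share"),
              by = "chrom")
  ranking <- rank_sandbox_indicators(indicators)
  top_counts <- ranking |>
    filter(.data$rank == 1) |>
    dplyr::count(.data$chrom, name = "n_top") |>
    arrange(dplyr::desc(.data$n_top))

  report <- structure(list(
    summary = summary_tab, tracks = list(gc = gc, pi = pi,
                                         tstv = tstv_tab),
    conservation = cons, specificity = spec_tot, enrichment = enr,
    flags = flags, arrays = arrays, blocks = blocks, block_pi = block_pi,
    hse = hse, dnds = dnds, indicators = indicators, ranking = ranking,
    top_counts = top_counts,
    sandbox_candidate = top_counts$chrom[1]
  ), class = "sandbox_report")

  if (!is.null(out_dir)) write_report(report, out_dir,
                                      params = list(
                                        gc_window = gc_window,
                                        pi_window = pi_window,
                                        tpm_threshold = tpm_threshold,
                                        depletion_set = depletion_set))
  report
}

write_report <- function(report, out_dir, params = list()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  readr::write_tsv(report$summary, file.path(out_dir, "summary.tsv"))
  write_window_track(report$tracks$gc, file.path(out_dir, "gc_track.tsv"),
                     params = params)
  write_window_track(report$tracks$pi, file.path(out_dir, "pi_track.tsv"),
                     params = params)
  readr::write_tsv(report$conservation,
                   file.path(out_dir, "conservation.tsv"))
  readr::write_tsv(report$specificity,
                   file.path(out_dir, "specificity.tsv"))
  readr::write_tsv(report$enrichment, file.path(out_dir, "enrichment.tsv"))
  if (!is.null(report$blocks)) {
    readr::write_tsv(report$blocks, file.path(out_dir, "blocks.tsv"))
  }
  if (!is.null(report$dnds)) {
    readr::write_tsv(report$dnds, file.path(out_dir, "dnds.tsv"))
  }
  combined <- list(
    params = params,
    indicators = report$indicators,
    ranking = report$ranking,
    top_counts = report$top_counts,
    sandbox_candidate = report$sandbox_candidate
  )
  jsonlite::write_json(combined, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.sandbox_report <- function(x, ...) {
  cat("<sandbox_report>\n")
  cat("  candidate sandbox chromosome:", x$sandbox_candidate, "\n")
  cat("  top-ranked indicators per chromosome:\n")
  for (i in seq_len(nrow(x$top_counts))) {
    cat("   ", x$top_counts$chrom[i], "-", x$top_counts$n_top[i], "of",
        dplyr::n_distinct(x$ranking$indicator), "\n")
  }
  invisible(x)
}
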