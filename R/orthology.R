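check_pair <- function(hits_fwd, hits_rev) {
  qf <- attr(hits_fwd, "query_species"); tf <- attr(hits_fwd, "target_species")
  qr <- attr(hits_rev, "query_species"); tr <- attr(hits_rev, "target_species")
  if (!is.null(qf) && !is.null(tr) && !identical(qf, tr)) {
    abort("species metadata mismatch: forward query != reverse target")
  }
  if (!is.null(tf) && !is.null(qr) && !identical(tf, qr)) {
    abort("species metadata mismatch: forward target != reverse query")
  }
  invisible(TRUE)
}

#' Genes conserved by reciprocal (bidirectional) hits
#'
#' A query-species gene `g` is conserved against the target species iff some
#' target gene `t` has both a forward hit `g -> t` and a return hit
#' `t -> g`. This is deliberately weaker than reciprocal-*best*-hit
#' ([rbh_pairs()]): any reciprocated pair counts. An `any_hit` mode relaxes
#' further to "g has at least one forward hit".
#'
#' @param hits_fwd,hits_rev Hit tibbles from [read_hits()] for the two
#'   directions of one species pair (same E-value ceiling).
#' @param mode `"reciprocal"` (default) or `"any_hit"`.
#' @return Character vector of conserved query-gene ids (sorted, unique).
#' @export
conserved_genes <- function(hits_fwd, hits_rev,
                            mode = c("reciprocal", "any_hit")) {
  mode <- match.arg(mode)
  check_pair(hits_fwd, hits_rev)
  if (mode == "any_hit") return(sort(unique(hits_fwd$query)))
  recip <- dplyr::inner_join(
    distinct(hits_fwd, .data$query, .data$target),
    distinct(hits_rev, query2 = .data$query, target2 = .data$target),
    by = c("query" = "target2", "target" = "query2")
  )
  sort(unique(recip$query))
}

best_hit_per_query <- function(hits) {
  hits |>
    arrange(.data$query, dplyr::desc(.data$bitscore), .data$evalue,
            .data$target) |>
    distinct(.data$query, .keep_all = TRUE)
}

#' Reciprocal-best-hit (1-to-1 ortholog) pairs
#'
#' `(g, t)` is an RBH iff `t` is `g`'s best forward hit and `g` is `t`'s
#' best reverse hit. "Best" is the maximum bitscore, ties broken by minimum
#' E-value, remaining ties by lexicographically smallest target id, so the
#' result is deterministic.
#'
#' @inheritParams conserved_genes
#' @return Tibble (`query`, `target`), one row per RBH pair.
#' @export
rbh_pairs <- function(hits_fwd, hits_rev) {
  check_pair(hits_fwd, hits_rev)
  bf <- best_hit_per_query(hits_fwd)
  br <- best_hit_per_query(hits_rev)
  dplyr::inner_join(
    select(bf, "query", "target"),
    select(br, rq = "query", rt = "target"),
    by = c("query" = "rt", "target" = "rq")
  ) |>
    arrange(.data$query)
}

#' Per-chromosome conservation profile
#'
#' For each target species, the fraction of each placed chromosome's genes
#' found in that species' conserved set. Genes on unplaced scaffolds are
#' excluded from chromosome rows and reported under chromosome
#' `"(unplaced)"`.
#'
#' @param annotation A [genome_annotation()].
#' @param conserved_sets Named list: target species id -> character vector of
#'   conserved query-gene ids (e.g. from [conserved_genes()]).
#' @return Tibble (`target_species`, `chrom`, `conserved`, `total`,
#'   `ratio`).
#' @export
conservation_profile <- function(annotation, conserved_sets) {
  genes <- annotation$genes
  placed_ids <- annotation$chromosomes$chrom[annotation$chromosomes$placed]
  genes <- mutate(genes, chrom_out = ifelse(.data$chrom %in% placed_ids,
                                            .data$chrom, "(unplaced)"))
  unknown <- setdiff(unlist(conserved_sets, use.names = FALSE),
                     genes$gene_id)
  if (length(unknown)) {
    abort(paste0("conserved set names unknown gene: ", unknown[1]))
  }
  purrr::imap_dfr(conserved_sets, function(set, sp) {
    genes |>
      group_by(chrom = .data$chrom_out) |>
      summarise(conserved = sum(.data$gene_id %in% set), total = n(),
                .groups = "drop") |>
      mutate(target_species = sp, ratio = .data$conserved / .data$total)
  }) |>
    select("target_species", "chrom", "conserved", "total", "ratio")
}

# position (1 = species itself, 2 = next clade, ...) of the narrowest clade
# on the focal path containing every member species
narrowest_on_focal_path <- function(member_species, clade_map) {
  focal_row <- which(clade_map$focal)
  focal_path <- clade_map$clades[[focal_row]]
  paths <- setNames(clade_map$clades, clade_map$species)
  for (i in seq_along(focal_path)) {
    clade <- focal_path[i]
    inside <- vapply(member_species,
                     function(s) clade %in% paths[[s]], TRUE)
    if (all(inside)) return(i)
  }
  length(focal_path)
}

#' Clade-specificity classification of focal-species genes
#'
#' Each orthogroup is labelled by the narrowest clade on the focal species'
#' clade path that contains every member species: the focal species alone
#' gives `focal_specific`, anything within the genus (the second clade on
#' the path) gives `genus_specific`, everything wider is `conserved`. The
#' group label propagates to its focal member genes. Focal genes absent from
#' every orthogroup are singletons: `focal_specific` by default, or
#' `unassigned` when `singletons_focal = FALSE`.
#'
#' @param groups Long orthogroup tibble from [read_orthogroups()].
#' @param clade_map Tibble from [read_clade_map()].
#' @param annotation A [genome_annotation()].
#' @param singletons_focal Treat orthogroup-less focal genes as
#'   focal-specific (default TRUE).
#' @return Tibble (`gene_id`, `chrom`, `start`, `label`, `group_id`), one
#'   row per annotated gene; `label` is one of `focal_specific`,
#'   `genus_specific`, `conserved`, `unassigned`.
#' @export
classify_clades <- function(groups, clade_map, annotation,
                            singletons_focal = TRUE) {
  validate_clade_map(clade_map)
  unknown_sp <- setdiff(unique(groups$species), clade_map$species)
  if (length(unknown_sp)) {
    abort(paste0("orthogroup species not in clade map: ", unknown_sp[1]))
  }
  dup <- groups |>
    distinct(.data$group_id, .data$gene_id) |>
    dplyr::count(.data$gene_id) |>
    filter(.data$n > 1)
  if (nrow(dup)) {
    abort(paste0("gene in more than one orthogroup: ", dup$gene_id[1]))
  }
  group_label <- groups |>
    group_by(.data$group_id) |>
    summarise(pos = narrowest_on_focal_path(unique(.data$species),
                                            clade_map),
              .groups = "drop") |>
    mutate(label = dplyr::case_when(
      .data$pos == 1 ~ "focal_specific",
      .data$pos == 2 ~ "genus_specific",
      TRUE ~ "conserved"
    ))
  focal_sp <- clade_map$species[clade_map$focal]
  gene_group <- groups |>
    filter(.data$species == focal_sp) |>
    select("gene_id", "group_id") |>
    left_join(group_label, by = "group_id")
  annotation$genes |>
    select("gene_id", "chrom", "start") |>
    left_join(select(gene_group, "gene_id", "group_id", "label"),
              by = "gene_id") |>
    mutate(label = ifelse(is.na(.data$label),
                          if (singletons_focal) "focal_specific"
                          else "unassigned",
                          .data$label)) |>
    arrange(.data$chrom, .data$start, .data$gene_id)
}

#' Cumulative clade-specificity counts along each chromosome
#'
#' Running per-label gene counts in (chromosome, start) order — the
#' coordinates behind cumulative specificity plots.
#'
#' @param assignment Output of [classify_clades()].
#' @param annotation A [genome_annotation()]; restricts to placed
#'   chromosomes and supplies gene order.
#' @return Tibble with one row per gene: `chrom`, `gene_rank`, `gene_id`,
#'   `start`, `label`, and cumulative columns `cum_focal_specific`,
#'   `cum_genus_specific`, `cum_conserved`, `cum_unassigned`.
#' @export
cumulative_specificity_profile <- function(assignment, annotation) {
  placed_ids <- annotation$chromosomes$chrom[annotation$chromosomes$placed]
  assignment |>
    filter(.data$chrom %in% placed_ids) |>
    arrange(.data$chrom, .data$start, .data$gene_id) |>
    group_by(.data$chrom) |>
    mutate(gene_rank = row_number(),
           cum_focal_specific = cumsum(.data$label == "focal_specific"),
           cum_genus_specific = cumsum(.data$label == "genus_specific"),
           cum_conserved = cumsum(.data$label == "conserved"),
           cum_unassigned = cumsum(.data$label == "unassigned")) |>
    ungroup() |>
    select("chrom", "gene_rank", "gene_id", "start", "label",
           dplyr::starts_with("cum_"))
}

#' Final clade-specificity totals per chromosome
#'
#' @inheritParams cumulative_specificity_profile
#' @return Tibble (`chrom`, `label`, `n`, `share_of_label`) where
#'   `share_of_label` is the chromosome's share of all genes carrying that
#'   label.
#' @export
specificity_totals <- function(assignment, annotation) {
  placed_ids <- annotation$chromosomes$chrom[annotation$chromosomes$placed]
  assignment |>
    filter(.data$chrom %in% placed_ids) |>
    dplyr::count(.data$chrom, .data$label) |>
    group_by(.data$label) |>
    mutate(share_of_label = .data$n / sum(.data$n)) |>
    ungroup()
}
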