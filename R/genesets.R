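#' Hypergeometric enrichment/depletion test
#'
#' Exact tail and two-sided probabilities for drawing `k` set members among a
#' chromosome's `n` genes when `K` of the `N` background genes belong to the
#' set. `p_enrich = P[X >= k]`, `p_deplete = P[X <= k]` under
#' Hypergeometric(N, K, n); `p_two_sided` follows Fisher's rule — the sum of
#' probabilities of all outcomes no more likely than the observed one —
#' capped at 1.
#'
#' @param k Observed overlap (set members on the chromosome).
#' @param K Set size.
#' @param n Chromosome gene count.
#' @param N Background gene count.
#' @return Tibble (`p_enrich`, `p_deplete`, `p_two_sided`).
#' @export
#' @examples
#' hypergeom_test(45, 117, 3241, 17624)
hypergeom_test <- function(k, K, n, N) {
  if (length(k) != 1) {
    return(purrr::pmap_dfr(list(k, K, n, N), hypergeom_test))
  }
  lo <- max(0L, n + K - N)
  hi <- min(K, n)
  if (k < lo || k > hi || K > N || n > N || min(k, K, n, N) < 0) {
    abort("inconsistent counts for hypergeometric test")
  }
  p_enrich <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_deplete <- phyper(k, K, N - K, n)
  support <- lo:hi
  pmf <- dhyper(support, K, N - K, n)
  observed <- dhyper(k, K, N - K, n)
  p_two <- min(1, sum(pmf[pmf <= observed * (1 + 1e-7)]))
  tibble(p_enrich = p_enrich, p_deplete = p_deplete, p_two_sided = p_two)
}

#' Per-chromosome gene-set enrichment/depletion
#'
#' Runs [hypergeom_test()] for every (set, placed chromosome) pair with a
#' genome-wide background of all or coding-only genes, and applies
#' Benjamini-Hochberg correction across the whole set-by-chromosome family.
#'
#' @param annotation A [genome_annotation()].
#' @param gene_sets Named list of character vectors of gene ids; every set
#'   must be a subset of the chosen background.
#' @param background `"all"` (default; all genes on placed chromosomes,
#'   matching a whole-annotation denominator) or `"coding"`.
#' @return Tibble with one row per set x chromosome: `set_id`, `chrom`,
#'   `k`, `K`, `n`, `N`, `expected`, `p_enrich`, `p_deplete`,
#'   `p_two_sided`, `q` (BH over the family), `direction`.
#' @export
enrich_sets <- function(annotation, gene_sets,
                        background = c("all", "coding")) {
  background <- match.arg(background)
  bg <- placed_genes(annotation)
  if (background == "coding") bg <- filter(bg, .data$biotype == "coding")
  if (nrow(bg) == 0) abort("empty background")
  outside <- setdiff(unlist(gene_sets, use.names = FALSE), bg$gene_id)
  if (length(outside)) {
    abort(paste0("gene set member outside background: ", outside[1]))
  }
  N <- nrow(bg)
  chrom_sizes <- dplyr::count(bg, .data$chrom, name = "n_chrom")
  res <- purrr::imap_dfr(gene_sets, function(set, sid) {
    set <- unique(set)
    on_chrom <- bg |>
      filter(.data$gene_id %in% set) |>
      dplyr::count(.data$chrom, name = "k")
    chrom_sizes |>
      left_join(on_chrom, by = "chrom") |>
      mutate(set_id = sid,
             k = as.integer(tidyr::replace_na(.data$k, 0L)),
             K = length(set), N = N)
  })
  tests <- hypergeom_test(res$k, res$K, res$n_chrom, res$N)
  res |>
    dplyr::bind_cols(tests) |>
    mutate(expected = .data$K * .data$n_chrom / .data$N,
           q = p.adjust(.data$p_two_sided, method = "BH"),
           direction = ifelse(.data$k > .data$expected, "enrich",
                              "deplete")) |>
    select("set_id", "chrom", "k", "K", n = "n_chrom", "N", "expected",
           "p_enrich", "p_deplete", "p_two_sided", "q", "direction")
}

#' Flag non-expressed (candidate pseudogene) genes
#'
#' A gene is flagged silent when its mean TPM across all samples is at or
#' below the threshold (default 1). Genes in the annotation but absent from
#' the expression table get the distinct status `"no_data"`.
#'
#' @param expression Expression tibble from [read_expression()].
#' @param threshold Mean-TPM cutoff (default 1; the flag uses `<=`).
#' @param annotation Optional [genome_annotation()] used to report genes
#'   missing from the table.
#' @return Tibble (`gene_id`, `mean_tpm`, `status`) with `status` in
#'   `silent` / `expressed` / `no_data`.
#' @export
flag_nonexpressed <- function(expression, threshold = 1,
                              annotation = NULL) {
  num <- expression[setdiff(names(expression), "gene_id")]
  out <- tibble(
    gene_id = expression$gene_id,
    mean_tpm = rowMeans(as.matrix(num)),
    status = ifelse(rowMeans(as.matrix(num)) <= threshold,
                    "silent", "expressed")
  )
  if (!is.null(annotation)) {
    missing <- setdiff(annotation$genes$gene_id, out$gene_id)
    if (length(missing)) {
      out <- bind_rows(out, tibble(gene_id = missing, mean_tpm = NA_real_,
                                   status = "no_data"))
    }
  }
  out
}

#' Detect tandem gene arrays from family labels
#'
#' A tandem array is a maximal run of two or more same-family genes along
#' the gene order of a chromosome, allowing at most `max_intervening` other
#' genes between consecutive members. With `require_same_strand`, a strand
#' change breaks the run; otherwise strand homogeneity is only reported.
#'
#' @param annotation A [genome_annotation()] whose genes carry `family`
#'   labels (genes with `NA` family are ignored as members but count as
#'   intervening genes).
#' @param max_intervening Maximum number of non-member genes between
#'   consecutive array members (default 1).
#' @param require_same_strand Break arrays at strand changes (default
#'   FALSE).
#' @return Tibble with one row per array: `array_id`, `chrom`, `family`,
#'   `genes` (list-column, in coordinate order), `n_genes`, `start`, `end`,
#'   `strand_homogeneous`.
#' @export
detect_tandem_arrays <- function(annotation, max_intervening = 1,
                                 require_same_strand = FALSE) {
  genes <- placed_genes(annotation) |>
    arrange(.data$chrom, .data$start, .data$gene_id) |>
    group_by(.data$chrom) |>
    mutate(idx = row_number()) |>
    ungroup()
  members <- filter(genes, !is.na(.data$family))
  arrays <- members |>
    group_by(.data$chrom, .data$family) |>
    arrange(.data$idx, .by_group = TRUE) |>
    mutate(gap = .data$idx - dplyr::lag(.data$idx, default = -1e9) - 1L,
           new_run = .data$gap > max_intervening |
             (require_same_strand &
                .data$strand != dplyr::lag(.data$strand,
                                           default = dplyr::first(.data$strand))),
           run = cumsum(.data$new_run)) |>
    group_by(.data$chrom, .data$family, .data$run) |>
    summarise(genes = list(.data$gene_id),
              n_genes = n(),
              start = min(.data$start), end = max(.data$end),
              strand_homogeneous = dplyr::n_distinct(.data$strand) == 1,
              .groups = "drop") |>
    filter(.data$n_genes >= 2) |>
    arrange(.data$chrom, .data$start) |>
    mutate(array_id = paste0("array_", row_number())) |>
    select("array_id", "chrom", "family", "genes", "n_genes", "start",
           "end", "strand_homogeneous")
  arrays
}

summary_from_counts <- function(counts) {
  counts |>
    mutate(
      genes_per_mb = round(.data$total / (.data$length / 1e6), 1),
      expressed_per_mb = round(.data$expressed / (.data$length / 1e6), 1),
      pct_length = round(100 * .data$length / sum(.data$length)),
      pct_genes = round(100 * .data$total / sum(.data$total)),
      pct_coding = round(100 * .data$coding / .data$total),
      pct_noncoding = round(100 * .data$noncoding / .data$total),
      pct_expressed = round(100 * .data$expressed / .data$total),
      pct_nonexpressed = round(100 * .data$nonexpressed / .data$total)
    )
}

#' Chromosome summary table
#'
#' Per placed chromosome: length, gene totals, coding/non-coding split,
#' expressed (mean TPM > threshold) and non-expressed counts, gene and
#' expressed-gene densities per Mb (1 decimal), and percentages of the
#' placed-chromosome totals (nearest integer). Genes absent from the
#' expression table count as non-expressed.
#'
#' @param annotation A [genome_annotation()].
#' @param expression Expression tibble from [read_expression()].
#' @param tpm_threshold Mean-TPM expression cutoff (default 1; expressed
#'   means strictly greater).
#' @return Tibble, one row per placed chromosome, with raw counts and the
#'   derived densities/percentages.
#' @export
summarize_chromosomes <- function(annotation, expression,
                                  tpm_threshold = 1) {
  genes <- placed_genes(annotation)
  flags <- flag_nonexpressed(expression, threshold = tpm_threshold,
                             annotation = annotation)
  genes <- left_join(genes, select(flags, "gene_id", "status"),
                     by = "gene_id")
  chr <- placed_chromosomes(annotation)
  genes |>
    group_by(.data$chrom) |>
    summarise(
      total = n(),
      coding = sum(.data$biotype == "coding"),
      noncoding = sum(.data$biotype == "noncoding"),
      expressed = sum(.data$status == "expressed", na.rm = TRUE),
      nonexpressed = sum(.data$status != "expressed" |
                           is.na(.data$status)),
      .groups = "drop"
    ) |>
    dplyr::right_join(select(chr, "chrom", "length"), by = "chrom") |>
    mutate(across(c("total", "coding", "noncoding", "expressed",
                    "nonexpressed"),
                  ~ as.integer(tidyr::replace_na(.x, 0L)))) |>
    select("chrom", "length", everything()) |>
    summary_from_counts()
}

#' Chromosome summary from pre-tabulated counts
#'
#' Same derived quantities as [summarize_chromosomes()] but starting from a
#' counts table rather than an annotation — useful for recomputing a
#' published per-chromosome table's densities and percentages from its raw
#' counts.
#'
#' @param counts Tibble with columns `chrom`, `length`, `total`, `coding`,
#'   `noncoding`, `expressed`, `nonexpressed`.
#' @return The input plus the derived density/percentage columns.
#' @export
summarize_chromosome_counts <- function(counts) {
  need <- c("chrom", "length", "total", "coding", "noncoding", "expressed",
            "nonexpressed")
  if (!all(need %in% names(counts))) {
    abort(paste("counts needs columns", paste(need, collapse = ", ")))
  }
  summary_from_counts(as_tibble(counts))
}
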