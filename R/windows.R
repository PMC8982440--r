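#' Tile placed chromosomes into consecutive windows
#'
#' Windows are non-overlapping, tile each placed chromosome completely, and
#' the final window of a chromosome keeps its true (shorter) span. Reported
#' coordinates are 1-based inclusive.
#'
#' @param annotation A [genome_annotation()].
#' @param window_size Window size in bases (> 0).
#' @return Tibble (`chrom`, `start`, `end`).
#' @export
#' @examples
#' ann <- genome_annotation(
#'   tibble::tibble(chrom = "c1", length = 250000L),
#'   tibble::tibble(gene_id = character(), chrom = character(),
#'                  start = integer(), end = integer(),
#'                  strand = character(), biotype = character())
#' )
#' partition_windows(ann, 1e5)
partition_windows <- function(annotation, window_size) {
  if (window_size <= 0) abort("window_size must be positive")
  window_size <- as.integer(window_size)
  chr <- placed_chromosomes(annotation)
  purrr::map_dfr(seq_len(nrow(chr)), function(i) {
    len <- chr$length[i]
    start0 <- seq.int(0L, len - 1L, by = window_size)
    tibble(chrom = chr$chrom[i],
           start = start0 + 1L,
           end = pmin(start0 + window_size, len))
  })
}

#' Windowed GC ratio
#'
#' GC per window is (G+C)/(A+C+G+T); non-ACGT bases (Ns) are excluded from
#' numerator and denominator, and windows with more than half non-ACGT bases
#' are masked (`NA`).
#'
#' @inheritParams partition_windows
#' @param max_n_fraction Mask windows whose non-ACGT fraction exceeds this
#'   (default 0.5).
#' @return Window-track tibble (`chrom`, `start`, `end`, `value`,
#'   `n_informative`) where `n_informative` is the count of ACGT bases.
#' @export
gc_track <- function(annotation, window_size = 1e5, max_n_fraction = 0.5) {
  chr <- placed_chromosomes(annotation)
  if (anyNA(chr$sequence)) abort("gc_track needs sequences attached")
  wins <- partition_windows(annotation, window_size)
  purrr::map_dfr(seq_len(nrow(chr)), function(i) {
    w <- filter(wins, .data$chrom == chr$chrom[i])
    s <- Biostrings::DNAString(chr$sequence[i])
    views <- Biostrings::Views(s, start = w$start, end = w$end)
    freq <- Biostrings::letterFrequency(views, c("A", "C", "G", "T"))
    acgt <- rowSums(freq)
    gc <- freq[, "C"] + freq[, "G"]
    span <- w$end - w$start + 1L
    value <- ifelse(span - acgt > max_n_fraction * span | acgt == 0,
                    NA_real_, gc / acgt)
    mutate(w, value = value, n_informative = as.integer(acgt))
  })
}

#' Coding-sequence GC per gene
#'
#' GC ratio of each coding gene's sequence span (the exonic CDS union is not
#' modelled; the full gene span is used). Genes on chromosomes without
#' sequence get `NA`.
#'
#' @inheritParams partition_windows
#' @return Tibble (`gene_id`, `chrom`, `gc`) for coding genes on placed
#'   chromosomes.
#' @export
coding_gc_per_gene <- function(annotation) {
  chr <- placed_chromosomes(annotation)
  genes <- filter(placed_genes(annotation), .data$biotype == "coding")
  purrr::map_dfr(seq_len(nrow(chr)), function(i) {
    g <- filter(genes, .data$chrom == chr$chrom[i])
    if (nrow(g) == 0) return(tibble())
    if (is.na(chr$sequence[i])) {
      return(mutate(g[c("gene_id", "chrom")], gc = NA_real_))
    }
    s <- Biostrings::DNAString(chr$sequence[i])
    views <- Biostrings::Views(s, start = g$start, end = g$end)
    freq <- Biostrings::letterFrequency(views, c("A", "C", "G", "T"))
    acgt <- rowSums(freq)
    tibble(gene_id = g$gene_id, chrom = g$chrom,
           gc = ifelse(acgt == 0, NA_real_,
                       (freq[, "C"] + freq[, "G"]) / acgt))
  })
}

#' Per-chromosome mean coding GC
#'
#' @inheritParams partition_windows
#' @return Tibble (`chrom`, `mean_gc`, `n_genes`).
#' @export
coding_gc_by_chromosome <- function(annotation) {
  coding_gc_per_gene(annotation) |>
    group_by(.data$chrom) |>
    summarise(mean_gc = mean(.data$gc, na.rm = TRUE),
              n_genes = sum(!is.na(.data$gc)), .groups = "drop")
}

#' Windowed gene density
#'
#' Counts genes whose start coordinate falls in each window, so every gene is
#' counted exactly once.
#'
#' @inheritParams partition_windows
#' @param biotype Optional filter, `"coding"` or `"noncoding"`.
#' @return Window-track tibble with integer `value` counts.
#' @export
gene_density_track <- function(annotation, window_size = 5e4,
                               biotype = NULL) {
  wins <- partition_windows(annotation, window_size)
  genes <- placed_genes(annotation)
  if (!is.null(biotype)) genes <- filter(genes, .data$biotype == !!biotype)
  counts <- genes |>
    mutate(win_start = ((.data$start - 1L) %/% as.integer(window_size)) *
             as.integer(window_size) + 1L) |>
    dplyr::count(.data$chrom, .data$win_start)
  wins |>
    left_join(counts, by = c("chrom", "start" = "win_start")) |>
    mutate(value = as.integer(tidyr::replace_na(.data$n, 0L)),
           n_informative = .data$value) |>
    select(-"n")
}
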