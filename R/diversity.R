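#' Per-site pairwise diversity from pooled read counts
#'
#' The unbiased per-site heterozygosity estimate from pooled sequencing
#' reads: with read counts `r` (reference) and `a` (alternate), depth
#' `n = r + a`, and read frequencies `p = r/n`, `q = a/n`,
#' `pi = n/(n-1) * (1 - p^2 - q^2)`. This equals the average pairwise
#' difference over all read pairs drawn without replacement.
#'
#' @param ref_count,alt_count Integer vectors of per-allele read counts.
#' @param min_depth Sites with `n < min_depth` return `NA` (default 10).
#' @return Numeric vector of per-site pi values in `[0, n/(n-1) * 0.5]`.
#' @export
#' @examples
#' pi_site(5, 5)   # 10/9 * 0.5 = 0.5556
#' pi_site(10, 0)  # 0
pi_site <- function(ref_count, alt_count, min_depth = 10) {
  n <- ref_count + alt_count
  p <- ref_count / n
  q <- alt_count / n
  ifelse(n < min_depth, NA_real_, n / (n - 1) * (1 - p^2 - q^2))
}

#' Windowed nucleotide diversity (pi) from pooled allele counts
#'
#' Window pi is the sum of [pi_site()] over qualifying polymorphic sites
#' divided by the number of window positions with qualifying depth. Positions
#' absent from the allele-count table are treated as covered and monomorphic
#' (variant files rarely list invariant sites); listed sites below
#' `min_depth` are removed from the denominator. Windows where qualifying
#' positions fall below `min_fraction` of the span are masked.
#'
#' @param sites Allele-count tibble from [read_allele_counts()].
#' @param annotation A [genome_annotation()].
#' @param window_size Window size in bases (default 50 kb).
#' @param min_depth Minimum read depth for a site to qualify (default 10).
#' @param min_minor_count Minimum minor-allele read count for a site to be
#'   treated as polymorphic (default 2).
#' @param min_fraction Mask windows with fewer qualifying positions than this
#'   fraction of the span (default 0.5).
#' @return Window-track tibble; `n_informative` is the number of polymorphic
#'   sites that contributed.
#' @export
pi_track <- function(sites, annotation, window_size = 5e4, min_depth = 10,
                     min_minor_count = 2, min_fraction = 0.5) {
  wins <- partition_windows(annotation, window_size)
  ws <- as.integer(window_size)
  ann_sites <- sites |>
    filter(.data$chrom %in% wins$chrom) |>
    mutate(
      win_start = ((.data$pos - 1L) %/% ws) * ws + 1L,
      minor = pmin(.data$ref_count, .data$alt_count),
      qual = .data$depth >= min_depth,
      poly = .data$qual & .data$minor >= min_minor_count,
      pi = ifelse(.data$poly,
                  pi_site(.data$ref_count, .data$alt_count, min_depth), 0)
    )
  agg <- ann_sites |>
    group_by(.data$chrom, .data$win_start) |>
    summarise(pi_sum = sum(.data$pi),
              n_poly = sum(.data$poly),
              n_lowdepth = sum(!.data$qual), .groups = "drop")
  wins |>
    left_join(agg, by = c("chrom", "start" = "win_start")) |>
    mutate(
      pi_sum = tidyr::replace_na(.data$pi_sum, 0),
      n_poly = as.integer(tidyr::replace_na(.data$n_poly, 0L)),
      n_lowdepth = tidyr::replace_na(.data$n_lowdepth, 0L),
      span = .data$end - .data$start + 1L,
      denom = .data$span - .data$n_lowdepth,
      value = ifelse(.data$denom < min_fraction * .data$span,
                     NA_real_, .data$pi_sum / .data$denom),
      n_informative = .data$n_poly
    ) |>
    select("chrom", "start", "end", "value", "n_informative")
}

is_transition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

#' Transition/transversion ratio of biallelic SNVs
#'
#' Transitions are A<->G and C<->T; everything else among ACGT pairs is a
#' transversion. Classification is per site (no frequency weighting). The
#' ratio is `NA` where the transversion count is zero.
#'
#' @param sites Allele-count tibble from [read_allele_counts()].
#' @param annotation Required for `scope = "window"`, to tile chromosomes.
#' @param scope `"chromosome"` (default), `"genome"`, or `"window"`.
#' @param window_size Window size for `scope = "window"`.
#' @return For `"genome"`, a single number (or `NA`); otherwise a tibble
#'   with `ts`, `tv` counts and `tstv`.
#' @export
tstv <- function(sites, annotation = NULL,
                 scope = c("chromosome", "genome", "window"),
                 window_size = 5e4) {
  scope <- match.arg(scope)
  x <- mutate(sites, is_ts = is_transition(.data$ref, .data$alt))
  if (scope == "genome") {
    tv <- sum(!x$is_ts)
    return(if (tv == 0) NA_real_ else sum(x$is_ts) / tv)
  }
  if (scope == "chromosome") {
    return(x |>
             group_by(.data$chrom) |>
             summarise(ts = sum(.data$is_ts), tv = sum(!.data$is_ts),
                       .groups = "drop") |>
             mutate(tstv = ifelse(.data$tv == 0, NA_real_,
                                  .data$ts / .data$tv)))
  }
  if (is.null(annotation)) abort("scope = \"window\" needs an annotation")
  ws <- as.integer(window_size)
  agg <- x |>
    mutate(win_start = ((.data$pos - 1L) %/% ws) * ws + 1L) |>
    group_by(.data$chrom, .data$win_start) |>
    summarise(ts = sum(.data$is_ts), tv = sum(!.data$is_ts),
              .groups = "drop")
  partition_windows(annotation, window_size) |>
    left_join(agg, by = c("chrom", "start" = "win_start")) |>
    mutate(ts = tidyr::replace_na(.data$ts, 0L),
           tv = tidyr::replace_na(.data$tv, 0L),
           value = ifelse(.data$tv == 0, NA_real_, .data$ts / .data$tv),
           n_informative = .data$ts + .data$tv) |>
    select("chrom", "start", "end", "value", "n_informative")
}
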