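#' Genome annotation container
#'
#' Bundles chromosome records (id, length, optional sequence, placed flag)
#' with gene records into the validated backbone that all per-chromosome
#' statistics are computed against. Coordinates are 1-based inclusive, the
#' GFF3 convention.
#'
#' @param chromosomes Tibble with columns `chrom` (character, unique),
#'   `length` (positive integer bases), optionally `sequence` (nucleotide
#'   string of exactly `length` characters, or `NA`) and `placed` (logical;
#'   unplaced scaffolds are kept but excluded from per-chromosome statistics).
#' @param genes Tibble with columns `gene_id` (unique), `chrom`, `start`,
#'   `end` (1-based inclusive), `strand` (`"+"`/`"-"`), `biotype`
#'   (`"coding"`/`"noncoding"`), and optionally `family` and `protein`
#'   (character, `NA` where absent; `protein` only for coding genes).
#'
#' @return An object of class `genome_annotation`: a list with tibbles
#'   `$chromosomes` and `$genes`.
#' @export
#' @examples
#' ann <- genome_annotation(
#'   tibble::tibble(chrom = "chr1", length = 1000L),
#'   tibble::tibble(gene_id = "g1", chrom = "chr1", start = 11L, end = 310L,
#'                  strand = "+", biotype = "coding")
#' )
#' ann
genome_annotation <- function(chromosomes, genes) {
  chromosomes <- as_tibble(chromosomes)
  genes <- as_tibble(genes)
  if (!all(c("chrom", "length") %in% names(chromosomes))) {
    abort("`chromosomes` needs columns chrom, length")
  }
  if (!"sequence" %in% names(chromosomes)) chromosomes$sequence <- NA_character_
  if (!"placed" %in% names(chromosomes)) chromosomes$placed <- TRUE
  chromosomes$length <- as.integer(chromosomes$length)

  need <- c("gene_id", "chrom", "start", "end", "strand", "biotype")
  if (!all(need %in% names(genes))) {
    abort(paste("`genes` needs columns", paste(need, collapse = ", ")))
  }
  if (!"family" %in% names(genes)) genes$family <- NA_character_
  if (!"protein" %in% names(genes)) genes$protein <- NA_character_
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)

  ann <- structure(
    list(chromosomes = chromosomes,
         genes = arrange(genes, .data$chrom, .data$start, .data$gene_id)),
    class = "genome_annotation"
  )
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  chr <- ann$chromosomes
  g <- ann$genes
  if (anyDuplicated(chr$chrom)) abort("duplicate chromosome ids")
  if (any(chr$length <= 0L)) abort("chromosome lengths must be positive")
  has_seq <- !is.na(chr$sequence)
  if (any(has_seq & nchar(chr$sequence) != chr$length)) {
    bad <- chr$chrom[has_seq & nchar(chr$sequence) != chr$length][1]
    abort(paste0("sequence length disagrees with declared length for ", bad))
  }
  if (anyDuplicated(g$gene_id)) {
    abort(paste0("duplicate gene id: ", g$gene_id[duplicated(g$gene_id)][1]))
  }
  missing_chrom <- setdiff(g$chrom, chr$chrom)
  if (length(missing_chrom)) {
    abort(paste0("gene chromosome not in annotation: ", missing_chrom[1]))
  }
  if (!all(g$strand %in% c("+", "-"))) abort("gene strand must be + or -")
  if (!all(g$biotype %in% c("coding", "noncoding"))) {
    abort("gene biotype must be coding or noncoding")
  }
  len <- setNames(chr$length, chr$chrom)
  bad <- g$start < 1L | g$start > g$end | g$end > len[g$chrom]
  if (any(bad)) {
    abort(paste0("gene coordinates outside chromosome: ",
                 paste(g$gene_id[bad], collapse = ", ")))
  }
  if (any(!is.na(g$protein) & g$biotype != "coding")) {
    abort("protein attached to a non-coding gene")
  }
  invisible(ann)
}

#' @export
print.genome_annotation <- function(x, ...) {
  n_placed <- sum(x$chromosomes$placed)
  cat("<genome_annotation> ", nrow(x$chromosomes), " sequences (",
      n_placed, " placed), ", nrow(x$genes), " genes, ",
      sum(!is.na(x$chromosomes$sequence)), " sequences attached\n", sep = "")
  invisible(x)
}

#' @export
format.genome_annotation <- function(x, ...) {
  paste0("<genome_annotation: ", nrow(x$genes), " genes on ",
         nrow(x$chromosomes), " sequences>")
}

# genes on placed chromosomes only, in (chrom, start) order
placed_genes <- function(annotation) {
  keep <- annotation$chromosomes$chrom[annotation$chromosomes$placed]
  filter(annotation$genes, .data$chrom %in% keep)
}

placed_chromosomes <- function(annotation) {
  filter(annotation$chromosomes, .data$placed)
}
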