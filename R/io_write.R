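#' Writers for the pipeline's standard formats
#'
#' Counterparts of the readers in this package; used by the synthetic
#' generator and for exporting results. All emit plain text.
#'
#' @param annotation A [genome_annotation()] with sequences attached (for
#'   FASTA) or gene records (for GFF3).
#' @param path Output file path.
#' @name writers
NULL

#' @rdname writers
#' @export
write_genome_fasta <- function(annotation, path) {
  chr <- annotation$chromosomes
  if (anyNA(chr$sequence)) abort("cannot write FASTA: sequences not attached")
  seqs <- Biostrings::DNAStringSet(setNames(chr$sequence, chr$chrom))
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' @rdname writers
#' @export
write_genes_gff3 <- function(annotation, path) {
  g <- annotation$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(g$start, g$end),
    strand = g$strand
  )
  S4Vectors::mcols(gr)$source <- "chromsandbox"
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- g$gene_id
  S4Vectors::mcols(gr)$biotype <- g$biotype
  if (any(!is.na(g$family))) S4Vectors::mcols(gr)$family <- g$family
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname writers
#' @param proteins Named character vector of amino-acid strings.
#' @export
write_protein_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins)
  Biostrings::writeXStringSet(aa, path, width = 80L)
  invisible(path)
}

#' @rdname writers
#' @param x Tibble to serialise (dialect per the matching reader).
#' @export
write_matrix_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname writers
#' @param hits Hit tibble (`query`, `target`, `evalue`, `bitscore`).
#' @export
write_hits <- function(hits, path) {
  full <- tibble(
    qseqid = hits$query, sseqid = hits$target,
    pident = 90, length = 100L, mismatch = 10L, gapopen = 0L,
    qstart = 1L, qend = 100L, sstart = 1L, send = 100L,
    evalue = hits$evalue, bitscore = hits$bitscore
  )
  readr::write_tsv(full, path, col_names = FALSE)
  invisible(path)
}

#' @rdname writers
#' @param groups Long orthogroup tibble (`group_id`, `species`, `gene_id`).
#' @param species Column order for the emitted species columns; default
#'   alphabetical.
#' @export
write_orthogroups <- function(groups, path, species = NULL) {
  species <- species %||% sort(unique(groups$species))
  wide <- groups |>
    group_by(.data$group_id, .data$species) |>
    summarise(gene_id = paste(.data$gene_id, collapse = ","),
              .groups = "drop") |>
    tidyr::pivot_wider(names_from = "species", values_from = "gene_id",
                       values_fill = "")
  for (sp in setdiff(species, names(wide))) wide[[sp]] <- ""
  readr::write_tsv(wide[c("group_id", species)], path)
  invisible(path)
}

#' @rdname writers
#' @param map Clade-map tibble as returned by [read_clade_map()].
#' @export
write_clade_map <- function(map, path) {
  out <- tibble(
    species = map$species,
    focal = as.integer(map$focal),
    clades = vapply(map$clades, paste, "", collapse = ",")
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname writers
#' @param sites Allele-count tibble (`chrom`, `pos`, `ref`, `alt`,
#'   `ref_count`, `alt_count`).
#' @export
write_allele_counts_tsv <- function(sites, path) {
  readr::write_tsv(
    sites[c("chrom", "pos", "ref", "alt", "ref_count", "alt_count")], path)
  invisible(path)
}

#' @rdname writers
#' @param contigs Named integer vector of chromosome lengths for the VCF
#'   header.
#' @param sample_id Sample column name in the emitted VCF.
#' @export
write_allele_counts_vcf <- function(sites, path, contigs,
                                    sample_id = "pool") {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=chromsandbox",
    paste0("##contig=<ID=", names(contigs), ",length=", contigs, ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t")
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:AD:DP\t0/1:%d,%d:%d",
                  sites$chrom, sites$pos, sites$ref, sites$alt,
                  sites$ref_count, sites$alt_count,
                  sites$ref_count + sites$alt_count)
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname writers
#' @param track A window track tibble (`chrom`, `start`, `end`, `value`,
#'   `n_informative`). Written as BED-like 4-column TSV (0-based start) with
#'   a JSON sidecar recording parameters.
#' @param params Named list of masking/threshold parameters for the sidecar.
#' @export
write_window_track <- function(track, path, params = list()) {
  bed <- tibble(
    chrom = track$chrom,
    start0 = track$start - 1L,
    end = track$end,
    value = ifelse(is.na(track$value), ".", format(track$value, digits = 10))
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  jsonlite::write_json(params, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
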