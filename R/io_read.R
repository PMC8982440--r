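#' Read a genome (FASTA + GFF3) into an annotation
#'
#' Parses a nucleotide FASTA and a GFF3 gene annotation into a validated
#' [genome_annotation()]. Genes are GFF3 `gene` features; mRNA/transcript
#' children are only consulted to decide the biotype (a gene with any
#' `mRNA`/`CDS` child, or with a `biotype`-like attribute, is `coding`).
#' Optionally attaches one protein per gene from a protein FASTA keyed by
#' gene id.
#'
#' @param gff3_path Path to a GFF3 file with gene-level features carrying an
#'   `ID` attribute; optional attributes `biotype` (or `gene_biotype`) and
#'   `family` are picked up.
#' @param fasta_path Optional path to the genome FASTA; when given, sequences
#'   are attached and coordinates are checked against true sequence lengths.
#' @param protein_fasta Optional path to a protein FASTA whose record ids are
#'   gene ids; matched proteins are attached to coding genes.
#' @param placed Optional character vector of chromosome ids regarded as
#'   placed chromosomes; all other seqids are kept but flagged unplaced.
#'   Default: every seqid is placed.
#'
#' @return A [genome_annotation()].
#' @export
read_genome <- function(gff3_path, fasta_path = NULL, protein_fasta = NULL,
                        placed = NULL) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  md <- as.data.frame(S4Vectors::mcols(gr))
  seqid <- as.character(GenomicRanges::seqnames(gr))

  is_gene <- md$type == "gene"
  if (!any(is_gene)) abort("GFF3 contains no gene features")

  ids <- md$ID[is_gene]
  if (anyNA(ids)) abort("gene feature without an ID attribute")

  # biotype: explicit attribute wins, otherwise coding iff a mRNA/CDS child
  # names this gene in Parent
  biotype <- rep(NA_character_, sum(is_gene))
  for (cand in c("biotype", "gene_biotype")) {
    if (cand %in% names(md)) {
      v <- as.character(md[[cand]][is_gene])
      biotype[is.na(biotype) & !is.na(v)] <- v[is.na(biotype) & !is.na(v)]
    }
  }
  child <- md$type %in% c("mRNA", "CDS", "transcript")
  coding_parents <- character(0)
  if (any(child) && "Parent" %in% names(md)) {
    coding_parents <- unique(unlist(md$Parent[child]))
  }
  biotype[is.na(biotype)] <-
    ifelse(ids[is.na(biotype)] %in% coding_parents, "coding", "noncoding")
  biotype[biotype %in% c("protein_coding", "mRNA")] <- "coding"
  biotype[!biotype %in% c("coding", "noncoding")] <- "noncoding"

  family <- if ("family" %in% names(md)) {
    as.character(md$family[is_gene])
  } else NA_character_

  genes <- tibble(
    gene_id = as.character(ids),
    chrom = seqid[is_gene],
    start = GenomicRanges::start(gr)[is_gene],
    end = GenomicRanges::end(gr)[is_gene],
    strand = as.character(GenomicRanges::strand(gr))[is_gene],
    biotype = biotype,
    family = family
  )
  if (any(genes$strand == "*")) {
    abort(paste0("gene without strand: ",
                 genes$gene_id[genes$strand == "*"][1]))
  }

  if (!is.null(fasta_path)) {
    seqs <- Biostrings::readDNAStringSet(fasta_path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    missing <- setdiff(unique(seqid), names(seqs))
    if (length(missing)) {
      abort(paste0("GFF3 seqid absent from FASTA: ", missing[1]))
    }
    chromosomes <- tibble(
      chrom = names(seqs),
      length = Biostrings::width(seqs),
      sequence = as.character(seqs)
    )
  } else {
    chromosomes <- tibble(
      chrom = unique(seqid),
      length = vapply(split(genes$end, genes$chrom), max, 1L)[unique(seqid)],
      sequence = NA_character_
    )
  }
  chromosomes$placed <- if (is.null(placed)) TRUE else
    chromosomes$chrom %in% placed

  if (!is.null(protein_fasta)) {
    prot <- Biostrings::readAAStringSet(protein_fasta)
    names(prot) <- sub("\\s.*$", "", names(prot))
    hit <- match(genes$gene_id, names(prot))
    genes$protein <- ifelse(is.na(hit), NA_character_,
                            as.character(prot)[hit])
    genes$protein[genes$biotype != "coding"] <- NA_character_
  }

  genome_annotation(chromosomes, genes)
}

#' Read a gene-by-sample TPM expression matrix
#'
#' @param tsv_path TSV with a `gene_id` column followed by one numeric column
#'   per sample (TPM, non-negative).
#' @param annotation Optional [genome_annotation()]; rows whose gene id does
#'   not resolve against it are dropped with a reported count (attribute
#'   `rejected_ids`).
#'
#' @return Tibble `gene_id` + sample columns; attribute `rejected_ids` holds
#'   any unresolvable ids.
#' @export
read_expression <- function(tsv_path, annotation = NULL) {
  x <- readr::read_tsv(tsv_path, show_col_types = FALSE)
  names(x)[1] <- "gene_id"
  num <- x[setdiff(names(x), "gene_id")]
  if (!all(vapply(num, is.numeric, TRUE))) {
    abort("non-numeric TPM column in expression table")
  }
  if (any(unlist(num) < 0, na.rm = TRUE)) abort("negative TPM value")
  rejected <- character(0)
  if (!is.null(annotation)) {
    rejected <- setdiff(x$gene_id, annotation$genes$gene_id)
    if (length(rejected)) {
      inform(paste0("read_expression: dropped ", length(rejected),
                    " unresolvable gene ids"))
      x <- filter(x, !.data$gene_id %in% rejected)
    }
  }
  attr(x, "rejected_ids") <- rejected
  x
}

#' Read differential-expression calls and their condition categories
#'
#' The call matrix is a TSV with a `gene_id` column and one column per
#' condition, each cell one of `up`, `down`, `ns`. Conditions map onto
#' free-text categories (for example `"osmotic"`, `"anhydrobiosis"`) through
#' `categories`; every condition must be mapped.
#'
#' @param tsv_path Path to the call matrix TSV.
#' @param categories Named character vector `condition -> category`, or a
#'   two-column data frame (`condition`, `category`).
#'
#' @return Long tibble with columns `gene_id`, `condition`, `call`,
#'   `category`.
#' @export
read_de_calls <- function(tsv_path, categories) {
  x <- readr::read_tsv(tsv_path, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  names(x)[1] <- "gene_id"
  long <- tidyr::pivot_longer(x, -"gene_id", names_to = "condition",
                              values_to = "call")
  if (!all(long$call %in% c("up", "down", "ns"))) {
    abort("DE calls must be one of up/down/ns")
  }
  if (is.data.frame(categories)) {
    categories <- setNames(as.character(categories[[2]]),
                           as.character(categories[[1]]))
  }
  unmapped <- setdiff(unique(long$condition), names(categories))
  if (length(unmapped)) {
    abort(paste0("condition without a category: ", unmapped[1]))
  }
  mutate(long, category = unname(categories[.data$condition]))
}

blast12_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

#' Read a 12-column tabular protein hit file
#'
#' Standard blast-like `outfmt 6` tables. Only query, subject, E-value and
#' bitscore are retained; records above the E-value ceiling are dropped.
#'
#' @param tsv_path Path to the tab-separated 12-column hit file (no header).
#' @param query_species,target_species Species ids for the two sides, kept as
#'   attributes and checked by downstream pairing operations.
#' @param evalue_ceiling Records with `evalue` above this are dropped
#'   (default `1e-5`).
#'
#' @return Tibble (`query`, `target`, `evalue`, `bitscore`) with attributes
#'   `query_species` and `target_species`.
#' @export
read_hits <- function(tsv_path, query_species, target_species,
                      evalue_ceiling = 1e-5) {
  x <- suppressWarnings(
    readr::read_tsv(tsv_path, col_names = blast12_cols,
                    col_types = "ccdddddddddd", show_col_types = FALSE))
  pr <- readr::problems(x)
  if (nrow(pr) > 0) {
    abort(paste0("malformed hit record at line ", pr$row[1],
                 ": ", pr$expected[1]))
  }
  if (anyNA(x$evalue) || anyNA(x$bitscore)) {
    abort(paste0("non-numeric evalue/bitscore at line ",
                 which(is.na(x$evalue) | is.na(x$bitscore))[1]))
  }
  out <- x |>
    filter(.data$evalue <= evalue_ceiling) |>
    select(query = "qseqid", target = "sseqid", "evalue", "bitscore")
  attr(out, "query_species") <- query_species
  attr(out, "target_species") <- target_species
  attr(out, "evalue_ceiling") <- evalue_ceiling
  out
}

#' Read an orthogroup membership table
#'
#' One row per orthogroup: a `group_id` column then one column per species
#' holding comma-separated gene ids (empty when the species is absent).
#'
#' @param tsv_path Path to the orthogroup TSV (header row names the species).
#' @return Long tibble (`group_id`, `species`, `gene_id`); errors if any gene
#'   appears in more than one group.
#' @export
read_orthogroups <- function(tsv_path) {
  x <- readr::read_tsv(tsv_path, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  names(x)[1] <- "group_id"
  long <- x |>
    tidyr::pivot_longer(-"group_id", names_to = "species",
                        values_to = "gene_id") |>
    filter(!is.na(.data$gene_id), .data$gene_id != "") |>
    tidyr::separate_rows("gene_id", sep = ",\\s*") |>
    filter(.data$gene_id != "")
  dup <- long |>
    distinct(.data$group_id, .data$gene_id) |>
    dplyr::count(.data$gene_id) |>
    filter(.data$n > 1)
  if (nrow(dup)) {
    abort(paste0("gene in more than one orthogroup: ", dup$gene_id[1]))
  }
  long
}

#' Read a species-to-clade map
#'
#' TSV with columns `species`, `focal` (0/1), `clades` — the ordered clade
#' path from the species itself outwards to the shared root, comma-separated
#' (e.g. `Pvan,Polypedilum,Chironomidae,Diptera`).
#'
#' @param tsv_path Path to the map.
#' @return Tibble (`species`, `focal`, `clades` list-column). Exactly one
#'   focal species is required and all paths must share their final (root)
#'   clade.
#' @export
read_clade_map <- function(tsv_path) {
  x <- readr::read_tsv(tsv_path, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  out <- tibble(
    species = x$species,
    focal = x$focal %in% c("1", "TRUE", "true"),
    clades = lapply(strsplit(x$clades, ",\\s*"), as.character)
  )
  validate_clade_map(out)
  out
}

validate_clade_map <- function(map) {
  if (sum(map$focal) != 1L) abort("clade map must flag exactly one focal species")
  roots <- vapply(map$clades, function(p) p[length(p)], "")
  if (length(unique(roots)) != 1L) abort("clade paths must share a common root")
  invisible(map)
}

#' Read biallelic SNV allele counts from VCF or TSV
#'
#' From a VCF, keeps biallelic SNV records with per-allele depths (`AD`) for
#' a single pooled sample; multiallelic and indel records are skipped with a
#' logged count, and records whose `DP` disagrees with the `AD` sum are
#' rejected. The TSV fallback dialect has columns
#' `chrom, pos, ref, alt, ref_count, alt_count`.
#'
#' @param path Path to a `.vcf` (detected by extension/content) or TSV file.
#' @return Tibble (`chrom`, `pos`, `ref`, `alt`, `ref_count`, `alt_count`,
#'   `depth`) sorted by (`chrom`, `pos`), with attribute `skipped` — a named
#'   integer vector of skip reasons.
#' @export
read_allele_counts <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^##fileformat=VCF", first) || grepl("\\.vcf$", path)) {
    read_allele_counts_vcf(path)
  } else {
    read_allele_counts_tsv(path)
  }
}

read_allele_counts_tsv <- function(path) {
  x <- readr::read_tsv(
    path, show_col_types = FALSE,
    col_types = readr::cols(chrom = "c", pos = "i", ref = "c", alt = "c",
                            ref_count = "i", alt_count = "i"))
  skipped <- c(multiallelic = 0L, indel = 0L, depth_mismatch = 0L)
  snv <- x$ref %in% c("A", "C", "G", "T") & x$alt %in% c("A", "C", "G", "T")
  skipped["indel"] <- sum(!snv)
  out <- x[snv, ] |>
    mutate(depth = .data$ref_count + .data$alt_count) |>
    arrange(.data$chrom, .data$pos)
  attr(out, "skipped") <- skipped
  out
}

read_allele_counts_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n0 <- nrow(fix)
  multi <- grepl(",", fix$ALT)
  snv <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  keep <- !multi & snv
  ad <- vcfR::extract.gt(v, element = "AD")[, 1]
  dp <- tryCatch(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)[, 1],
                 error = function(e) rep(NA_real_, n0))
  parts <- strsplit(ifelse(is.na(ad), "NA,NA", ad), ",")
  ref_count <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
  alt_count <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  mism <- keep & !is.na(dp) & !is.na(ref_count) &
    (ref_count + alt_count) != dp
  skipped <- c(multiallelic = sum(multi),
               indel = sum(!snv & !multi),
               depth_mismatch = sum(mism))
  keep <- keep & !mism & !is.na(ref_count) & !is.na(alt_count)
  out <- tibble(
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep],
    alt = fix$ALT[keep],
    ref_count = ref_count[keep],
    alt_count = alt_count[keep]
  ) |>
    mutate(depth = .data$ref_count + .data$alt_count) |>
    arrange(.data$chrom, .data$pos)
  attr(out, "skipped") <- skipped
  out
}
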