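#' Regulation signatures from differential-expression calls
#'
#' A gene's regulation signature is the set of condition categories in
#' which it has at least one `up` or `down` call; genes with no call in any
#' condition are silent. Signatures are canonicalised to a sorted
#' `"+"`-joined string (empty string = silent) so they compare directly.
#'
#' @param de_calls Long call tibble from [read_de_calls()] (columns
#'   `gene_id`, `condition`, `call`, and `category` unless supplied here).
#' @param category_map Optional named character vector `condition ->
#'   category` used when `de_calls` lacks a `category` column; every
#'   condition must be mapped.
#' @return Tibble (`gene_id`, `signature`, `categories` list-column,
#'   `silent`).
#' @export
regulation_signature <- function(de_calls, category_map = NULL) {
  if (!"category" %in% names(de_calls)) {
    if (is.null(category_map)) abort("no category column and no category_map")
    unmapped <- setdiff(unique(de_calls$condition), names(category_map))
    if (length(unmapped)) {
      abort(paste0("condition without a category: ", unmapped[1]))
    }
    de_calls <- mutate(de_calls,
                       category = unname(category_map[.data$condition]))
  }
  de_calls |>
    group_by(.data$gene_id) |>
    summarise(
      categories = list(sort(unique(
        .data$category[.data$call %in% c("up", "down")]))),
      .groups = "drop"
    ) |>
    mutate(signature = vapply(.data$categories, paste, "", collapse = "+"),
           silent = .data$signature == "") |>
    select("gene_id", "signature", "categories", "silent")
}

#' Group a tandem array into regulation blocks
#'
#' Scans the array's genes in coordinate order and groups consecutive genes
#' sharing a regulation signature into blocks. Up to `max_silent_gap`
#' consecutive silent genes are skipped without breaking a block; a longer
#' silent stretch terminates it. A gene whose signature differs from the
#' open block's starts a new block. Blocks partition the array's non-silent
#' genes.
#'
#' @param array_genes Character vector of gene ids in coordinate order
#'   (e.g. one `genes` entry of [detect_tandem_arrays()]).
#' @param signatures Signature tibble from [regulation_signature()]; genes
#'   absent from it are treated as silent.
#' @param max_silent_gap Maximum silent genes bridged inside a block
#'   (default 1).
#' @param array_id Label carried into the output (default `"array_1"`).
#' @return Tibble (`array_id`, `block`, `gene_id`, `signature`), one row
#'   per non-silent gene.
#' @export
group_blocks <- function(array_genes, signatures, max_silent_gap = 1,
                         array_id = "array_1") {
  sig <- setNames(signatures$signature, signatures$gene_id)
  s <- unname(sig[array_genes])
  s[is.na(s)] <- ""
  block <- integer(length(array_genes))
  current_sig <- NULL
  current_block <- 0L
  silent_run <- 0L
  for (i in seq_along(array_genes)) {
    if (s[i] == "") {
      silent_run <- silent_run + 1L
      if (silent_run > max_silent_gap) current_sig <- NULL
      next
    }
    if (is.null(current_sig) || s[i] != current_sig) {
      current_block <- current_block + 1L
      current_sig <- s[i]
    }
    block[i] <- current_block
    silent_run <- 0L
  }
  keep <- block > 0L
  tibble(array_id = array_id, block = block[keep],
         gene_id = array_genes[keep], signature = s[keep])
}

# per-position unit labels: 1 = nGAAn, 2 = nTTCn, 0 = neither
hse_unit_labels <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  lab <- integer(max(0L, n - 4L))
  if (n < 5L) return(lab)
  core <- substring(s, seq_len(n - 4L) + 1L, seq_len(n - 4L) + 3L)
  lab[core == "GAA"] <- 1L
  lab[core == "TTC"] <- 2L
  lab
}

#' Scan a sequence for heat-shock elements
#'
#' A heat-shock element (HSE) is a run of contiguous 5-mer units
#' alternating between `nGAAn` and `nTTCn` (`n` = any base). Every maximal
#' run of at least `min_units` units on the given strand is reported. With
#' `allow_mismatch`, one unit per run may deviate from its expected core by
#' a single base (run ends still require exact units).
#'
#' @param sequence Nucleotide string (scan the strand you pass; for the
#'   gene-level convenience wrapper see [scan_hse_upstream()]).
#' @param min_units Minimum alternating units (default 3).
#' @param allow_mismatch Tolerate one mismatched internal unit per run
#'   (default FALSE).
#' @return Tibble (`offset` 1-based, `length` bases, `units`).
#' @export
#' @examples
#' scan_hse("aGAAttTTCtaGAAt")  # one 3-unit element
scan_hse <- function(sequence, min_units = 3, allow_mismatch = FALSE) {
  lab <- hse_unit_labels(sequence)
  if (allow_mismatch) {
    return(scan_hse_mismatch(sequence, lab, min_units))
  }
  hits <- list()
  for (i in seq_along(lab)) {
    if (lab[i] == 0L) next
    # chain start: no alternating unit immediately before
    if (i > 5L && lab[i - 5L] != 0L && lab[i - 5L] != lab[i]) next
    u <- 1L
    j <- i
    while (j + 5L <= length(lab) && lab[j + 5L] != 0L &&
           lab[j + 5L] != lab[j]) {
      j <- j + 5L
      u <- u + 1L
    }
    if (u >= min_units) {
      hits[[length(hits) + 1L]] <-
        tibble(offset = i, length = 5L * u, units = u)
    }
  }
  if (!length(hits)) {
    return(tibble(offset = integer(), length = integer(),
                  units = integer()))
  }
  bind_rows(hits)
}

core_mismatch <- function(s, pos, expected_label) {
  core <- toupper(substring(s, pos + 1L, pos + 3L))
  target <- if (expected_label == 1L) "GAA" else "TTC"
  sum(strsplit(core, "")[[1]] != strsplit(target, "")[[1]])
}

scan_hse_mismatch <- function(sequence, lab, min_units) {
  n_pos <- length(lab)
  hits <- list()
  for (i in seq_len(n_pos)) {
    if (lab[i] == 0L) next
    if (i > 5L && lab[i - 5L] != 0L && lab[i - 5L] != lab[i]) next
    u <- 1L
    j <- i
    used_mm <- FALSE
    expected <- 3L - lab[i]  # alternate of current
    while (j + 5L <= n_pos) {
      nxt <- j + 5L
      if (lab[nxt] == expected) {
        # exact alternating unit
      } else if (!used_mm && nchar(sequence) >= nxt + 4L &&
                 core_mismatch(sequence, nxt, expected) == 1L &&
                 nxt + 5L <= n_pos && lab[nxt + 5L] == 3L - expected) {
        used_mm <- TRUE  # bridge one near-miss unit if the run continues
      } else break
      j <- nxt
      u <- u + 1L
      expected <- 3L - expected
    }
    if (u >= min_units) {
      hits[[length(hits) + 1L]] <-
        tibble(offset = i, length = 5L * u, units = u)
    }
  }
  if (!length(hits)) {
    return(tibble(offset = integer(), length = integer(),
                  units = integer()))
  }
  distinct(bind_rows(hits))
}

#' Scan gene upstream regions for heat-shock elements
#'
#' Extracts the strand-aware upstream window of each requested gene
#' (default 1,000 bases 5' of the gene start, clipped at chromosome ends,
#' reverse-complemented for minus-strand genes) and runs [scan_hse()].
#'
#' @param annotation A [genome_annotation()] with sequences attached.
#' @param gene_ids Genes to scan (default: all).
#' @param window Upstream window size in bases (default 1000).
#' @inheritParams scan_hse
#' @return Tibble (`gene_id`, `n_elements`, `max_units`, `has_hse`).
#' @export
scan_hse_upstream <- function(annotation, gene_ids = NULL, window = 1000,
                              min_units = 3, allow_mismatch = FALSE) {
  genes <- annotation$genes
  if (!is.null(gene_ids)) genes <- filter(genes, .data$gene_id %in% gene_ids)
  seqs <- setNames(annotation$chromosomes$sequence,
                   annotation$chromosomes$chrom)
  len <- setNames(annotation$chromosomes$length,
                  annotation$chromosomes$chrom)
  purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    chrom_seq <- seqs[[g$chrom]]
    if (is.na(chrom_seq)) abort("scan_hse_upstream needs sequences attached")
    if (g$strand == "+") {
      from <- max(1L, g$start - as.integer(window)); to <- g$start - 1L
    } else {
      from <- g$end + 1L; to <- min(len[[g$chrom]], g$end + as.integer(window))
    }
    up <- if (from > to) "" else substring(chrom_seq, from, to)
    if (g$strand == "-" && nchar(up)) {
      up <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(up)))
    }
    h <- scan_hse(up, min_units = min_units, allow_mismatch = allow_mismatch)
    tibble(gene_id = g$gene_id, n_elements = nrow(h),
           max_units = if (nrow(h)) max(h$units) else 0L,
           has_hse = nrow(h) > 0)
  })
}
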