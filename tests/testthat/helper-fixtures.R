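# small in-code fixtures shared across test files

toy_annotation <- function(with_seq = TRUE) {
  seq1 <- paste(rep("ATGC", 2500), collapse = "")   # 10 kb, GC 0.5
  seq2 <- paste(rep("AATGCGCA", 625), collapse = "") # 5 kb, GC 0.5
  genome_annotation(
    tibble::tibble(
      chrom = c("c1", "c2"),
      length = c(10000L, 5000L),
      sequence = if (with_seq) c(seq1, seq2) else NA_character_
    ),
    tibble::tibble(
      gene_id = c("g1", "g2", "g3"),
      chrom = c("c1", "c1", "c2"),
      start = c(101L, 2001L, 501L),
      end = c(700L, 2600L, 1100L),
      strand = c("+", "-", "+"),
      biotype = c("coding", "coding", "noncoding")
    )
  )
}

# a bundle at reduced scale, generated once per test run
small_sim_config <- function(seed = 101) {
  simulation_config(
    seed = seed,
    total_length = 8e5,
    family_copies = 12, family_sandbox = 6, family_silent = 10,
    island_blocks = 2, island_genes_per_block = 3,
    island_pi_targets = c(6.87, 4.74),
    island_signatures = c("anhydrobiosis+osmotic", "osmotic"),
    essential_size = 30
  )
}

small_bundle_cache <- new.env()

small_bundle <- function() {
  if (is.null(small_bundle_cache$bundle)) {
    dir <- file.path(tempdir(), "chromsandbox_small_bundle")
    small_bundle_cache$sim <- simulate_bundle(small_sim_config(), dir)
    small_bundle_cache$bundle <- read_bundle(dir)
    small_bundle_cache$dir <- dir
  }
  small_bundle_cache
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}
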