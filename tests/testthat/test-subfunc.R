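de_long <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(gene_id = r[[1]], condition = r[[2]], call = r[[3]],
                   category = r[[4]])
  }))
}

test_that("regulation signatures collect categories with any up/down call", {
  de <- de_long(
    list("g1", "NaCl_T1", "up", "osmotic"),
    list("g1", "Heat42_T1", "ns", "stress"),
    list("g2", "NaCl_T1", "ns", "osmotic"),
    list("g3", "NaCl_T1", "up", "osmotic"),
    list("g3", "PreCondTre_T0vsT12", "down", "anhydrobiosis")
  )
  sig <- regulation_signature(de)
  s <- setNames(sig$signature, sig$gene_id)
  expect_equal(s[["g1"]], "osmotic")
  expect_equal(s[["g2"]], "")
  expect_true(sig$silent[sig$gene_id == "g2"])
  expect_equal(s[["g3"]], "anhydrobiosis+osmotic")
})

test_that("unmapped condition is a hard error", {
  de <- tibble::tibble(gene_id = "g1", condition = "mystery", call = "up")
  expect_error(regulation_signature(de, c(NaCl_T1 = "osmotic")),
               "mystery")
})

sig_table <- function(sigs) {
  tibble::tibble(gene_id = sprintf("g%02d", seq_along(sigs)),
                 signature = sigs,
                 categories = lapply(sigs, identity),
                 silent = sigs == "")
}

test_that("block grouping splits on signature change and bridges silents", {
  b1 <- group_blocks(sprintf("g%02d", 1:4), sig_table(c("X", "X", "Y", "Y")))
  expect_equal(b1$block, c(1L, 1L, 2L, 2L))

  b2 <- group_blocks(sprintf("g%02d", 1:3), sig_table(c("X", "", "X")),
                     max_silent_gap = 1)
  expect_equal(b2$block, c(1L, 1L))
  expect_equal(b2$gene_id, c("g01", "g03"))

  b3 <- group_blocks(sprintf("g%02d", 1:4), sig_table(c("X", "", "", "X")),
                     max_silent_gap = 1)
  expect_equal(b3$block, c(1L, 2L))  # gap exceeded terminates the block
})

test_that("block grouping matches the segmentation oracle on random strings", {
  set.seed(13)
  for (rep in 1:200) {
    n <- sample(2:10, 1)
    sigs <- sample(c("X", "Y", "Z", ""), n, replace = TRUE)
    gap <- sample(0:2, 1)
    got <- group_blocks(sprintf("g%02d", seq_len(n)), sig_table(sigs),
                        max_silent_gap = gap)
    want <- oracle_blocks(sigs, gap)
    expect_equal(dplyr::n_distinct(got$block), length(want))
    got_split <- split(match(got$gene_id, sprintf("g%02d", seq_len(n))),
                       got$block)
    expect_equal(unname(lapply(got_split, as.numeric)),
                 lapply(want, as.numeric), info = paste("rep", rep))
  }
})

test_that("HSE scanning finds alternating nGAAn/nTTCn runs", {
  h <- scan_hse("aGAAttTTCtaGAAt")
  expect_equal(nrow(h), 1)
  expect_equal(h$units, 3L)
  expect_equal(h$offset, 1L)
  # no alternation -> no hit at min_units 3
  expect_equal(nrow(scan_hse("aGAAtaGAAt")), 0)
  # two units only
  expect_equal(nrow(scan_hse("aGAAttTTCt", min_units = 2)), 1)
})

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

test_that("HSE scanning equals brute-force enumeration on random strings", {
  set.seed(41)
  for (rep in 1:300) {
    n <- sample(10:60, 1)
    s <- random_dna(n)
    # seed some motif fragments to make hits likely
    if (rep %% 2 == 0) {
      s <- paste0(substr(s, 1, 5), "aGAAttTTCcaGAAg",
                  substr(s, 21, n))
    }
    for (mu in 2:3) {
      got <- dplyr::arrange(scan_hse(s, min_units = mu), offset)
      want <- oracle_hse(s, mu)
      expect_equal(as.data.frame(got), as.data.frame(want),
                   info = paste("rep", rep, "min_units", mu, s))
    }
  }
})

test_that("HSE hits are strand-symmetric under reverse complement", {
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  set.seed(43)
  for (rep in 1:50) {
    s <- paste0(random_dna(8), "tGAAgaTTCtcGAAa", random_dna(8))
    fwd <- scan_hse(s)
    rc <- scan_hse(revcomp(s))
    expect_equal(nrow(fwd), nrow(rc))
    expect_equal(sort(fwd$units), sort(rc$units))
    if (nrow(fwd)) {
      # offsets mirror: a run at offset i, length L maps to
      # nchar - (i + L - 1) + 1 on the reverse strand
      expect_setequal(nchar(s) - (fwd$offset + fwd$length - 1) + 1,
                      rc$offset)
    }
  }
})

test_that("upstream scanning is strand-aware", {
  ins <- "cGAAgaTTCgcGAAt"
  up_plus <- paste0(random_dna(20), ins, random_dna(30))
  revcomp <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  # plus-strand gene at 101..160 with the motif upstream; minus-strand gene
  # at 201..260 with the reverse-complemented motif downstream (its 5' side)
  seqs <- paste0(substr(paste0(up_plus, random_dna(40)), 1, 100),
                 random_dna(60),            # plus gene body, 101..160
                 random_dna(40),            # spacer, 161..200
                 random_dna(60),            # minus gene body, 201..260
                 revcomp(up_plus),          # 261..325
                 random_dna(35))
  ann <- genome_annotation(
    tibble::tibble(chrom = "c1", length = nchar(seqs), sequence = seqs),
    tibble::tibble(gene_id = c("plusG", "minusG"), chrom = "c1",
                   start = c(101L, 201L), end = c(160L, 260L),
                   strand = c("+", "-"), biotype = "coding")
  )
  res <- scan_hse_upstream(ann, window = 100)
  expect_true(res$has_hse[res$gene_id == "plusG"])
  expect_true(res$has_hse[res$gene_id == "minusG"])
})
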