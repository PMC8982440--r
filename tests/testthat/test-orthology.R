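mk_hits <- function(df, qs = NULL, ts = NULL) {
  out <- tibble::as_tibble(df)
  attr(out, "query_species") <- qs
  attr(out, "target_species") <- ts
  out
}

test_that("conserved_genes requires a reciprocated hit", {
  fwd <- mk_hits(tibble::tibble(query = "g1", target = "t1",
                                evalue = 1e-20, bitscore = 200))
  rev_ok <- mk_hits(tibble::tibble(query = "t1", target = "g1",
                                   evalue = 1e-18, bitscore = 190))
  rev_none <- rev_ok[0, ]
  expect_equal(conserved_genes(fwd, rev_ok), "g1")
  expect_equal(conserved_genes(fwd, rev_none), character(0))
  expect_equal(conserved_genes(fwd, rev_none, mode = "any_hit"), "g1")
})

test_that("species metadata mismatch is a hard error", {
  fwd <- mk_hits(tibble::tibble(query = "g1", target = "t1",
                                evalue = 1e-20, bitscore = 200), "A", "B")
  rev <- mk_hits(tibble::tibble(query = "t1", target = "g1",
                                evalue = 1e-20, bitscore = 200), "C", "A")
  expect_error(conserved_genes(fwd, rev), "mismatch")
})

test_that("conserved set and RBH match brute force on random toy tables", {
  set.seed(11)
  for (rep in 1:200) {
    h <- random_hit_tables()
    expect_equal(conserved_genes(h$fwd, h$rev),
                 oracle_conserved(h$fwd, h$rev))
    got <- rbh_pairs(h$fwd, h$rev)
    want <- dplyr::arrange(oracle_rbh(h$fwd, h$rev), query)
    expect_equal(got$query, want$query)
    expect_equal(got$target, want$target)
    # structural invariants
    expect_true(all(got$query %in% conserved_genes(h$fwd, h$rev)))
    expect_lte(nrow(got), min(dplyr::n_distinct(h$fwd$query),
                              dplyr::n_distinct(h$rev$query)))
    # swapping arguments gives the target-side conserved set
    expect_equal(conserved_genes(h$rev, h$fwd),
                 oracle_conserved(h$rev, h$fwd))
  }
})

test_that("RBH tie-breaking is deterministic: bitscore, evalue, then id", {
  fwd <- mk_hits(tibble::tibble(
    query = c("g1", "g1", "g1"), target = c("t3", "t2", "t1"),
    evalue = c(1e-30, 1e-30, 1e-20), bitscore = c(200, 200, 200)))
  rev <- mk_hits(tibble::tibble(
    query = c("t2", "t3", "t1"), target = "g1",
    evalue = 1e-30, bitscore = 300))
  # t2 and t3 tie on bitscore+evalue; lexicographically smaller t2 wins
  expect_equal(rbh_pairs(fwd, rev)$target, "t2")
})

test_that("conservation profile computes per-chromosome ratios", {
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:14),
    chrom = c(rep("c1", 10), rep("scaf", 4)),
    start = seq(1, by = 100, length.out = 14),
    end = seq(50, by = 100, length.out = 14),
    strand = "+", biotype = "coding"
  )
  ann <- genome_annotation(
    tibble::tibble(chrom = c("c1", "scaf"), length = 5000L,
                   placed = c(TRUE, FALSE)),
    genes
  )
  prof <- conservation_profile(ann, list(SpX = sprintf("g%02d", 1:4)))
  c1 <- prof[prof$chrom == "c1", ]
  expect_equal(c1$ratio, 0.4)
  expect_equal(prof$chrom, c("(unplaced)", "c1"))
  empty <- conservation_profile(ann, list(SpX = character(0)))
  expect_true(all(empty$ratio == 0))
})

toy_clade_map <- function() {
  tibble::tibble(
    species = c("F", "G1", "G2", "O1", "O2"),
    focal = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    clades = list(
      c("F", "Genus", "Family", "Root"),
      c("G1", "Genus", "Family", "Root"),
      c("G2", "Genus", "Family", "Root"),
      c("O1", "Family", "Root"),
      c("O2", "OtherFamily", "Root")
    )
  )
}

test_that("clade classification labels groups by narrowest clade", {
  map <- toy_clade_map()
  ann <- genome_annotation(
    tibble::tibble(chrom = "c1", length = 10000L),
    tibble::tibble(gene_id = c("f1", "f2", "f3", "f4"),
                   chrom = "c1", start = c(1L, 101L, 201L, 301L),
                   end = c(50L, 150L, 250L, 350L), strand = "+",
                   biotype = "coding")
  )
  groups <- tibble::tibble(
    group_id = c("OG1", "OG1", "OG2", "OG2", "OG3"),
    species = c("F", "O1", "F", "G1", "F"),
    gene_id = c("f1", "o1_1", "f2", "g1_1", "f3")
  )
  res <- classify_clades(groups, map, ann)
  lab <- setNames(res$label, res$gene_id)
  expect_equal(lab[["f1"]], "conserved")       # spans an outgroup
  expect_equal(lab[["f2"]], "genus_specific")  # focal + congener
  expect_equal(lab[["f3"]], "focal_specific")  # focal-only group
  expect_equal(lab[["f4"]], "focal_specific")  # singleton default
  res2 <- classify_clades(groups, map, ann, singletons_focal = FALSE)
  expect_equal(setNames(res2$label, res2$gene_id)[["f4"]], "unassigned")
})

test_that("clade classification matches semantics oracle on random groups", {
  map <- toy_clade_map()
  set.seed(23)
  ann <- genome_annotation(
    tibble::tibble(chrom = "c1", length = 100000L),
    tibble::tibble(gene_id = sprintf("f%02d", 1:30), chrom = "c1",
                   start = seq(1L, by = 100L, length.out = 30),
                   end = seq(50L, by = 100L, length.out = 30),
                   strand = "+", biotype = "coding")
  )
  for (rep in 1:50) {
    rows <- lapply(1:10, function(gi) {
      sp <- unique(c("F", sample(map$species,
                                 sample(0:4, 1), replace = FALSE)))
      tibble::tibble(group_id = paste0("OG", gi), species = sp,
                     gene_id = ifelse(sp == "F", sprintf("f%02d", gi),
                                      paste0(tolower(sp), "_", gi)))
    })
    groups <- dplyr::bind_rows(rows)
    res <- classify_clades(groups, map, ann)
    for (gi in 1:10) {
      members <- groups$species[groups$group_id == paste0("OG", gi)]
      expect_equal(res$label[res$gene_id == sprintf("f%02d", gi)],
                   oracle_clade_label(members, map),
                   info = paste("rep", rep, "group", gi))
    }
    # permutation invariance of rows
    res_perm <- classify_clades(groups[sample(nrow(groups)), ], map, ann)
    expect_equal(dplyr::arrange(res, gene_id),
                 dplyr::arrange(res_perm, gene_id))
  }
})

test_that("cumulative specificity counts run along the gene order", {
  ann <- genome_annotation(
    tibble::tibble(chrom = "c1", length = 1000L),
    tibble::tibble(gene_id = c("a", "b", "c", "d"), chrom = "c1",
                   start = c(10L, 20L, 30L, 40L), end = c(15L, 25L, 35L, 45L),
                   strand = "+", biotype = "coding")
  )
  assignment <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"), chrom = "c1",
    start = c(10L, 20L, 30L, 40L),
    label = c("focal_specific", "genus_specific", "conserved",
              "focal_specific")
  )
  prof <- cumulative_specificity_profile(assignment, ann)
  expect_equal(prof$cum_focal_specific, c(1L, 1L, 1L, 2L))
  expect_equal(prof$cum_genus_specific, c(0L, 1L, 1L, 1L))
  expect_equal(prof$gene_rank, 1:4)
  tot <- specificity_totals(assignment, ann)
  expect_equal(sum(tot$n), 4L)
})
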