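test_that("same seed gives byte-identical bundles", {
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  cfg <- small_sim_config(seed = 77)
  simulate_bundle(cfg, d1)
  simulate_bundle(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_setequal(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("generator fails fast on infeasible configurations", {
  cfg <- small_sim_config()
  cfg$chrom_lengths <- rep(20000L, 4)  # far too small for the gene load
  expect_error(simulate_bundle(cfg, tempdir()), "infeasible")
})

test_that("silent multicopy-family members are recovered exactly", {
  sb <- small_bundle()
  cfg <- small_sim_config()
  fam <- sb$bundle$annotation$genes
  fam_ids <- fam$gene_id[!is.na(fam$family) & fam$family == "IRfam"]
  expect_length(fam_ids, cfg$family_copies)
  fl <- flag_nonexpressed(sb$bundle$expression)
  expect_equal(sum(fl$status[fl$gene_id %in% fam_ids] == "silent"),
               cfg$family_silent)
})

test_that("per-chromosome coding GC recovers its targets within 0.005", {
  sb <- small_bundle()
  got <- coding_gc_by_chromosome(sb$bundle$annotation)
  want <- small_sim_config()$coding_gc
  expect_equal(got$mean_gc, want, tolerance = 0.005)
})

test_that("windowed GC matches the generator's intended composition", {
  sb <- small_bundle()
  gc <- gc_track(sb$bundle$annotation, window_size = 2e4)
  by_chr <- gc |>
    dplyr::group_by(chrom) |>
    dplyr::summarise(m = stats::weighted.mean(value, end - start + 1))
  intended <- sb$sim$truth$chromosomes$intended_gc
  expect_equal(by_chr$m, intended, tolerance = 0.005)
  # sandbox (GC shift -0.03) is the low-GC outlier
  expect_equal(by_chr$chrom[which.min(by_chr$m)], "chr_4")
})

test_that("sandbox diversity region and Ts/Tv depression are recovered", {
  sb <- small_bundle()
  b <- sb$bundle
  cfg <- small_sim_config()
  pi <- pi_track(b$sites, b$annotation, window_size = 2e4)
  len4 <- b$annotation$chromosomes$length[4]
  in_region <- pi$chrom == "chr_4" &
    pi$start >= cfg$pi_region[1] * len4 & pi$end <= cfg$pi_region[2] * len4
  ratio <- mean(pi$value[in_region], na.rm = TRUE) /
    mean(pi$value, na.rm = TRUE)
  expect_gt(ratio, 2)
  expect_lt(ratio, 4)
  ts <- tstv(b$sites, scope = "chromosome")
  expect_equal(ts$chrom[which.min(ts$tstv)], "chr_4")
})

test_that("clade labels round-trip through orthogroup classification", {
  sb <- small_bundle()
  b <- sb$bundle
  assignment <- classify_clades(b$orthogroups, b$clade_map, b$annotation)
  truth <- sb$sim$truth$genes
  merged <- dplyr::inner_join(assignment,
                              dplyr::select(truth, gene_id, clade_label),
                              by = "gene_id")
  expect_equal(merged$label, merged$clade_label)
})

test_that("island blocks, pI contrast and HSEs are recovered from the bundle", {
  sb <- small_bundle()
  b <- sb$bundle
  cfg <- small_sim_config()
  arrays <- detect_tandem_arrays(b$annotation)
  main <- arrays[which.max(arrays$n_genes), ]
  expect_equal(main$family, "Lea")
  expect_equal(main$n_genes,
               cfg$island_blocks * cfg$island_genes_per_block)
  expect_true(main$strand_homogeneous)

  sig <- regulation_signature(b$de_calls)
  blocks <- group_blocks(main$genes[[1]], sig)
  expect_equal(dplyr::n_distinct(blocks$block), cfg$island_blocks)
  expect_equal(unname(table(blocks$block)),
               rep(cfg$island_genes_per_block, cfg$island_blocks),
               ignore_attr = TRUE)
  # recovered block signatures equal the configured ones, in order
  expect_equal(unique(blocks$signature), cfg$island_signatures)

  cmp <- compare_block_pi(blocks, b$annotation)
  means <- cmp$means$mean
  expect_equal(means, cfg$island_pi_targets, tolerance = 0.4)

  hse <- scan_hse_upstream(b$annotation, gene_ids = main$genes[[1]])
  truth <- sb$sim$truth$genes
  merged <- dplyr::inner_join(hse,
                              dplyr::select(truth, gene_id, has_hse),
                              by = "gene_id")
  expect_equal(merged$has_hse.x, merged$has_hse.y)
})

test_that("essential sets are depleted on the sandbox chromosome", {
  sb <- small_bundle()
  b <- sb$bundle
  enr <- enrich_sets(b$annotation, b$gene_sets)
  ess4 <- enr[enr$set_id == "essential" & enr$chrom == "chr_4", ]
  expect_equal(ess4$direction, "deplete")
  expect_lt(ess4$q, 0.05)
})
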