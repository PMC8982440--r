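test_that("hypergeometric test handles degenerate and saturated cases", {
  z <- hypergeom_test(0, 0, 10, 100)
  expect_equal(z$p_enrich, 1)
  z2 <- hypergeom_test(5, 5, 5, 5)
  expect_equal(unlist(z2), c(p_enrich = 1, p_deplete = 1, p_two_sided = 1))
  expect_error(hypergeom_test(6, 5, 10, 100), "inconsistent")
  expect_error(hypergeom_test(0, 50, 60, 100), "inconsistent") # k < lower bound
})

test_that("hypergeometric tails match exhaustive pmf enumeration, N <= 30", {
  worst <- 0
  identity_worst <- 0
  for (N in 1:30) {
    for (K in 0:N) {
      for (n in 0:N) {
        o <- oracle_hyper_pmf(N, K, n)
        got <- hypergeom_test(o$support, rep(K, length(o$support)),
                              rep(n, length(o$support)),
                              rep(N, length(o$support)))
        want_enrich <- rev(cumsum(rev(o$pmf)))
        want_deplete <- cumsum(o$pmf)
        want_two <- vapply(seq_along(o$pmf), function(idx)
          min(1, sum(o$pmf[o$pmf <= o$pmf[idx] * (1 + 1e-7)])), 1)
        worst <- max(worst,
                     abs(got$p_enrich - want_enrich),
                     abs(got$p_deplete - want_deplete),
                     abs(got$p_two_sided - want_two))
        identity_worst <- max(identity_worst,
                              abs(got$p_enrich + got$p_deplete -
                                    (1 + o$pmf)))
      }
    }
  }
  expect_lt(worst, 1e-9)
  # p_enrich + p_deplete = 1 + P[X = k]
  expect_lt(identity_worst, 1e-9)
})

test_that("two-sided p agrees with fisher.test on sample tables", {
  cases <- list(c(3, 10, 12, 40), c(45, 117, 110, 599), c(0, 5, 8, 30),
                c(7, 9, 14, 20))
  for (cs in cases) {
    k <- cs[1]; K <- cs[2]; n <- cs[3]; N <- cs[4]
    got <- hypergeom_test(k, K, n, N)$p_two_sided
    ft <- stats::fisher.test(matrix(c(k, K - k, n - k, N - K - n + k), 2))
    expect_equal(got, ft$p.value, tolerance = 1e-7)
  }
})

scatter_annotation <- function(n_genes = 500,
                               sizes = c(c1 = 150L, c2 = 150L,
                                         c3 = 120L, c4 = 80L)) {
  chrom <- rep(names(sizes), sizes)
  genome_annotation(
    tibble::tibble(chrom = names(sizes), length = 1000000L),
    tibble::tibble(gene_id = sprintf("g%04d", seq_len(sum(sizes))),
                   chrom = chrom,
                   start = as.integer(stats::ave(seq_len(sum(sizes)),
                                                 chrom,
                                                 FUN = seq_along) * 1000L),
                   end = as.integer(stats::ave(seq_len(sum(sizes)), chrom,
                                               FUN = seq_along) * 1000L + 500L),
                   strand = "+", biotype = "coding")
  )
}

test_that("enrich_sets flags a fully concentrated set and applies BH", {
  ann <- scatter_annotation()
  set_on_c4 <- ann$genes$gene_id[ann$genes$chrom == "c4"][1:30]
  res <- enrich_sets(ann, list(conc = set_on_c4))
  expect_equal(nrow(res), 4)
  expect_equal(res$chrom[which.min(res$p_enrich)], "c4")
  expect_true(res$q[res$chrom == "c4"] < 0.05)
  expect_equal(res$direction[res$chrom == "c4"], "enrich")
  expect_true(all(res$q >= res$p_two_sided - 1e-12))
  expect_error(enrich_sets(ann, list(bad = "nonexistent")), "outside")
})

test_that("non-expressed flagging uses mean TPM with an inclusive threshold", {
  expr <- tibble::tibble(gene_id = c("gA", "gB"),
                         S1 = c(0, 2), S2 = c(0, 2), S3 = c(3, 2))
  fl <- flag_nonexpressed(expr)
  expect_equal(fl$status, c("silent", "expressed"))  # mean 1.0 is silent
  ann <- toy_annotation(with_seq = FALSE)
  fl2 <- flag_nonexpressed(
    tibble::tibble(gene_id = "g1", S1 = 5), annotation = ann)
  expect_setequal(fl2$status[fl2$gene_id %in% c("g2", "g3")], "no_data")
})

array_annotation <- function(families, strands = NULL) {
  n <- length(families)
  if (is.null(strands)) strands <- rep("+", n)
  genome_annotation(
    tibble::tibble(chrom = "c1", length = 100000L),
    tibble::tibble(gene_id = sprintf("g%02d", seq_len(n)), chrom = "c1",
                   start = seq(1L, by = 1000L, length.out = n),
                   end = seq(500L, by = 1000L, length.out = n),
                   strand = strands, biotype = "coding",
                   family = families)
  )
}

test_that("tandem arrays bridge allowed intervening genes", {
  a1 <- detect_tandem_arrays(array_annotation(c("A", "A", "B", "A")),
                             max_intervening = 1)
  arrA <- a1[a1$family == "A", ]
  expect_equal(arrA$n_genes, 3L)
  expect_equal(arrA$genes[[1]], c("g01", "g02", "g04"))

  a0 <- detect_tandem_arrays(array_annotation(c("A", "B", "B", "A")),
                             max_intervening = 0)
  expect_equal(nrow(a0), 1)
  expect_equal(a0$family, "B")
})

test_that("tandem arrays match brute force on random family strings", {
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(4:12, 1)
    fams <- sample(c("A", "B", NA), n, replace = TRUE)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    for (mi in 0:2) {
      for (same_strand in c(FALSE, TRUE)) {
        got <- detect_tandem_arrays(array_annotation(fams, strands),
                                    max_intervening = mi,
                                    require_same_strand = same_strand)
        want <- oracle_tandem(fams, strands, mi, same_strand)
        expect_equal(nrow(got), length(want), info = paste(rep, mi))
        if (length(want)) {
          want_genes <- lapply(want, function(r)
            sprintf("g%02d", r$members))
          got_genes <- got$genes
          expect_setequal(vapply(got_genes, paste, "", collapse = ","),
                          vapply(want_genes, paste, "", collapse = ","))
        }
        # partition invariant: no gene in two arrays
        all_members <- unlist(got$genes)
        expect_equal(anyDuplicated(all_members), 0L)
      }
    }
  }
})

test_that("chromosome summary reproduces published density/percentage cells", {
  s <- summarize_chromosome_counts(pv_chromosome_counts())
  expect_equal(s$genes_per_mb, c(143.0, 139.5, 133.5, 231.2))
  expect_equal(s$expressed_per_mb, c(81.0, 77.8, 70.5, 82.5))
  expect_equal(s$pct_length, c(31, 30, 27, 12))
  expect_equal(s$pct_genes, c(30, 28, 24, 18))
  expect_equal(s$pct_coding, c(93, 93, 93, 97))
  expect_equal(s$pct_expressed, c(57, 56, 53, 36))
  expect_equal(s$pct_nonexpressed, c(43, 44, 47, 64))
})

test_that("summarize_chromosomes derives the same cells from an annotation", {
  sb <- small_bundle()
  s <- summarize_chromosomes(sb$bundle$annotation, sb$bundle$expression)
  truth_genes <- sb$sim$truth$genes
  for (ch in unique(s$chrom)) {
    expect_equal(s$total[s$chrom == ch], sum(truth_genes$chrom == ch))
    expect_equal(s$nonexpressed[s$chrom == ch],
                 sum(truth_genes$chrom == ch & !truth_genes$expressed))
  }
  expect_equal(s$coding + s$noncoding, s$total)
  expect_equal(s$expressed + s$nonexpressed, s$total)
})

test_that("group_compare: null, separated, and hand-computed cases", {
  same <- group_compare(list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4)))
  expect_gt(tidy(same)$p_adj, 0.99)

  set.seed(5)
  sep <- group_compare(list(a = rnorm(30), b = rnorm(30, mean = 5)))
  expect_lt(tidy(sep)$p_adj, 1e-6)
  expect_lt(glance(sep)$p_value, 1e-6)

  # hand-computed one-way ANOVA: groups {1,2,3}, {2,3,4}, {6,7,8}
  g <- list(x = c(1, 2, 3), y = c(2, 3, 4), z = c(6, 7, 8))
  grand <- mean(unlist(g))
  ss_b <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2, 1))
  ss_w <- sum(vapply(g, function(v) sum((v - mean(v))^2), 1))
  f_hand <- (ss_b / 2) / (ss_w / 6)
  fit <- group_compare(g)
  expect_equal(glance(fit)$f_statistic, f_hand, tolerance = 1e-10)
  expect_equal(glance(fit)$df_between, 2)
  expect_equal(glance(fit)$df_within, 6)

  # degenerate all-identical data reports a missing F
  flat <- group_compare(list(a = c(2, 2, 2), b = c(2, 2, 2)))
  expect_true(is.na(glance(flat)$f_statistic))
})
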