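test_that("identical sequences give zero distances and a missing ratio", {
  r <- ng86_dnds("ATGGCTAAA", "ATGGCTAAA")
  expect_equal(r$dn, 0)
  expect_equal(r$ds, 0)
  expect_true(is.na(r$dnds))
  expect_equal(r$n_codons, 3L)
})

test_that("a single synonymous change yields dS > 0, dN = 0", {
  # GGA -> GGG (both glycine) in a two-codon alignment: the synonymous
  # proportion is 1/(4/3) = 3/4, exactly where the Jukes-Cantor correction
  # degenerates, so the distance is flagged saturated
  r2 <- ng86_dnds("GGAAAA", "GGGAAA")
  expect_equal(r2$nd, 0)
  expect_equal(r2$sd, 1)
  expect_equal(r2$dn, 0)
  expect_true(r2$saturated)
  # with more synonymous sites the corrected dS is positive and finite
  r <- ng86_dnds("GGAAAAGGAGGA", "GGGAAAGGAGGA")
  expect_equal(r$dn, 0)
  expect_gt(r$ds, 0)
  expect_equal(r$nd, 0)
  expect_equal(r$sd, 1)
})

test_that("length mismatches and frame violations are hard errors", {
  expect_error(ng86_dnds("ATGGCT", "ATG"), "lengths differ")
  expect_error(ng86_dnds("ATGG", "ATGC"), "multiple of 3")
})

test_that("codons with gaps or stops are skipped and counted", {
  r <- ng86_dnds("ATG---AAA", "ATGGCTAAA")
  expect_equal(r$n_codons, 2L)
  expect_equal(r$n_skipped, 1L)
  r2 <- ng86_dnds("ATGTAAAAA", "ATGTAAAAA")  # internal stop codon
  expect_equal(r2$n_skipped, 1L)
})

test_that("site and pathway counts match exhaustive enumeration", {
  set.seed(19)
  codons <- sense_codons()
  checked <- 0
  for (rep in 1:400) {
    c1 <- sample(codons, 1)
    c2 <- sample(codons, 1)
    d <- sum(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (d > 2) next  # spec scope: pairs differing at <= 2 positions
    got <- ng86_dnds(c1, c2)
    want <- oracle_ng86_pair(c1, c2)
    expect_equal(got$s_sites, want$s_sites, tolerance = 1e-12,
                 info = paste(c1, c2))
    expect_equal(got$n_sites, 3 - want$s_sites, tolerance = 1e-12)
    expect_equal(got$sd, want$sd, tolerance = 1e-12, info = paste(c1, c2))
    expect_equal(got$nd, want$nd, tolerance = 1e-12, info = paste(c1, c2))
    checked <- checked + 1
  }
  expect_gt(checked, 100)
})

test_that("multi-codon sequences agree with the per-codon oracle totals", {
  set.seed(29)
  codons <- sense_codons()
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    a <- sample(codons, n, replace = TRUE)
    b <- a
    # mutate a couple of codons (any distance, including 3)
    for (j in sample(n, 2)) b[j] <- sample(codons, 1)
    got <- ng86_dnds(paste(a, collapse = ""), paste(b, collapse = ""))
    per <- lapply(seq_len(n), function(j) oracle_ng86_pair(a[j], b[j]))
    expect_equal(got$s_sites, sum(vapply(per, `[[`, 1, "s_sites")),
                 tolerance = 1e-10)
    expect_equal(got$sd, sum(vapply(per, `[[`, 1, "sd")),
                 tolerance = 1e-10)
    expect_equal(got$nd, sum(vapply(per, `[[`, 1, "nd")),
                 tolerance = 1e-10)
    # invariants: symmetry and site-count conservation
    swapped <- ng86_dnds(paste(b, collapse = ""), paste(a, collapse = ""))
    expect_equal(got$dn, swapped$dn, tolerance = 1e-12)
    expect_equal(got$ds, swapped$ds, tolerance = 1e-12)
    expect_equal(got$n_sites + got$s_sites, 3 * got$n_codons,
                 tolerance = 1e-10)
  }
})

test_that("Jukes-Cantor saturation is flagged missing", {
  # force an extreme proportion via a tiny alignment with all-different,
  # nonsynonymous codons
  r <- ng86_dnds("AAA", "TGG")  # K -> W, three differences
  expect_true(is.finite(r$nd + r$sd))
  if (is.na(r$dn) || is.na(r$ds)) expect_true(r$saturated)
})
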