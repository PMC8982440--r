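BASES <- c("A", "C", "G", "T")

codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# fraction-of-3 synonymous site count for one sense codon; mutations to stop
# codons count as nonsynonymous
codon_syn_sites <- function(codon) {
  aa <- codon_aa(codon)
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(BASES, substring(codon, pos, pos))) {
      mut <- codon
      substring(mut, pos, pos) <- b
      if (identical(codon_aa(mut), aa)) s <- s + 1 / 3
    }
  }
  s
}

# all substitution pathways between two sense codons; returns averaged
# (syn, nonsyn) step counts, excluding pathways through stop codons
codon_path_counts <- function(c1, c2) {
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  d <- length(diff_pos)
  if (d == 0) return(c(syn = 0, nonsyn = 0))
  perms <- if (d == 1) list(diff_pos) else {
    idx <- permutations_of(d)
    lapply(idx, function(o) diff_pos[o])
  }
  tallies <- lapply(perms, function(order) {
    cur <- c1
    syn <- 0; nonsyn <- 0; blocked <- FALSE
    for (pos in order) {
      nxt <- cur
      substring(nxt, pos, pos) <- substring(c2, pos, pos)
      if (codon_aa(nxt) == "*") blocked <- TRUE
      if (codon_aa(nxt) == codon_aa(cur)) syn <- syn + 1 else
        nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn, blocked = as.numeric(blocked))
  })
  m <- do.call(rbind, tallies)
  valid <- m[, "blocked"] == 0
  if (any(valid)) m <- m[valid, , drop = FALSE]
  c(syn = mean(m[, "syn"]), nonsyn = mean(m[, "nonsyn"]))
}

permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- permutations_of(n - 1)
    for (r in rest) out[[length(out) + 1L]] <- c(i, ifelse(r >= i, r + 1L, r))
  }
  out
}

jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -3 / 4 * log(1 - 4 / 3 * p))
}

split_codons <- function(x) {
  substring(toupper(x), seq(1, nchar(x), 3), seq(3, nchar(x), 3))
}

#' Nei-Gojobori (1986) dN/dS for an aligned codon pair of sequences
#'
#' Counts synonymous and nonsynonymous sites per codon (averaged over the
#' two sequences; mutations creating stop codons count as nonsynonymous)
#' and substitutions with pathway averaging over all orderings of the
#' observed per-codon differences, excluding pathways through stop codons
#' (all-blocked codon pairs fall back to averaging over every pathway).
#' The Jukes-Cantor correction `d = -(3/4) ln(1 - (4/3) p)` is applied to
#' both proportions; a proportion at or above 3/4 leaves that distance (and
#' the ratio) missing, flagged in `saturated`.
#'
#' Codons containing gaps, ambiguity codes, or stop codons in either
#' sequence are skipped and counted in `n_skipped`.
#'
#' @param cds_a,cds_b In-frame aligned nucleotide strings of equal length,
#'   a multiple of 3.
#' @return One-row tibble: `dn`, `ds`, `dnds` (`NA` when `ds` is 0 or a
#'   distance is undefined), `n_codons` (used), `n_skipped`, `n_sites`,
#'   `s_sites`, `nd`, `sd`, `saturated`.
#' @export
#' @examples
#' ng86_dnds("GGAAAA", "GGGAAA")  # one synonymous change
ng86_dnds <- function(cds_a, cds_b) {
  if (nchar(cds_a) != nchar(cds_b)) {
    abort("aligned CDS lengths differ")
  }
  if (nchar(cds_a) %% 3 != 0) abort("CDS length is not a multiple of 3")
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  clean[clean] <- codon_aa(ca[clean]) != "*" & codon_aa(cb[clean]) != "*"
  n_skipped <- sum(!clean)
  ca <- ca[clean]; cb <- cb[clean]
  n_codons <- length(ca)
  if (n_codons == 0) {
    return(tibble(dn = NA_real_, ds = NA_real_, dnds = NA_real_,
                  n_codons = 0L, n_skipped = n_skipped, n_sites = NA_real_,
                  s_sites = NA_real_, nd = NA_real_, sd = NA_real_,
                  saturated = FALSE))
  }
  s_a <- vapply(ca, codon_syn_sites, 1)
  s_b <- vapply(cb, codon_syn_sites, 1)
  s_sites <- sum((s_a + s_b) / 2)
  n_sites <- 3 * n_codons - s_sites
  counts <- vapply(seq_len(n_codons),
                   function(i) codon_path_counts(ca[i], cb[i]), numeric(2))
  sd_ <- sum(counts["syn", ])
  nd_ <- sum(counts["nonsyn", ])
  ps <- if (s_sites > 0) sd_ / s_sites else 0
  pn <- if (n_sites > 0) nd_ / n_sites else 0
  ds <- jc_correct(ps)
  dn <- jc_correct(pn)
  saturated <- is.na(ds) || is.na(dn)
  dnds <- if (saturated || ds == 0) NA_real_ else dn / ds
  tibble(dn = dn, ds = ds, dnds = dnds, n_codons = n_codons,
         n_skipped = n_skipped, n_sites = n_sites, s_sites = s_sites,
         nd = nd_, sd = sd_, saturated = saturated)
}

#' dN/dS for many aligned pairs
#'
#' @param pairs Tibble with columns `pair_id`, `cds_a`, `cds_b`.
#' @return One [ng86_dnds()] row per pair, keyed by `pair_id`.
#' @export
ng86_dnds_pairs <- function(pairs) {
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    mutate(ng86_dnds(pairs$cds_a[i], pairs$cds_b[i]),
           pair_id = pairs$pair_id[i], .before = 1)
  })
}
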