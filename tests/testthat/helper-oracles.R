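# independent brute-force oracles; each deliberately re-derives its quantity
# from first principles rather than calling the implementation's path

# average pairwise difference over all read pairs drawn without replacement
oracle_pi_pairs <- function(ref_count, alt_count) {
  reads <- c(rep(0L, ref_count), rep(1L, alt_count))
  n <- length(reads)
  diffs <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) diffs <- diffs + as.integer(reads[i] != reads[j])
  }
  diffs / choose(n, 2)
}

# hypergeometric pmf over the full support from binomial coefficients
oracle_hyper_pmf <- function(N, K, n) {
  support <- max(0, n + K - N):min(K, n)
  pmf <- choose(K, support) * choose(N - K, n - support) / choose(N, n)
  list(support = support, pmf = pmf)
}

# reciprocal-hit conserved set by scanning every forward/reverse pair
oracle_conserved <- function(fwd, rev) {
  out <- character(0)
  for (i in seq_len(nrow(fwd))) {
    g <- fwd$query[i]; t <- fwd$target[i]
    for (j in seq_len(nrow(rev))) {
      if (rev$query[j] == t && rev$target[j] == g) {
        out <- c(out, g)
        break
      }
    }
  }
  sort(unique(out))
}

# RBH by explicit best-hit search with the (bitscore, -evalue, id) rule
oracle_best <- function(hits, q) {
  rows <- hits[hits$query == q, ]
  best <- NULL
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    if (is.null(best) ||
        r$bitscore > best$bitscore ||
        (r$bitscore == best$bitscore && r$evalue < best$evalue) ||
        (r$bitscore == best$bitscore && r$evalue == best$evalue &&
         r$target < best$target)) {
      best <- r
    }
  }
  best$target
}

oracle_rbh <- function(fwd, rev) {
  pairs <- list()
  for (q in sort(unique(fwd$query))) {
    t <- oracle_best(fwd, q)
    if (t %in% rev$query && oracle_best(rev, t) == q) {
      pairs[[length(pairs) + 1]] <- c(q, t)
    }
  }
  if (!length(pairs)) {
    return(tibble::tibble(query = character(), target = character()))
  }
  m <- do.call(rbind, pairs)
  tibble::tibble(query = m[, 1], target = m[, 2])
}

# random hit-table pair over small gene universes
random_hit_tables <- function(n_query = 20, n_target = 20, n_hits = 40) {
  qg <- sprintf("q%02d", seq_len(n_query))
  tg <- sprintf("t%02d", seq_len(n_target))
  mk <- function(qs, ts) {
    tibble::tibble(
      query = sample(qs, n_hits, replace = TRUE),
      target = sample(ts, n_hits, replace = TRUE),
      evalue = 10^-sample(5:30, n_hits, replace = TRUE),
      bitscore = sample(seq(50, 300, by = 10), n_hits, replace = TRUE)
    ) |> dplyr::distinct(query, target, .keep_all = TRUE)
  }
  list(fwd = mk(qg, tg), rev = mk(tg, qg))
}

# clade label straight from member-species semantics
oracle_clade_label <- function(member_species, clade_map) {
  focal <- clade_map$species[clade_map$focal]
  genus <- clade_map$clades[[which(clade_map$focal)]][2]
  genus_species <- clade_map$species[vapply(clade_map$clades,
                                            function(p) genus %in% p, TRUE)]
  if (all(member_species == focal)) return("focal_specific")
  if (all(member_species %in% genus_species)) return("genus_specific")
  "conserved"
}

# maximal same-family runs by direct scanning over the gene order
oracle_tandem <- function(families, strands, max_intervening,
                          require_same_strand = FALSE) {
  runs <- list()
  for (fam in unique(families[!is.na(families)])) {
    idx <- which(!is.na(families) & families == fam)
    current <- idx[1]
    for (i in idx[-1]) {
      gap_ok <- i - current[length(current)] - 1 <= max_intervening
      strand_ok <- !require_same_strand ||
        strands[i] == strands[current[length(current)]]
      if (gap_ok && strand_ok) {
        current <- c(current, i)
      } else {
        if (length(current) >= 2) runs[[length(runs) + 1]] <-
            list(family = fam, members = current)
        current <- i
      }
    }
    if (length(current) >= 2) runs[[length(runs) + 1]] <-
        list(family = fam, members = current)
  }
  runs
}

# greedy left-to-right segmentation re-derived with explicit state
oracle_blocks <- function(signatures, max_silent_gap) {
  blocks <- list()
  open_sig <- NA_character_
  silent_seen <- 0
  for (i in seq_along(signatures)) {
    s <- signatures[i]
    if (s == "") {
      silent_seen <- silent_seen + 1
      if (silent_seen > max_silent_gap) open_sig <- NA_character_
      next
    }
    silent_seen <- 0
    if (!is.na(open_sig) && s == open_sig) {
      blocks[[length(blocks)]] <- c(blocks[[length(blocks)]], i)
    } else {
      blocks[[length(blocks) + 1]] <- i
      open_sig <- s
    }
  }
  blocks
}

# every maximal alternating nGAAn/nTTCn run by exhaustive (offset, units)
# checking
oracle_hse <- function(s, min_units) {
  s <- toupper(s)
  n <- nchar(s)
  unit_type <- function(i) {
    if (i < 1 || i + 4 > n) return(0L)
    core <- substr(s, i + 1, i + 3)
    if (core == "GAA") return(1L)
    if (core == "TTC") return(2L)
    0L
  }
  valid_run <- function(i, u) {
    types <- vapply(seq_len(u), function(k) unit_type(i + 5 * (k - 1)), 0L)
    if (any(types == 0L)) return(FALSE)
    if (u > 1 && any(types[-1] == types[-u])) return(FALSE)
    TRUE
  }
  hits <- list()
  for (i in seq_len(max(0, n - 4))) {
    for (u in seq_len((n - i + 1) %/% 5)) {
      if (!valid_run(i, u)) next
      left_ext <- i - 5 >= 1 && valid_run(i - 5, u + 1)
      right_ext <- valid_run(i, u + 1)
      if (u >= min_units && !left_ext && !right_ext) {
        hits[[length(hits) + 1]] <-
          tibble::tibble(offset = i, length = 5L * u, units = u)
      }
    }
  }
  if (!length(hits)) {
    return(tibble::tibble(offset = integer(), length = integer(),
                          units = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(hits), offset)
}

# NG86 oracle: sites and pathway-averaged substitutions from scratch
oracle_all_orders <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (k in seq_along(v)) {
    for (rest in oracle_all_orders(v[-k])) {
      out[[length(out) + 1]] <- c(v[k], rest)
    }
  }
  out
}

oracle_ng86_pair <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  aa <- function(x) unname(gc[x])
  syn_sites <- function(codon) {
    tot <- 0
    for (pos in 1:3) {
      for (b in c("A", "C", "G", "T")) {
        if (b == substr(codon, pos, pos)) next
        mut <- codon
        substr(mut, pos, pos) <- b
        if (aa(mut) == aa(codon)) tot <- tot + 1
      }
    }
    tot / 3
  }
  d_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  path_counts <- if (!length(d_pos)) {
    c(0, 0)
  } else {
    res <- list()
    for (ord in oracle_all_orders(d_pos)) {
      cur <- c1; sy <- 0; ns <- 0; blocked <- FALSE
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (aa(nxt) == "*") blocked <- TRUE
        if (aa(nxt) == aa(cur)) sy <- sy + 1 else ns <- ns + 1
        cur <- nxt
      }
      res[[length(res) + 1]] <- c(sy, ns, blocked)
    }
    m <- do.call(rbind, res)
    keep <- m[, 3] == 0
    if (any(keep)) m <- m[keep, , drop = FALSE]
    c(mean(m[, 1]), mean(m[, 2]))
  }
  list(s_sites = (syn_sites(c1) + syn_sites(c2)) / 2,
       sd = path_counts[1], nd = path_counts[2])
}

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}
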