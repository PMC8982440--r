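# ionizable-group pKa set used throughout (termini plus C, D, E, H, K, R, Y)
default_pka <- c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
                 H = 6.5, K = 10.8, R = 12.5, Y = 10.1)

net_charge_at <- function(pH, counts, pka) {
  pos_groups <- c("Nterm", "H", "K", "R")
  neg_groups <- c("Cterm", "C", "D", "E", "Y")
  pos <- sum(counts[pos_groups] / (1 + 10^(pH - pka[pos_groups])))
  neg <- sum(counts[neg_groups] / (1 + 10^(pka[neg_groups] - pH)))
  pos - neg
}

#' Protein isoelectric point (pI)
#'
#' The pH at which the protein's net charge crosses zero, with per-group
#' charges from the Henderson-Hasselbalch equation (one N-terminal and one
#' C-terminal group plus side chains of C, D, E, H, K, R, Y), solved by
#' bisection on pH 0–14 to within 0.001. Characters outside the standard
#' 20-letter alphabet are ignored with a warning.
#'
#' @param protein Character vector of amino-acid sequences.
#' @param pka Named pKa vector; the default is
#'   `c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1, H = 6.5,
#'   K = 10.8, R = 12.5, Y = 10.1)`.
#' @return Numeric vector of pI values.
#' @export
#' @examples
#' isoelectric_point("KKKK") > isoelectric_point("DDDD")
isoelectric_point <- function(protein, pka = default_pka) {
  vapply(protein, function(p) {
    if (is.na(p) || nchar(p) == 0) abort("empty protein sequence")
    aa <- strsplit(toupper(p), "")[[1]]
    standard <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    if (any(!aa %in% standard)) {
      warn(paste0("ignoring ", sum(!aa %in% standard),
                  " non-standard residues"))
      aa <- aa[aa %in% standard]
      if (!length(aa)) abort("no standard residues in protein sequence")
    }
    counts <- c(Nterm = 1, Cterm = 1,
                C = sum(aa == "C"), D = sum(aa == "D"), E = sum(aa == "E"),
                H = sum(aa == "H"), K = sum(aa == "K"), R = sum(aa == "R"),
                Y = sum(aa == "Y"))
    lo <- 0; hi <- 14
    while (hi - lo > 0.001) {
      mid <- (lo + hi) / 2
      if (net_charge_at(mid, counts, pka) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1), USE.NAMES = !is.null(names(protein)))
}

#' Compare protein pI between regulation blocks
#'
#' Computes one pI per member gene (one protein per gene) and delegates to
#' [group_compare()] (one-way ANOVA + Tukey HSD) over the per-block pI
#' lists. Blocks with fewer than two proteins are excluded with a warning.
#'
#' @param blocks Block assignment tibble from [group_blocks()].
#' @param proteins Named character vector `gene_id -> protein`, or a
#'   [genome_annotation()] whose genes carry proteins.
#' @param pka Passed to [isoelectric_point()].
#' @return A [group_compare()] result; the per-gene pI table is attached as
#'   attribute `"pi_values"`.
#' @export
compare_block_pi <- function(blocks, proteins, pka = default_pka) {
  if (inherits(proteins, "genome_annotation")) {
    proteins <- setNames(proteins$genes$protein, proteins$genes$gene_id)
  }
  prot <- proteins[blocks$gene_id]
  missing <- blocks$gene_id[is.na(prot)]
  if (length(missing)) {
    warn(paste0("no protein for ", length(missing), " block genes; dropped"))
  }
  pi_tab <- tibble(
    gene_id = blocks$gene_id[!is.na(prot)],
    block = blocks$block[!is.na(prot)],
    pi = isoelectric_point(unname(prot[!is.na(prot)]), pka = pka)
  )
  sizes <- dplyr::count(pi_tab, .data$block)
  small <- sizes$block[sizes$n < 2]
  if (length(small)) {
    warn(paste0("excluding block(s) with a single protein: ",
                paste(small, collapse = ", ")))
    pi_tab <- filter(pi_tab, !.data$block %in% small)
  }
  out <- group_compare(tibble(label = paste0("block_", pi_tab$block),
                              value = pi_tab$pi))
  attr(out, "pi_values") <- pi_tab
  out
}
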