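#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Shared comparison engine for per-window statistics between chromosomes
#' (GC, Ts/Tv) and per-block protein pI: a one-way ANOVA followed by Tukey's
#' honestly-significant-difference test on the studentized-range
#' distribution.
#'
#' @param values Either a tibble with columns `label` and `value`, or a
#'   named list of numeric vectors. At least two groups with at least two
#'   observations each are required; all-identical data yields a missing F.
#' @return Object of class `group_comparison`: list with `anova` (one-row
#'   tibble: `f_statistic`, `p_value`, `df_between`, `df_within`),
#'   `pairwise` (Tukey table as a tibble), and `means`.
#' @seealso [tidy.group_comparison()], [glance.group_comparison()]
#' @export
#' @examples
#' group_compare(list(a = rnorm(10), b = rnorm(10, 2)))
group_compare <- function(values) {
  if (!is.data.frame(values)) {
    values <- purrr::imap_dfr(values,
                              ~ tibble(label = .y, value = as.numeric(.x)))
  }
  values <- filter(values, !is.na(.data$value))
  sizes <- dplyr::count(values, .data$label)
  if (nrow(sizes) < 2) abort("group_compare needs at least two groups")
  if (any(sizes$n < 2)) {
    abort(paste0("group with fewer than two observations: ",
                 sizes$label[sizes$n < 2][1]))
  }
  values$label <- factor(values$label)
  if (dplyr::n_distinct(values$value) == 1) {
    # all-identical data: F is 0/0, undefined
    return(structure(
      list(anova = tibble(f_statistic = NA_real_, p_value = NA_real_,
                          df_between = nrow(sizes) - 1L,
                          df_within = nrow(values) - nrow(sizes)),
           pairwise = tibble(contrast = character(), diff = double(),
                             lwr = double(), upr = double(),
                             p_adj = double()),
           means = values |>
             group_by(label = as.character(.data$label)) |>
             summarise(mean = mean(.data$value), n = n(),
                       .groups = "drop")),
      class = "group_comparison"
    ))
  }
  fit <- aov(value ~ label, data = values)
  tab <- summary(fit)[[1]]
  f_stat <- tab[["F value"]][1]
  p_val <- tab[["Pr(>F)"]][1]
  if (!is.finite(f_stat)) {
    f_stat <- NA_real_
    p_val <- NA_real_
  }
  pairwise <- if (is.na(f_stat)) {
    tibble(contrast = character(), diff = double(), lwr = double(),
           upr = double(), p_adj = double())
  } else {
    tk <- TukeyHSD(fit)$label
    tibble(contrast = rownames(tk), diff = tk[, "diff"],
           lwr = tk[, "lwr"], upr = tk[, "upr"], p_adj = tk[, "p adj"])
  }
  structure(
    list(
      anova = tibble(f_statistic = f_stat, p_value = p_val,
                     df_between = tab[["Df"]][1],
                     df_within = tab[["Df"]][2]),
      pairwise = pairwise,
      means = values |>
        group_by(label = as.character(.data$label)) |>
        summarise(mean = mean(.data$value), n = n(), .groups = "drop")
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  cat("  ANOVA: F =", format(x$anova$f_statistic, digits = 4),
      "on", x$anova$df_between, "and", x$anova$df_within,
      "df, p =", format(x$anova$p_value, digits = 3), "\n")
  cat("  groups:", paste0(x$means$label, " (n=", x$means$n, ")",
                          collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a group comparison into its Tukey pairwise table
#'
#' @param x A [group_compare()] result.
#' @param ... Unused.
#' @return Tibble with one row per pairwise contrast (`contrast`, `diff`,
#'   `lwr`, `upr`, `p_adj`).
#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) x$pairwise

#' One-row model summary of a group comparison
#'
#' @inheritParams tidy.group_comparison
#' @return One-row tibble: `f_statistic`, `p_value`, `df_between`,
#'   `df_within`, `n_groups`.
#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  mutate(x$anova, n_groups = nrow(x$means))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
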