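# Expression summaries: per-copy family RPM, median expression across
# tissues, and the tissue-specificity index tau.

#' Tissue-specificity index tau
#'
#' tau = sum_i (1 - x_i / x_max) / (n - 1) over per-tissue expression values
#' x_i. 0 means constitutive expression, 1 single-tissue expression. Missing
#' (NA) when all values are zero.
#'
#' @param x Numeric vector of per-tissue expression values (n >= 2,
#'   non-negative, replicates already collapsed to per-tissue means).
#' @return tau in \[0, 1\], or NA for an all-zero vector.
#' @export
tau <- function(x) {
  if (length(x) < 2) abort("tau requires at least 2 tissues")
  if (anyNA(x)) abort("tau input must not contain NA")
  if (any(x < 0)) abort("expression values must be non-negative")
  xmax <- max(x)
  if (xmax == 0) {
    return(NA_real_)
  }
  sum(1 - x / xmax) / (length(x) - 1)
}

#' Per-copy family expression in reads per million
#'
#' Counts are normalised to reads per million per replicate
#' (count / library_size * 1e6), averaged over replicates within each
#' tissue, and divided by family size to give a per-copy metric. Copies
#' located inside genes are excluded before family totals: the divisor is
#' the number of non-genic copies, and families whose copies are all genic
#' are dropped from the output.
#'
#' @param counts Tibble `family_id`, `tissue`, `replicate`, `count`.
#' @param library_sizes Tibble `tissue`, `replicate`, `library_size` (> 0).
#' @param family_sizes Tibble `family_id`, `n_copies`, or a copies tibble
#'   with `copy_id`, `family_id` and (optionally) a logical `genic` column.
#' @return Tibble `family_id`, `tissue`, `family_rpm`, `per_copy_rpm`.
#' @export
per_copy_family_rpm <- function(counts, library_sizes, family_sizes) {
  if (any(library_sizes$library_size <= 0)) abort("library sizes must be positive")
  if ("copy_id" %in% names(family_sizes)) {
    cp <- family_sizes
    if (!"genic" %in% names(cp)) cp$genic <- FALSE
    family_sizes <- cp %>%
      group_by(.data$family_id) %>%
      summarise(n_copies = sum(!.data$genic), .groups = "drop")
  }
  if (any(family_sizes$n_copies == 0 &
          family_sizes$family_id %in% counts$family_id)) {
    dropped <- family_sizes$family_id[family_sizes$n_copies == 0]
    warn(paste0(
      length(dropped), " family(ies) with only genic copies excluded: ",
      paste(head(dropped, 5), collapse = ", ")
    ))
  }
  fam <- family_sizes %>% filter(.data$n_copies > 0)
  if (nrow(fam) == 0) abort("no family with a positive non-genic copy number")
  counts %>%
    inner_join(fam, by = "family_id") %>%
    inner_join(library_sizes, by = c("tissue", "replicate")) %>%
    mutate(rpm = .data$count / .data$library_size * 1e6) %>%
    group_by(.data$family_id, .data$tissue, .data$n_copies) %>%
    summarise(family_rpm = mean(.data$rpm), .groups = "drop") %>%
    mutate(per_copy_rpm = .data$family_rpm / .data$n_copies) %>%
    select("family_id", "tissue", "family_rpm", "per_copy_rpm")
}

#' Median expression and tissue specificity per entity
#'
#' One summary row per entity (TE family or gene) from a long per-tissue
#' expression table: median across tissues and [tau()]. Genes and TE
#' families run through the identical code path; any non-negative
#' normalised unit (RPM, RPKM) is accepted.
#'
#' @param values Long tibble `entity_id`, `tissue`, `value`.
#' @return Tibble `entity_id`, `median_expr`, `tau`.
#' @export
summarize_expression <- function(values) {
  values %>%
    group_by(entity_id = .data$entity_id) %>%
    summarise(
      median_expr = median(.data$value),
      tau = tau(.data$value),
      .groups = "drop"
    )
}
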