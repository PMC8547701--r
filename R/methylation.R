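# Methylation profiling: 100 bp window summaries per context and tissue,
# per-copy body means and 20-window flanking profiles, family-mean
# imputation.

METH_CONTEXTS <- c("CG", "CHG", "CHH")

#' Summarise per-cytosine methylation calls into fixed 100 bp windows
#'
#' Aggregates per-cytosine records into genome-anchored windows (window
#' start = floor(pos / window_bp) * window_bp) per context and tissue. The
#' window fraction is missing when the window contains no covered cytosine.
#'
#' @param calls Tibble with `chrom`, `pos` (0-based), `context`, `tissue`,
#'   and either a logical/0-1 `methylated` column (one row per cytosine) or
#'   count columns `methylated_c`, `total_c`.
#' @param window_bp Window width (default 100).
#' @return Tibble `chrom`, `start`, `end`, `context`, `tissue`,
#'   `methylated_c`, `total_c`, `fraction`.
#' @export
window_summarize <- function(calls, window_bp = 100) {
  bad <- setdiff(unique(calls$context), METH_CONTEXTS)
  if (length(bad) > 0) {
    abort(paste0("unknown methylation context(s): ", paste(bad, collapse = ", ")))
  }
  if (!"methylated_c" %in% names(calls)) {
    calls <- calls %>% mutate(methylated_c = as.numeric(.data$methylated), total_c = 1)
  }
  calls %>%
    mutate(start = floor(.data$pos / window_bp) * window_bp) %>%
    group_by(.data$chrom, .data$start, .data$context, .data$tissue) %>%
    summarise(
      methylated_c = sum(.data$methylated_c),
      total_c = sum(.data$total_c),
      .groups = "drop"
    ) %>%
    mutate(
      end = .data$start + window_bp,
      fraction = ifelse(.data$total_c > 0, .data$methylated_c / .data$total_c, NA_real_)
    ) %>%
    select("chrom", "start", "end", "context", "tissue",
           "methylated_c", "total_c", "fraction")
}

# window slots of one copy: body windows (those overlapping owned segments)
# and 20 genome-anchored 100 bp bins walking outward from the bin boundary
# at each span edge.
copy_window_slots <- function(copy, segments_copy, window_bp = 100, n_flank = 20) {
  up_anchor <- floor(copy$start / window_bp)
  dn_anchor <- ceiling(copy$end / window_bp)
  tibble(
    slot = c(-(1:n_flank), seq_len(n_flank)),
    start = c((up_anchor - 1:n_flank) * window_bp,
              (dn_anchor + 0:(n_flank - 1)) * window_bp)
  ) %>%
    mutate(end = .data$start + window_bp)
}

#' Methylation profile of resolved TE copies
#'
#' For every non-dropped copy, tissue and context: the TE body mean
#' (cytosine-count-weighted mean over windows overlapping the copy's owned
#' segments) and 20 flanking 100 bp window fractions on each side, ordered
#' by distance from the TE span edge (slots -20..-1 upstream, 0 = body,
#' 1..20 downstream). Flank windows are genome-anchored bins walking outward
#' from the bin boundary at each span edge; they are clipped only at
#' chromosome ends and may overlap neighbouring TEs.
#'
#' @param resolved A `resolved_annotation`.
#' @param windows Window table from [window_summarize()] (or pre-binned
#'   input of the same shape).
#' @param chrom_lengths Optional named vector; windows beyond chromosome
#'   ends are missing.
#' @param weighted Weight body windows by their covered-cytosine counts
#'   (default TRUE); FALSE gives each overlapping window equal weight.
#' @param window_bp,n_flank Window width and flank window count.
#' @return Long tibble `copy_id`, `tissue`, `context`, `slot` (-20..20),
#'   `value`, `imputed` (all FALSE here; see [impute_missing()]).
#' @export
te_methylation_profile <- function(resolved, windows, chrom_lengths = NULL,
                                   weighted = TRUE, window_bp = 100,
                                   n_flank = 20) {
  stopifnot(inherits(resolved, "resolved_annotation"))
  kept <- resolved$copies %>% filter(!.data$dropped)
  combos <- windows %>% distinct(.data$tissue, .data$context)
  segs <- split(resolved$segments, resolved$segments$copy_id)

  win_by_chrom <- split(windows, windows$chrom)
  rows <- vector("list", nrow(kept))
  for (i in seq_len(nrow(kept))) {
    cp <- kept[i, ]
    w <- win_by_chrom[[cp$chrom]]
    sg <- segs[[cp$copy_id]]
    # body: windows overlapping any owned segment
    if (!is.null(w) && nrow(sg) > 0) {
      hit <- rep(FALSE, nrow(w))
      for (k in seq_len(nrow(sg))) {
        hit <- hit | (w$start < sg$seg_end[k] & w$end > sg$seg_start[k])
      }
      wb <- w[hit, , drop = FALSE]
    } else {
      wb <- windows[0, ]
    }
    body <- wb %>%
      group_by(.data$tissue, .data$context) %>%
      summarise(
        value = if (weighted) {
          if (sum(.data$total_c) > 0) {
            sum(.data$methylated_c) / sum(.data$total_c)
          } else {
            NA_real_
          }
        } else {
          mean(.data$fraction, na.rm = TRUE)
        },
        .groups = "drop"
      ) %>%
      mutate(slot = 0L)
    slots <- copy_window_slots(cp, sg, window_bp, n_flank)
    max_len <- if (!is.null(chrom_lengths)) chrom_lengths[[cp$chrom]] else Inf
    slots <- slots %>%
      mutate(valid = .data$start >= 0 & .data$end <= max_len)
    fl <- tidyr::crossing(combos, slots) %>%
      left_join(
        if (is.null(w)) windows[0, ] else w,
        by = c("tissue", "context", "start", "end")
      ) %>%
      mutate(value = ifelse(.data$valid, .data$fraction, NA_real_)) %>%
      select("tissue", "context", "slot", "value")
    all_slots <- tidyr::crossing(combos, tibble(slot = c(-(1:n_flank), 0L, seq_len(n_flank)))) %>%
      left_join(bind_rows(body[, c("tissue", "context", "slot", "value")], fl),
        by = c("tissue", "context", "slot")
      )
    rows[[i]] <- all_slots %>% mutate(copy_id = cp$copy_id)
  }
  bind_rows(rows) %>%
    mutate(value = ifelse(is.nan(.data$value), NA_real_, .data$value),
           imputed = FALSE) %>%
    select("copy_id", "tissue", "context", "slot", "value", "imputed")
}

#' Impute missing profile values with the family mean
#'
#' Each missing (copy, tissue, context, slot) cell is replaced by the mean
#' over non-missing values of the same family at that slot; when the whole
#' family is missing, the superfamily mean; then the global (tissue,
#' context, slot) mean. Non-missing cells are never touched.
#'
#' @param profiles Long profile tibble from [te_methylation_profile()].
#' @param copies Tibble with `copy_id`, `family_id`, `superfamily`.
#' @return `profiles` with missing `value`s filled and `imputed` flags set.
#' @export
impute_missing <- function(profiles, copies) {
  df <- profiles %>%
    left_join(copies[, c("copy_id", "family_id", "superfamily")], by = "copy_id")
  df <- df %>%
    group_by(.data$family_id, .data$tissue, .data$context, .data$slot) %>%
    mutate(fam_mean = mean(.data$value, na.rm = TRUE)) %>%
    group_by(.data$superfamily, .data$tissue, .data$context, .data$slot) %>%
    mutate(sf_mean = mean(.data$value, na.rm = TRUE)) %>%
    group_by(.data$tissue, .data$context, .data$slot) %>%
    mutate(gl_mean = mean(.data$value, na.rm = TRUE)) %>%
    ungroup()
  # NaN group means (all-missing groups) fall through to the next level
  fam <- ifelse(is.nan(df$fam_mean), NA_real_, df$fam_mean)
  sf <- ifelse(is.nan(df$sf_mean), NA_real_, df$sf_mean)
  gl <- ifelse(is.nan(df$gl_mean), NA_real_, df$gl_mean)
  fill <- dplyr::coalesce(fam, sf, gl)
  missing <- is.na(df$value)
  df$value[missing] <- fill[missing]
  df$imputed <- missing & !is.na(df$value)
  df %>% select("copy_id", "tissue", "context", "slot", "value", "imputed")
}

#' Wide per-copy methylation feature columns
#'
#' Spreads a (possibly imputed) profile into one numeric column per
#' (context, tissue, slot), named `mCG_anther_body`, `mCHH_SAM_up05`,
#' `mCG_earshoot_dn12`, ...
#'
#' @param profiles Long profile tibble.
#' @return Tibble keyed by `copy_id`.
#' @export
methylation_feature_table <- function(profiles) {
  profiles %>%
    mutate(
      slot_name = dplyr::case_when(
        .data$slot == 0 ~ "body",
        .data$slot < 0 ~ paste0("up", str_pad(-.data$slot, 2, pad = "0")),
        TRUE ~ paste0("dn", str_pad(.data$slot, 2, pad = "0"))
      ),
      feature = paste0("m", .data$context, "_", .data$tissue, "_", .data$slot_name)
    ) %>%
    select("copy_id", "feature", "value") %>%
    pivot_wider(names_from = "feature", values_from = "value")
}
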