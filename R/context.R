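# Genomic-neighborhood features: nearest (syntenic) gene, recombination
# rate from a genetic map, MNase hypersensitivity, segregating-site density,
# subgenome assignment. All intervals 0-based half-open; distances use the
# half-open gap convention (adjacent intervals are at distance 0).

#' Distance to the closest gene and closest syntenic gene
#'
#' For each TE, the bp gap to the closest gene irrespective of strand (0 on
#' any overlap), whether the TE intersects a transcript span (introns and
#' UTRs included), and the same restricted to syntenic genes. Equidistant
#' genes are broken leftmost-first, then by lexicographic gene id.
#'
#' @param tes Tibble with `copy_id`, `chrom`, `start`, `end`.
#' @param genes Tibble with `gene_id`, `chrom`, `start`, `end`.
#' @param syntenic_ids Character vector of syntenic gene ids (optional).
#' @return Tibble `copy_id`, `dist_gene`, `closest_gene_id`,
#'   `within_transcript`, and when `syntenic_ids` is given
#'   `dist_syntenic_gene`, `closest_syntenic_gene_id`. Distances are NA on
#'   chromosomes with no (syntenic) gene.
#' @export
nearest_gene_features <- function(tes, genes, syntenic_ids = NULL) {
  nearest_one <- function(genes) {
    function(chrom, start, end) {
      g <- genes[genes$chrom == chrom, , drop = FALSE]
      if (nrow(g) == 0) {
        return(list(dist = NA_real_, id = NA_character_))
      }
      d <- pmax(0, pmax(g$start - end, start - g$end))
      i <- which(d == min(d))
      if (length(i) > 1) {
        i <- i[order(g$start[i], g$gene_id[i])][1]
      }
      list(dist = d[i], id = g$gene_id[i])
    }
  }
  f_all <- nearest_one(genes)
  res <- pmap(list(tes$chrom, tes$start, tes$end), f_all)
  out <- tibble(
    copy_id = tes$copy_id,
    dist_gene = map_dbl(res, "dist"),
    closest_gene_id = map_chr(res, "id"),
    within_transcript = map_dbl(res, "dist") == 0 & !is.na(map_dbl(res, "dist"))
  )
  if (!is.null(syntenic_ids)) {
    syn <- genes[genes$gene_id %in% syntenic_ids, , drop = FALSE]
    f_syn <- nearest_one(syn)
    res_s <- pmap(list(tes$chrom, tes$start, tes$end), f_syn)
    out$dist_syntenic_gene <- map_dbl(res_s, "dist")
    out$closest_syntenic_gene_id <- map_chr(res_s, "id")
  }
  out
}

#' Fit a monotone map function to genetic-map points
#'
#' Fits a least-squares polynomial of the given degree to (bp, cM) points of
#' one chromosome (orthogonal basis on scaled positions), evaluates it on a
#' dense grid, and projects the grid values to the nearest non-decreasing
#' sequence (isotonic regression). The returned function interpolates that
#' monotone grid linearly and clamps to the boundary cM values outside the
#' fitted range, so it is non-decreasing everywhere by construction. With
#' fewer than `degree + 1` points it falls back to monotone piecewise-linear
#' interpolation of the points themselves, with a warning.
#'
#' @param points Tibble with `pos` (bp) and `cM` for a single chromosome.
#' @param degree Polynomial degree (default 7).
#' @param n_grid Number of grid points for the monotone projection
#'   (default 2001).
#' @return Object of class `monotone_map`: list with `fn` (vectorised
#'   bp -> cM), `range` (fitted bp range), `residuals` (at the input points)
#'   and `method` ("polynomial" or "piecewise_linear").
#' @export
fit_monotonic_map <- function(points, degree = 7, n_grid = 2001) {
  stopifnot(all(c("pos", "cM") %in% names(points)))
  points <- points %>%
    distinct(.data$pos, .keep_all = TRUE) %>%
    arrange(.data$pos)
  if (nrow(points) < 2) abort("need at least 2 map points")
  rng <- range(points$pos)
  if (nrow(points) < degree + 1) {
    warn("too few map points for polynomial fit; using monotone piecewise-linear interpolation")
    iso <- isoreg(points$pos, points$cM)
    fn <- approxfun(points$pos, iso$yf, rule = 2)
    return(structure(
      list(fn = fn, range = rng,
           residuals = iso$yf - points$cM, method = "piecewise_linear"),
      class = "monotone_map"
    ))
  }
  # scale positions for numerical conditioning
  xs <- (points$pos - rng[1]) / (rng[2] - rng[1])
  fit <- lm(cM ~ poly(xs, degree = degree), data = tibble(cM = points$cM, xs = xs))
  grid_x <- seq(0, 1, length.out = n_grid)
  grid_y <- predict(fit, newdata = tibble(xs = grid_x))
  mono_y <- isoreg(grid_x, grid_y)$yf
  grid_pos <- rng[1] + grid_x * (rng[2] - rng[1])
  fn <- approxfun(grid_pos, mono_y, rule = 2)
  structure(
    list(fn = fn, range = rng, residuals = fn(points$pos) - points$cM,
         method = "polynomial"),
    class = "monotone_map"
  )
}

#' @export
print.monotone_map <- function(x, ...) {
  cat("<monotone_map> ", x$method, " fit over [",
      format(x$range[1], big.mark = ","), ", ",
      format(x$range[2], big.mark = ","), "] bp; RMS residual ",
      signif(sqrt(mean(x$residuals^2)), 3), " cM\n", sep = "")
  invisible(x)
}

#' Fit monotone maps for every chromosome of a genetic map
#'
#' @param map Tibble with `chrom`, `pos`, `cM`.
#' @param degree Polynomial degree (default 7).
#' @return Named list of `monotone_map` objects, one per chromosome.
#' @export
fit_genetic_map <- function(map, degree = 7) {
  map %>%
    group_by(.data$chrom) %>%
    group_map(~ fit_monotonic_map(.x, degree = degree)) %>%
    setNames(sort(unique(map$chrom)))
}

#' Recombination rate across a TE
#'
#' cM spanned by the TE divided by its length in megabases:
#' (f(end) - f(start)) / ((end - start) / 1e6). Values are flagged
#' `extrapolated` when the interval falls outside the fitted map range
#' (where the map is clamped).
#'
#' @param map_fn A `monotone_map`.
#' @param start,end TE interval (0-based half-open), vectorised.
#' @return Tibble `cm_mb`, `extrapolated`.
#' @export
te_recombination_rate <- function(map_fn, start, end) {
  stopifnot(inherits(map_fn, "monotone_map"))
  if (any(end - start < 1)) abort("TE length must be at least 1 bp")
  cm <- map_fn$fn(end) - map_fn$fn(start)
  tibble(
    cm_mb = cm / ((end - start) / 1e6),
    extrapolated = start < map_fn$range[1] | end > map_fn$range[2]
  )
}

#' Chromatin-accessibility features of a region
#'
#' Counts MNase hypersensitive intervals intersecting a region and the
#' proportion of region bases they cover.
#'
#' @param region Tibble `chrom`, `start`, `end` (one or more regions).
#' @param hs Tibble of hypersensitive intervals `chrom`, `start`, `end`.
#' @return Tibble `mnase_count`, `mnase_prop` aligned to `region` rows.
#' @export
mnase_features <- function(region, hs) {
  res <- pmap(list(region$chrom, region$start, region$end), function(ch, s, e) {
    h <- hs[hs$chrom == ch, , drop = FALSE]
    if (nrow(h) == 0) {
      return(c(0, 0))
    }
    ov <- overlap_bp(s, e, h$start, h$end)
    # covered bases use the union of (possibly overlapping) intervals
    merged <- IRanges::reduce(IRanges::IRanges(h$start + 1L, h$end))
    cov <- overlap_bp(s, e, IRanges::start(merged) - 1L, IRanges::end(merged))
    c(sum(ov > 0), sum(cov) / (e - s))
  })
  tibble(
    mnase_count = vapply(res, `[`, numeric(1), 1),
    mnase_prop = vapply(res, `[`, numeric(1), 2)
  )
}

#' Segregating-site density of a region
#'
#' Number of variant positions inside the region divided by region length.
#'
#' @param region Tibble `chrom`, `start`, `end`.
#' @param variants Tibble `chrom`, `pos` (0-based positions).
#' @return Numeric vector of sites per bp, aligned to `region` rows.
#' @export
segregating_site_density <- function(region, variants) {
  vapply(seq_len(nrow(region)), function(i) {
    v <- variants$pos[variants$chrom == region$chrom[i]]
    sum(v >= region$start[i] & v < region$end[i]) / (region$end[i] - region$start[i])
  }, numeric(1))
}

#' Subgenome assignment by maximal overlap
#'
#' Assigns each region to the subgenome block set ("A" or "B") covering the
#' most of its bases; ties and zero overlap give "none".
#'
#' @param region Tibble `chrom`, `start`, `end`.
#' @param subgenomes Tibble `chrom`, `start`, `end`, `subgenome` with
#'   non-overlapping intervals.
#' @return Character vector in \{"A", "B", "none"\}.
#' @export
subgenome_assign <- function(region, subgenomes) {
  vapply(seq_len(nrow(region)), function(i) {
    sg <- subgenomes[subgenomes$chrom == region$chrom[i], , drop = FALSE]
    if (nrow(sg) == 0) {
      return("none")
    }
    ov <- overlap_bp(region$start[i], region$end[i], sg$start, sg$end)
    tot <- tapply(ov, sg$subgenome, sum)
    tot <- tot[tot > 0]
    if (length(tot) == 0) {
      return("none")
    }
    best <- names(tot)[tot == max(tot)]
    if (length(best) > 1) "none" else best
  }, character(1))
}

#' Assemble all context features for resolved TE copies
#'
#' Convenience wrapper computing, for every non-dropped copy: nearest-gene
#' features, recombination rate, MNase features for the TE and its pooled
#' 1 kb flanks per tissue, segregating-site densities and subgenome.
#'
#' @param resolved A `resolved_annotation`.
#' @param genes Gene tibble (`gene_id`, `chrom`, `start`, `end`).
#' @param syntenic_ids Character vector of syntenic gene ids.
#' @param genetic_map Tibble `chrom`, `pos`, `cM`.
#' @param mnase Named list (by tissue) of interval tibbles.
#' @param variants Tibble `chrom`, `pos`.
#' @param subgenomes Subgenome interval tibble.
#' @param flank_bp Flank width for MNase/segregating-site flank metrics
#'   (default 1000).
#' @param chrom_lengths Named vector of chromosome lengths (for flank
#'   clipping).
#' @return Tibble keyed by `copy_id`.
#' @export
context_features <- function(resolved, genes, syntenic_ids = NULL,
                             genetic_map = NULL, mnase = NULL,
                             variants = NULL, subgenomes = NULL,
                             flank_bp = 1000, chrom_lengths = NULL) {
  stopifnot(inherits(resolved, "resolved_annotation"))
  kept <- resolved$copies %>% filter(!.data$dropped)
  region <- kept %>% select("copy_id", "chrom", "start", "end")
  out <- nearest_gene_features(region, genes, syntenic_ids)

  # pooled flanks, clipped at chromosome ends when lengths are known
  clip <- function(x, ch) {
    if (is.null(chrom_lengths)) x else pmin(x, chrom_lengths[ch])
  }
  fl <- bind_rows(
    region %>% mutate(start = pmax(0, .data$start - flank_bp), end = region$start),
    region %>% mutate(start = region$end, end = clip(.data$end + flank_bp, .data$chrom))
  ) %>% filter(.data$end > .data$start)

  if (!is.null(genetic_map)) {
    maps <- fit_genetic_map(genetic_map)
    rr <- map_dbl(seq_len(nrow(region)), function(i) {
      m <- maps[[region$chrom[i]]]
      if (is.null(m)) return(NA_real_)
      te_recombination_rate(m, region$start[i], region$end[i])$cm_mb
    })
    out$cm_mb <- rr
  }
  if (!is.null(mnase)) {
    for (tissue in names(mnase)) {
      mte <- mnase_features(region, mnase[[tissue]])
      out[[paste0("mnase_count_te_", tissue)]] <- mte$mnase_count
      out[[paste0("mnase_prop_te_", tissue)]] <- mte$mnase_prop
      mfl <- mnase_features(fl, mnase[[tissue]])
      agg <- tibble(copy_id = fl$copy_id, n = mfl$mnase_count,
                    bp = (fl$end - fl$start) * mfl$mnase_prop,
                    w = fl$end - fl$start) %>%
        group_by(.data$copy_id) %>%
        summarise(count = sum(.data$n), prop = sum(.data$bp) / sum(.data$w),
                  .groups = "drop")
      j <- match(region$copy_id, agg$copy_id)
      out[[paste0("mnase_count_flank_", tissue)]] <- agg$count[j]
      out[[paste0("mnase_prop_flank_", tissue)]] <- agg$prop[j]
    }
  }
  if (!is.null(variants)) {
    out$segsites_per_bp_te <- segregating_site_density(region, variants)
    fl_d <- segregating_site_density(fl, variants)
    agg <- tibble(copy_id = fl$copy_id,
                  n = fl_d * (fl$end - fl$start), w = fl$end - fl$start) %>%
      group_by(.data$copy_id) %>%
      summarise(d = sum(.data$n) / sum(.data$w), .groups = "drop")
    out$segsites_per_bp_flank <- agg$d[match(region$copy_id, agg$copy_id)]
  }
  if (!is.null(subgenomes)) {
    out$subgenome <- subgenome_assign(region, subgenomes)
  }
  out
}
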