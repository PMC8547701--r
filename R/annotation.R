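#' Superfamily taxonomy of transposable elements
#'
#' The 13 three-letter Wicker superfamily codes used throughout the package,
#' with their order and class. `DT*` codes are terminal-inverted-repeat (TIR)
#' DNA transposons, `DHH` are Helitrons, `RL*` are LTR retrotransposons, and
#' `RI*`/`RST` are nonLTR retroelements (LINEs and SINEs).
#'
#' @return A tibble with columns `superfamily`, `order`, `te_class` and
#'   `common_name`.
#' @export
te_superfamilies <- function() {
  tribble(
    ~superfamily, ~order,     ~te_class, ~common_name,
    "DHH",        "Helitron", "II",      "Helitron",
    "DTA",        "TIR",      "II",      "hAT",
    "DTC",        "TIR",      "II",      "CACTA",
    "DTH",        "TIR",      "II",      "Pif/Harbinger",
    "DTM",        "TIR",      "II",      "Mutator",
    "DTT",        "TIR",      "II",      "Tc1/Mariner",
    "DTX",        "TIR",      "II",      "Unknown TIR",
    "RLC",        "LTR",      "I",       "Ty1/Copia",
    "RLG",        "LTR",      "I",       "Ty3/Gypsy",
    "RLX",        "LTR",      "I",       "Unknown LTR",
    "RIL",        "nonLTR",   "I",       "L1",
    "RIT",        "nonLTR",   "I",       "RTE",
    "RST",        "nonLTR",   "I",       "SINE"
  )
}

validate_te_copies <- function(copies) {
  tax <- te_superfamilies()
  bad_sf <- setdiff(unique(copies$superfamily), tax$superfamily)
  if (length(bad_sf) > 0) {
    abort(paste0("unknown superfamily code(s): ", paste(bad_sf, collapse = ", ")))
  }
  prefix <- str_sub(copies$family_id, 1, 3)
  mism <- which(prefix != copies$superfamily)
  if (length(mism) > 0) {
    abort(paste0(
      "family_id prefix does not match superfamily for copy ",
      copies$copy_id[mism[1]], " (family ", copies$family_id[mism[1]],
      ", superfamily ", copies$superfamily[mism[1]], ")"
    ))
  }
  if (any(copies$start >= copies$end)) {
    abort("all TE intervals must satisfy start < end")
  }
  invisible(copies)
}

#' Read a TE annotation from GFF3
#'
#' Parses a GFF3 file whose records carry `ID`, `family` and `superfamily`
#' attributes (and optionally `parent_te` for nested insertions), validates
#' the taxonomy against [te_superfamilies()], and returns one row per copy
#' with 0-based half-open coordinates.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble of TE copies: `copy_id`, `family_id`, `superfamily`,
#'   `order`, `te_class`, `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, `parent_te`, ordered by (chrom, start, copy_id).
#' @export
read_te_gff <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  need <- c("ID", "family", "superfamily")
  for (attr in need) {
    if (is.null(mc[[attr]]) || anyNA(mc[[attr]])) {
      bad <- if (is.null(mc[[attr]])) seq_along(gr) else which(is.na(mc[[attr]]))
      abort(paste0(
        "GFF3 record ", bad[1], " is missing required attribute '", attr, "'"
      ))
    }
  }
  copies <- tibble(
    copy_id = as.character(mc$ID),
    family_id = as.character(mc$family),
    superfamily = as.character(mc$superfamily),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    parent_te = if (is.null(mc$parent_te)) NA_character_ else as.character(mc$parent_te),
    longest_orf_aa = if (is.null(mc$longest_orf_aa)) NA_integer_ else
      suppressWarnings(as.integer(mc$longest_orf_aa))
  )
  copies$strand[copies$strand == "*"] <- "."
  validate_te_copies(copies)
  copies %>%
    left_join(te_superfamilies()[, c("superfamily", "order", "te_class")],
      by = "superfamily"
    ) %>%
    arrange(.data$chrom, .data$start, .data$copy_id) %>%
    select(
      "copy_id", "family_id", "superfamily", "order", "te_class",
      "chrom", "start", "end", "strand", "parent_te", "longest_orf_aa"
    )
}

#' Write a TE annotation to GFF3
#'
#' Inverse of [read_te_gff()]: takes the package's 0-based half-open copy
#' table and writes 1-based inclusive GFF3 with `ID`, `family`,
#' `superfamily` and `parent_te` attributes.
#'
#' @param copies Tibble of TE copies as returned by [read_te_gff()].
#' @param path Output path.
#' @export
write_te_gff <- function(copies, path) {
  gr <- as_granges0(copies)
  GenomicRanges::strand(gr) <- ifelse(copies$strand == ".", "*", copies$strand)
  S4Vectors::mcols(gr)$source <- "teecology"
  S4Vectors::mcols(gr)$type <- "transposable_element"
  S4Vectors::mcols(gr)$ID <- copies$copy_id
  S4Vectors::mcols(gr)$family <- copies$family_id
  S4Vectors::mcols(gr)$superfamily <- copies$superfamily
  if (!is.null(copies$parent_te)) S4Vectors::mcols(gr)$parent_te <- copies$parent_te
  if (!is.null(copies$longest_orf_aa)) {
    S4Vectors::mcols(gr)$longest_orf_aa <- copies$longest_orf_aa
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# containment map: for each copy, the indices of other copies strictly
# contained in it. Partial overlaps (neither containment nor disjoint) and
# duplicated intervals are annotation errors.
containment_hits <- function(copies) {
  gr <- as_granges0(copies)
  hits <- GenomicRanges::findOverlaps(gr, gr)
  h <- as_tibble(as.data.frame(hits))
  h <- h[h$queryHits != h$subjectHits, , drop = FALSE]
  if (nrow(h) == 0) {
    return(list(within = h[0, ], partial = h[0, ]))
  }
  qs <- copies$start[h$queryHits]; qe <- copies$end[h$queryHits]
  ss <- copies$start[h$subjectHits]; se <- copies$end[h$subjectHits]
  contained <- qs >= ss & qe <= se & !(qs == ss & qe == se)
  identical_iv <- qs == ss & qe == se
  partial <- !contained & !identical_iv &
    !(qs >= ss & qe <= se) & !(ss >= qs & se <= qe)
  if (any(identical_iv)) {
    i <- which(identical_iv)[1]
    abort(paste0(
      "copies ", copies$copy_id[h$queryHits[i]], " and ",
      copies$copy_id[h$subjectHits[i]],
      " have identical intervals; arrival order is undefined"
    ))
  }
  list(
    within = h[contained, , drop = FALSE],   # queryHits contained in subjectHits
    partial = h[partial, , drop = FALSE]
  )
}

#' Resolve nested TE insertions base-pair-exactly
#'
#' Assigns every annotated base to exactly one TE copy: the latest-arriving
#' copy covering it. Arrival order is taken from nesting topology -- a copy
#' contained inside another arrived after it -- so each copy's owned sequence
#' is its interval minus everything inserted into it. Copies left with fewer
#' than `min_surviving_bp` owned bases are flagged `dropped` and excluded
#' from downstream feature tables (they remain in the segment accounting).
#'
#' @param copies Tibble of TE copies (see [read_te_gff()]). Any two copies
#'   must be disjoint or strictly nested; partial overlaps are errors.
#' @param min_surviving_bp Minimum owned bases for a copy to be retained
#'   (default 50).
#' @return An object of class `resolved_annotation`: a list with
#'   \describe{
#'     \item{segments}{tibble `copy_id`, `chrom`, `seg_start`, `seg_end`
#'       (0-based half-open), pairwise disjoint across all copies}
#'     \item{copies}{the input copies plus `surviving_bp`, `span_bp`,
#'       `n_segments`, `disrupted`, `within_te`, `nesting_depth`, `dropped`}
#'   }
#' @export
resolve_nesting <- function(copies, min_surviving_bp = 50) {
  stopifnot(is.data.frame(copies), nrow(copies) > 0)
  validate_te_copies(copies)
  if (anyDuplicated(copies$copy_id)) abort("duplicate copy_id in annotation")
  ord <- order(copies$chrom, copies$start, copies$copy_id)
  copies <- copies[ord, , drop = FALSE]

  cont <- containment_hits(copies)
  if (nrow(cont$partial) > 0) {
    i <- cont$partial[1, ]
    abort(paste0(
      "copies ", copies$copy_id[i$queryHits], " and ",
      copies$copy_id[i$subjectHits],
      " overlap without containment; cannot order arrivals"
    ))
  }

  # explicit parent links, when present, must agree with containment
  if ("parent_te" %in% names(copies) && any(!is.na(copies$parent_te))) {
    idx <- match(copies$parent_te, copies$copy_id)
    linked <- which(!is.na(copies$parent_te))
    if (anyNA(idx[linked])) {
      abort(paste0(
        "parent_te of ", copies$copy_id[linked[which(is.na(idx[linked]))[1]]],
        " is not an annotated copy"
      ))
    }
    bad <- linked[copies$start[linked] < copies$start[idx[linked]] |
      copies$end[linked] > copies$end[idx[linked]] |
      linked == idx[linked]]
    if (length(bad) > 0) {
      abort(paste0(
        "copy ", copies$copy_id[bad[1]],
        " is not contained in its declared parent ", copies$parent_te[bad[1]]
      ))
    }
    # cycle check over declared links
    for (s in linked) {
      seen <- integer(); cur <- s
      while (!is.na(cur)) {
        if (cur %in% seen) abort("cyclic parent_te links detected")
        seen <- c(seen, cur)
        cur <- idx[cur]
      }
    }
  }

  n <- nrow(copies)
  children <- vector("list", n)
  depth <- integer(n) # number of copies this one is contained in
  if (nrow(cont$within) > 0) {
    children <- split(cont$within$queryHits, factor(cont$within$subjectHits, levels = seq_len(n)))
    depth <- tabulate(cont$within$queryHits, nbins = n)
  }

  seg_list <- vector("list", n)
  for (i in seq_len(n)) {
    own <- IRanges::IRanges(start = copies$start[i] + 1L, end = copies$end[i])
    kids <- children[[i]]
    if (length(kids) > 0) {
      kid_rng <- IRanges::reduce(IRanges::IRanges(
        start = copies$start[kids] + 1L, end = copies$end[kids]
      ))
      own <- IRanges::setdiff(own, kid_rng)
    }
    if (length(own) > 0) {
      seg_list[[i]] <- tibble(
        copy_id = copies$copy_id[i],
        chrom = copies$chrom[i],
        seg_start = IRanges::start(own) - 1L,
        seg_end = IRanges::end(own)
      )
    }
  }
  segments <- bind_rows(seg_list)

  per_copy <- segments %>%
    group_by(.data$copy_id) %>%
    summarise(
      surviving_bp = sum(.data$seg_end - .data$seg_start),
      n_segments = dplyr::n(),
      .groups = "drop"
    )
  out <- copies %>%
    left_join(per_copy, by = "copy_id") %>%
    mutate(
      surviving_bp = dplyr::coalesce(.data$surviving_bp, 0L),
      n_segments = dplyr::coalesce(.data$n_segments, 0L),
      span_bp = .data$end - .data$start,
      disrupted = .data$n_segments >= 2L,
      within_te = depth > 0L,
      nesting_depth = depth,
      dropped = .data$surviving_bp < min_surviving_bp
    )
  structure(
    list(segments = segments, copies = out,
         min_surviving_bp = min_surviving_bp),
    class = "resolved_annotation"
  )
}

#' @export
print.resolved_annotation <- function(x, ...) {
  cat("<resolved_annotation>\n")
  cat("  copies:   ", nrow(x$copies), " (", sum(x$copies$dropped),
      " dropped below ", x$min_surviving_bp, " bp)\n", sep = "")
  cat("  segments: ", nrow(x$segments), "\n", sep = "")
  cat("  owned bp: ", sum(x$copies$surviving_bp), "\n", sep = "")
  invisible(x)
}

#' Classify TE copies as autonomous or non-coding from protein-domain hits
#'
#' Applies superfamily-specific rules: LTR retrotransposons are
#' `autonomous_coding` only with evidence of all five proteins (GAG, AP, RT,
#' RNaseH, INT); partial LTR copies are labelled `GAG_only` (GAG alone),
#' `POL_only` (all four non-GAG proteins, no GAG) or `other_partial`. TIR
#' elements need a transposase (TPase) hit, Helitrons a Rep/Hel hit, and
#' LINEs a reverse-transcriptase (RT) hit; SINEs are non-coding by
#' definition.
#'
#' @param copies Tibble of TE copies.
#' @param domain_hits Tibble with columns `copy_id`, `domain`; domains must
#'   come from \{GAG, AP, RT, RNaseH, INT, TPase, RepHel\}.
#' @param dropped Optional character vector of dropped copy_ids excluded
#'   from `family_has_coding_member`.
#' @return Tibble `copy_id`, `family_id`, `superfamily`, `status`
#'   (`autonomous_coding`/`partial_coding`/`noncoding`), `partial_type`,
#'   `family_has_coding_member`.
#' @export
classify_autonomy <- function(copies, domain_hits, dropped = character()) {
  vocab <- c("GAG", "AP", "RT", "RNaseH", "INT", "TPase", "RepHel")
  if (nrow(domain_hits) > 0) {
    bad <- setdiff(unique(domain_hits$domain), vocab)
    if (length(bad) > 0) {
      abort(paste0("unknown protein domain name(s): ", paste(bad, collapse = ", ")))
    }
  }
  ltr_pol <- c("AP", "RT", "RNaseH", "INT")
  dom_by_copy <- split(domain_hits$domain, domain_hits$copy_id)

  status <- character(nrow(copies))
  partial <- rep(NA_character_, nrow(copies))
  for (i in seq_len(nrow(copies))) {
    doms <- unique(dom_by_copy[[copies$copy_id[i]]] %||% character())
    ord <- copies$order[i]
    if (ord == "LTR") {
      if (all(c("GAG", ltr_pol) %in% doms)) {
        status[i] <- "autonomous_coding"
      } else if (length(intersect(doms, c("GAG", ltr_pol))) == 0) {
        status[i] <- "noncoding"
      } else {
        status[i] <- "partial_coding"
        partial[i] <- if (identical(intersect(doms, c("GAG", ltr_pol)), "GAG")) {
          "GAG_only"
        } else if (all(ltr_pol %in% doms) && !("GAG" %in% doms)) {
          "POL_only"
        } else {
          "other_partial"
        }
      }
    } else if (ord == "TIR") {
      status[i] <- if ("TPase" %in% doms) "autonomous_coding" else "noncoding"
    } else if (ord == "Helitron") {
      status[i] <- if ("RepHel" %in% doms) "autonomous_coding" else "noncoding"
    } else { # nonLTR
      status[i] <- if (copies$superfamily[i] != "RST" && "RT" %in% doms) {
        "autonomous_coding"
      } else {
        "noncoding"
      }
    }
  }
  out <- tibble(
    copy_id = copies$copy_id,
    family_id = copies$family_id,
    superfamily = copies$superfamily,
    status = status,
    partial_type = partial
  )
  fam_coding <- out %>%
    filter(!(.data$copy_id %in% dropped)) %>%
    group_by(.data$family_id) %>%
    summarise(
      family_has_coding_member = any(.data$status == "autonomous_coding"),
      .groups = "drop"
    )
  out %>%
    left_join(fam_coding, by = "family_id") %>%
    mutate(family_has_coding_member =
             dplyr::coalesce(.data$family_has_coding_member, FALSE))
}

#' Per-family age histogram in 10,000-year bins
#'
#' @param ages Tibble with `copy_id`, `family_id`, `age_years`.
#' @param bin_width Bin width in years (default 10,000).
#' @return Tibble `family_id`, `bin` (index from 0), `bin_start` (years), `n`.
#' @export
family_age_histogram <- function(ages, bin_width = 10000) {
  ages %>%
    filter(!is.na(.data$age_years)) %>%
    mutate(bin = floor(.data$age_years / bin_width)) %>%
    count(.data$family_id, .data$bin, name = "n") %>%
    mutate(bin_start = .data$bin * bin_width) %>%
    select("family_id", "bin", "bin_start", "n")
}

#' Summarise TE families
#'
#' Per-family summaries over non-dropped copies: copy number, median
#' surviving length, median age, median distance to the closest gene,
#' proportion nested/intact/coding/in subgenome A, and whether the family
#' was active in the last 100,000 years (youngest copy < 100 ky). Families
#' are flagged `reportable` when they exceed `min_copies_for_reporting`
#' copies (outlier-style reporting uses only those).
#'
#' @param resolved A `resolved_annotation` from [resolve_nesting()].
#' @param ages Tibble `copy_id`, `age_years`.
#' @param features Optional tibble with `copy_id` plus any of `dist_gene`,
#'   `subgenome`.
#' @param autonomy Optional output of [classify_autonomy()].
#' @param min_copies_for_reporting Copy-number threshold for the
#'   outlier-reporting view (default 10, strict inequality).
#' @return Tibble with one row per family.
#' @export
family_summary <- function(resolved, ages, features = NULL, autonomy = NULL,
                           min_copies_for_reporting = 10) {
  stopifnot(inherits(resolved, "resolved_annotation"))
  kept <- resolved$copies %>% filter(!.data$dropped)
  empty_fams <- setdiff(resolved$copies$family_id, kept$family_id)
  if (length(empty_fams) > 0) {
    warn(paste0(
      length(empty_fams),
      " family(ies) have no surviving copies and are omitted: ",
      paste(head(empty_fams, 5), collapse = ", ")
    ))
  }
  df <- kept %>% left_join(ages, by = "copy_id")
  if (any(is.na(df$age_years))) {
    abort("ages must be present for every non-dropped copy")
  }
  if (!is.null(features)) {
    df <- df %>% left_join(features, by = "copy_id")
  }
  if (!("dist_gene" %in% names(df))) df$dist_gene <- NA_real_
  if (!("subgenome" %in% names(df))) df$subgenome <- NA_character_
  if (!is.null(autonomy)) {
    df <- df %>% left_join(autonomy[, c("copy_id", "status")], by = "copy_id")
  } else {
    df$status <- NA_character_
  }
  df %>%
    group_by(.data$family_id, .data$superfamily, .data$order) %>%
    summarise(
      copy_number = dplyr::n(),
      median_length_bp = median(.data$surviving_bp),
      median_span_bp = median(.data$span_bp),
      median_age_years = median(.data$age_years),
      median_dist_gene = median(.data$dist_gene),
      prop_within_te = mean(.data$within_te),
      prop_intact = mean(!.data$disrupted),
      prop_coding = if (all(is.na(.data$status))) NA_real_ else
        mean(.data$status == "autonomous_coding"),
      prop_subgenome_A = if (all(is.na(.data$subgenome))) NA_real_ else
        mean(.data$subgenome == "A"),
      active_last_100ky = min(.data$age_years) < 1e5,
      .groups = "drop"
    ) %>%
    mutate(reportable = .data$copy_number > min_copies_for_reporting) %>%
    arrange(desc(.data$copy_number), .data$family_id)
}
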