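# Base-composition features: GC content, methylatable cytosine contexts
# (CG, CHG, CHH; H = A, C or T), and TG/CA dinucleotide proportion.

# Count cytosines by methylation context on ONE strand of a sequence.
# Position i is CG when followed by G; CHG when the base two ahead is G (and
# the next is H); CHH when both following bases are H. A context window
# containing N is skipped; trailing Cs without a complete context window are
# uncounted.
count_contexts_strand <- function(x) {
  n <- length(x)
  cg <- chg <- chh <- 0L
  isC <- x == "C"
  if (n >= 2) {
    nxt <- c(x[-1], "")
    nxt2 <- if (n >= 3) c(x[-(1:2)], "", "") else rep("", n)
    h <- c("A", "C", "T")
    cg <- sum(isC & nxt == "G")
    chg <- sum(isC & nxt %in% h & nxt2 == "G")
    chh <- sum(isC & nxt %in% h & nxt2 %in% h)
  }
  c(cg = cg, chg = chg, chh = chh)
}

# Raw composition counts for one sequence; contexts counted on both strands
# (forward scan of the sequence and of its reverse complement).
composition_counts <- function(seq) {
  x <- seq_chars(seq)
  n <- length(x)
  if (n == 0) abort("empty sequence")
  fwd <- count_contexts_strand(x)
  rev <- count_contexts_strand(seq_chars(revcomp(seq)))
  din <- paste0(x[-n], x[-1])
  list(
    length_bp = n,
    n_gc = sum(x %in% c("G", "C")),
    n_cg = unname(fwd["cg"] + rev["cg"]),
    n_chg = unname(fwd["chg"] + rev["chg"]),
    n_chh = unname(fwd["chh"] + rev["chh"]),
    n_tgca = if (n >= 2) sum(din %in% c("TG", "CA")) else 0L,
    n_dinuc = max(n - 1L, 0L)
  )
}

#' Base-composition features of a sequence
#'
#' GC content; density of methylatable cytosine sites in each context (CG,
#' CHG, CHH; H = A, C or T), counted on both strands and divided by sequence
#' length (so values can reach 2 -- e.g. a CG dinucleotide carries one
#' methylatable C per strand); and the proportion of overlapping
#' dinucleotides equal to TG or CA (the deamination products of methylated
#' CG). Context windows containing N are skipped.
#'
#' @param seq A nucleotide sequence (alphabet A,C,G,T,N), length >= 3.
#' @param region_id Optional identifier carried into the output.
#' @return One-row tibble: `region_id`, `length_bp`, `gc`, `p_cg`, `p_chg`,
#'   `p_chh`, `p_tgca`.
#' @export
compute_composition <- function(seq, region_id = NA_character_) {
  if (!is.character(seq) || length(seq) != 1 || nchar(seq) == 0) {
    abort("seq must be a single non-empty string")
  }
  if (nchar(seq) < 3) abort("sequence must be at least 3 bp")
  cc <- composition_counts(seq)
  tibble(
    region_id = region_id,
    length_bp = cc$length_bp,
    gc = cc$n_gc / cc$length_bp,
    p_cg = cc$n_cg / cc$length_bp,
    p_chg = cc$n_chg / cc$length_bp,
    p_chh = cc$n_chh / cc$length_bp,
    p_tgca = if (cc$n_dinuc > 0) cc$n_tgca / cc$n_dinuc else NA_real_
  )
}

#' Extract the flanking sequences of an interval
#'
#' Returns the `flank_bp` bases on each side of a 0-based half-open
#' interval, clipped at chromosome boundaries.
#'
#' @param genome Named character vector or `Biostrings::DNAStringSet` of
#'   chromosome sequences.
#' @param chrom Chromosome name.
#' @param start,end Interval (0-based half-open).
#' @param flank_bp Flank width in bp (default 1000).
#' @return List `left`, `right` (possibly empty strings) and `left_bp`,
#'   `right_bp` actual lengths after clipping.
#' @export
extract_flanks <- function(genome, chrom, start, end, flank_bp = 1000) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (!chrom %in% names(genome)) abort(paste0("no such chromosome: ", chrom))
  L <- nchar(genome[[chrom]])
  if (start < 0 || end > L || start >= end) {
    abort("interval outside chromosome bounds")
  }
  ls <- max(0, start - flank_bp)
  left <- if (start > 0) substr(genome[[chrom]], ls + 1, start) else ""
  re <- min(L, end + flank_bp)
  right <- if (end < L) substr(genome[[chrom]], end + 1, re) else ""
  list(left = left, right = right,
       left_bp = nchar(left), right_bp = nchar(right))
}

#' Pooled composition of several sequences
#'
#' Combines sequences by summing raw counts and dividing by total length
#' (concatenation-free weighted counting: context windows never span the
#' junction between pieces). Used for the two 1 kb flanks of a TE and for
#' the owned segments of a disrupted copy.
#'
#' @param seqs Character vector of sequences; empty strings are ignored.
#' @param region_id Optional identifier.
#' @return One-row tibble as in [compute_composition()], or all-NA row if no
#'   sequence remains.
#' @export
pooled_composition <- function(seqs, region_id = NA_character_) {
  seqs <- seqs[nchar(seqs) > 0]
  if (length(seqs) == 0) {
    return(tibble(
      region_id = region_id, length_bp = 0L, gc = NA_real_, p_cg = NA_real_,
      p_chg = NA_real_, p_chh = NA_real_, p_tgca = NA_real_
    ))
  }
  counts <- lapply(seqs, composition_counts)
  tot <- function(f) sum(vapply(counts, `[[`, numeric(1), f))
  len <- tot("length_bp")
  ndn <- tot("n_dinuc")
  tibble(
    region_id = region_id,
    length_bp = as.integer(len),
    gc = tot("n_gc") / len,
    p_cg = tot("n_cg") / len,
    p_chg = tot("n_chg") / len,
    p_chh = tot("n_chh") / len,
    p_tgca = if (ndn > 0) tot("n_tgca") / ndn else NA_real_
  )
}

# sequence of a resolved copy: concatenation-free pooled counting over its
# owned segments
copy_segment_seqs <- function(genome, segments_copy) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  vapply(seq_len(nrow(segments_copy)), function(i) {
    substr(
      genome[[segments_copy$chrom[i]]],
      segments_copy$seg_start[i] + 1, segments_copy$seg_end[i]
    )
  }, character(1))
}

#' Composition features for every resolved TE copy and its flanks
#'
#' For each non-dropped copy, computes [pooled_composition()] over its owned
#' segments (suffix `_te`) and over its two 1 kb flanks pooled (suffix
#' `_flank`). Flanks are anchored at the copy's span boundaries (including
#' nested insertions) and clipped at chromosome ends.
#'
#' @param resolved A `resolved_annotation`.
#' @param genome Named character vector or `DNAStringSet`.
#' @param flank_bp Flank width (default 1000).
#' @return Tibble keyed by `copy_id` with `_te` and `_flank` feature columns.
#' @export
composition_features <- function(resolved, genome, flank_bp = 1000) {
  stopifnot(inherits(resolved, "resolved_annotation"))
  if (inherits(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  kept <- resolved$copies %>% filter(!.data$dropped)
  segs <- split(resolved$segments, resolved$segments$copy_id)
  rows <- lapply(seq_len(nrow(kept)), function(i) {
    id <- kept$copy_id[i]
    te <- pooled_composition(copy_segment_seqs(genome, segs[[id]]), id)
    fl <- extract_flanks(genome, kept$chrom[i], kept$start[i], kept$end[i], flank_bp)
    flank <- pooled_composition(c(fl$left, fl$right), id)
    te$length_bp <- NULL
    flank$length_bp <- NULL
    names(te)[-1] <- paste0(names(te)[-1], "_te")
    names(flank)[-1] <- paste0(names(flank)[-1], "_flank")
    bind_cols(tibble(copy_id = id), te[-1], flank[-1])
  })
  bind_rows(rows)
}
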