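# Internal helpers shared across modules.
#
# All internal coordinates are 0-based half-open [start, end); GRanges and
# GFF3 are 1-based inclusive, BED is 0-based half-open. Conversions happen
# only at IO boundaries, through the two helpers below.

# tibble with chrom/start/end (0-based half-open) -> GRanges (1-based closed)
as_granges0 <- function(df, keep = character()) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
  for (k in keep) S4Vectors::mcols(gr)[[k]] <- df[[k]]
  gr
}

# GRanges -> tibble with 0-based half-open coordinates
from_granges0 <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  ) %>%
    bind_cols(as_tibble(as.data.frame(S4Vectors::mcols(gr))))
}

# Deterministic child seeds derived from one master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Overlap in bp between one interval and a set of intervals (half-open).
overlap_bp <- function(start, end, starts, ends) {
  pmax(0L, pmin(end, ends) - pmax(start, starts))
}

# split a character string into a character vector of single bases
seq_chars <- function(seq) strsplit(toupper(seq), "", fixed = TRUE)[[1]]

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
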