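#' Kimura two-parameter divergence of an aligned sequence pair
#'
#' Computes the K2P distance between two aligned sequences, distinguishing
#' transitions (A<->G, C<->T; proportion P) from transversions (proportion
#' Q): d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q)). Columns containing a gap
#' or N in either sequence are excluded (pairwise deletion).
#'
#' @param seq1,seq2 Equal-length aligned sequences (alphabet A,C,G,T,N,-).
#' @param copy_id Optional identifier carried into the output.
#' @return One-row tibble: `copy_id`, `method` ("ltr_ltr"), `P`, `Q`, `d`,
#'   `aligned_sites`, `transitions`, `transversions`.
#' @export
k2p_divergence <- function(seq1, seq2, copy_id = NA_character_) {
  a <- seq_chars(seq1)
  b <- seq_chars(seq2)
  if (length(a) != length(b)) abort("aligned sequences must have equal length")
  ok_alpha <- c("A", "C", "G", "T", "N", "-")
  if (!all(a %in% ok_alpha) || !all(b %in% ok_alpha)) {
    abort("sequences must use alphabet {A,C,G,T,N,-}")
  }
  keep <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n == 0) abort("no aligned sites after removing gaps/Ns; divergence undefined")
  diff <- a != b
  purine <- c("A", "G")
  ts <- diff & ((a %in% purine) == (b %in% purine)) # same chemical class
  tv <- diff & !ts
  P <- sum(ts) / n
  Q <- sum(tv) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    abort(paste0(
      "K2P saturation: 1-2P-Q = ", signif(w1, 4), ", 1-2Q = ", signif(w2, 4),
      "; divergence not estimable"
    ), class = "teecology_saturation_error")
  }
  tibble(
    copy_id = copy_id, method = "ltr_ltr",
    P = P, Q = Q, d = -0.5 * log(w1 * sqrt(w2)),
    aligned_sites = n, transitions = sum(ts), transversions = sum(tv)
  )
}

#' Convert a divergence estimate to an age in years
#'
#' An LTR-LTR divergence accumulates on both LTRs after insertion, so
#' T = d / (2 mu); a terminal branch is a single lineage, so T = b / mu.
#'
#' @param d_or_b Divergence (substitutions/site) or branch length.
#' @param method `"ltr_ltr"` or `"terminal_branch"`.
#' @param mu Mutation rate in substitutions per site per year
#'   (default 3.3e-8).
#' @return Age in years.
#' @export
divergence_to_age <- function(d_or_b, method = c("ltr_ltr", "terminal_branch"),
                              mu = 3.3e-8) {
  method <- match.arg(method)
  if (!is_scalar_number(mu) || mu <= 0) abort("mu must be a positive number")
  if (any(d_or_b < 0)) abort("divergence must be non-negative")
  if (method == "ltr_ltr") d_or_b / (2 * mu) else d_or_b / mu
}

#' Read paired-LTR alignments from an aligned FASTA file
#'
#' Records are expected two per copy, named `<copy_id>_5LTR` and
#' `<copy_id>_3LTR`, each pair aligned to equal length.
#'
#' @param path Aligned FASTA path.
#' @return Named list (by copy_id) of length-2 character vectors.
#' @export
read_ltr_alignments <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- names(ss)
  m <- regmatches(ids, regexec("^(.*)_(5LTR|3LTR)$", ids))
  if (any(lengths(m) != 3)) {
    abort("LTR alignment record names must end in _5LTR or _3LTR")
  }
  copy <- vapply(m, `[`, character(1), 2)
  side <- vapply(m, `[`, character(1), 3)
  out <- list()
  for (id in unique(copy)) {
    i5 <- which(copy == id & side == "5LTR")
    i3 <- which(copy == id & side == "3LTR")
    if (length(i5) != 1 || length(i3) != 1) {
      abort(paste0("copy ", id, " does not have exactly one 5LTR and one 3LTR record"))
    }
    out[[id]] <- c(as.character(ss[[i5]]), as.character(ss[[i3]]))
  }
  out
}

#' Per-copy LTR-LTR ages from paired alignments
#'
#' Applies [k2p_divergence()] to every pair and converts to years with
#' [divergence_to_age()]. Saturated pairs are excluded with a warning.
#'
#' @param alignments Named list of aligned pairs (see
#'   [read_ltr_alignments()]) or a path to an aligned FASTA file.
#' @param mu Mutation rate (substitutions/site/year).
#' @return Tibble `copy_id`, `method`, `P`, `Q`, `d`, `aligned_sites`,
#'   `age_years`, `mu`.
#' @export
ltr_ages <- function(alignments, mu = 3.3e-8) {
  if (is.character(alignments) && length(alignments) == 1) {
    alignments <- read_ltr_alignments(alignments)
  }
  rows <- list()
  saturated <- character()
  for (id in names(alignments)) {
    pair <- alignments[[id]]
    res <- tryCatch(
      k2p_divergence(pair[1], pair[2], copy_id = id),
      teecology_saturation_error = function(e) NULL
    )
    if (is.null(res)) saturated <- c(saturated, id) else rows[[id]] <- res
  }
  if (length(saturated) > 0) {
    warn(paste0(
      length(saturated), " LTR pair(s) saturated and excluded: ",
      paste(head(saturated, 5), collapse = ", ")
    ))
  }
  bind_rows(rows) %>%
    mutate(age_years = divergence_to_age(.data$d, "ltr_ltr", mu), mu = mu) %>%
    select("copy_id", "method", "P", "Q", "d", "aligned_sites", "age_years", "mu")
}

#' Per-copy ages from terminal branch lengths of a copy phylogeny
#'
#' The terminal branch length of each leaf measures substitutions since
#' divergence from its closest relative in the genome; age = b / mu.
#'
#' @param tree A newick string, a path to a newick file, or an `ape::phylo`.
#' @param mu Mutation rate (substitutions/site/year).
#' @return Tibble `copy_id`, `method` ("terminal_branch"), `b`, `age_years`,
#'   `mu`; one row per leaf.
#' @export
terminal_branch_ages <- function(tree, mu = 3.3e-8) {
  if (!is_scalar_number(mu) || mu <= 0) abort("mu must be a positive number")
  if (is.character(tree)) {
    phy <- if (file.exists(tree)) ape::read.tree(tree) else ape::read.tree(text = tree)
  } else {
    phy <- tree
  }
  if (is.null(phy) || !inherits(phy, "phylo")) abort("could not parse newick tree")
  if (anyDuplicated(phy$tip.label)) abort("duplicate leaf labels in tree")
  ntips <- length(phy$tip.label)
  tip_edges <- match(seq_len(ntips), phy$edge[, 2])
  b <- phy$edge.length[tip_edges]
  if (anyNA(b)) {
    warn("missing terminal branch length(s) treated as 0")
    b[is.na(b)] <- 0
  }
  if (any(b < 0)) abort("negative branch lengths in tree")
  tibble(
    copy_id = phy$tip.label, method = "terminal_branch",
    b = b, age_years = divergence_to_age(b, "terminal_branch", mu), mu = mu
  )
}

#' Trim sequences to the terminal window used for tree building
#'
#' For large superfamilies, trees are built from at most `max_bp` of each
#' copy: the 3' terminal window for Helitrons and the 5' terminal window for
#' LTR and TIR elements.
#'
#' @param seqs Named character vector of sequences.
#' @param order TE order: `"Helitron"`, `"LTR"`, `"TIR"` or `"nonLTR"`.
#' @param max_bp Maximum bp retained (default 1000).
#' @return Named character vector of trimmed sequences.
#' @export
trim_for_tree <- function(seqs, order, max_bp = 1000) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    if (n <= max_bp) return(s)
    if (order == "Helitron") {
      substr(s, n - max_bp + 1, n)
    } else {
      substr(s, 1, max_bp)
    }
  }, character(1))
}
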