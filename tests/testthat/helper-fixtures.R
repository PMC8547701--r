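# Shared fixture builders. Everything is generated in code at test time.

# minimal TE copy row(s)
mk_copies <- function(ids, fams, starts, ends, chrom = "chr1",
                      parents = NA_character_) {
  sf <- substr(fams, 1, 3)
  tax <- te_superfamilies()
  tibble::tibble(
    copy_id = ids, family_id = fams, superfamily = sf,
    order = tax$order[match(sf, tax$superfamily)],
    te_class = tax$te_class[match(sf, tax$superfamily)],
    chrom = chrom, start = as.integer(starts), end = as.integer(ends),
    strand = "+", parent_te = parents
  )
}

# random annotation with containment-only overlaps (nesting depth <= max_depth)
random_nested_annotation <- function(seed, genome_bp = 100000, n = 25,
                                     max_depth = 4) {
  set.seed(seed)
  sf_pool <- c("RLG", "RLC", "DTA", "DHH")
  starts <- integer(0); ends <- integer(0); depth <- integer(0)
  for (i in seq_len(n)) {
    len <- sample(200:8000, 1)
    placed <- FALSE
    hosts <- which(ends - starts >= len + 2 & depth < max_depth - 1)
    if (length(hosts) > 0 && runif(1) < 0.45) {
      h <- hosts[sample.int(length(hosts), 1)]
      for (try in 1:30) {
        s <- starts[h] + sample.int(ends[h] - starts[h] - len - 1, 1)
        e <- s + len
        ov <- which(starts < e & ends > s)
        if (all(starts[ov] <= s & ends[ov] >= e) &&
            !any(starts[ov] >= s & ends[ov] <= e)) {
          inner <- ov[which.max(starts[ov])]
          starts <- c(starts, s); ends <- c(ends, e)
          depth <- c(depth, depth[inner] + 1L)
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) {
      for (try in 1:60) {
        s <- sample.int(genome_bp - len, 1) - 1L
        e <- s + len
        if (!any(starts < e & ends > s)) {
          starts <- c(starts, s); ends <- c(ends, e); depth <- c(depth, 0L)
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) break
  }
  m <- length(starts)
  sfs <- sample(sf_pool, m, replace = TRUE)
  mk_copies(
    ids = sprintf("te%03d", seq_len(m)),
    fams = paste0(sfs, "00001"),
    starts = starts, ends = ends
  )
}

# independent per-base sweep oracle for nesting resolution: each base goes
# to the smallest (innermost) interval covering it
per_base_ownership_oracle <- function(copies) {
  owner <- rep(NA_integer_, max(copies$end))
  width <- copies$end - copies$start
  for (b in seq_len(max(copies$end))) {
    pos <- b - 1L
    cover <- which(copies$start <= pos & copies$end > pos)
    if (length(cover) > 0) owner[b] <- cover[which.min(width[cover])]
  }
  owner
}

owner_vector_from_segments <- function(copies, segments) {
  owner <- rep(NA_integer_, max(copies$end))
  for (i in seq_len(nrow(segments))) {
    idx <- (segments$seg_start[i] + 1):segments$seg_end[i]
    owner[idx] <- match(segments$copy_id[i], copies$copy_id)
  }
  owner
}

# one small synthetic dataset shared across test files (built once)
toy_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(sim_config(
        seed = 42, n_chromosomes = 2, chrom_length = 200000,
        n_families_per_superfamily = 1,
        family_size_distribution = list(mu = 4, size = 1)
      ))
    }
    cache
  }
})

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
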