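# Synthetic toy genome with known ground truth: TE annotations with nesting,
# sequences diverged under a K80 substitution process, per-superfamily trees
# and paired-LTR alignments consistent with true ages, plus methylation,
# expression, genetic-map, chromatin, variant and subgenome layers.

#' Configuration for the synthetic-dataset generator
#'
#' The defaults define the package's standard toy study conditions: a
#' 3 x 300 kb genome, 2 families per superfamily with heavy-tailed sizes,
#' 30% nested insertions, the mutation rate 3.3e-8 substitutions per site
#' per year, and the five tissues of the methylation atlas.
#'
#' @param seed Integer master seed; a fixed seed gives byte-identical
#'   datasets.
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Chromosome length in bp.
#' @param n_families_per_superfamily Families simulated per superfamily.
#' @param family_size_distribution List `mu`, `size` of the negative
#'   binomial (shifted by +2 so every family has at least two copies).
#' @param nesting_probability Probability a new insertion lands inside an
#'   existing copy.
#' @param mu Mutation rate, substitutions per site per year.
#' @param age_effect_spec Optional named list mapping a feature name
#'   (`length_bp` or `dist_gene`) to `list(shape=, coef=)`; when given,
#'   copy ages are a known function of those features plus noise.
#' @param noise_sd Age noise (years) used with `age_effect_spec`.
#' @param tissue_names Tissues for the methylation and expression layers.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 3,
                       chrom_length = 300000,
                       n_families_per_superfamily = 2,
                       family_size_distribution = list(mu = 6, size = 0.8),
                       nesting_probability = 0.3,
                       mu = 3.3e-8,
                       age_effect_spec = NULL,
                       noise_sd = 50000,
                       tissue_names = c("anther", "SAM", "earshoot",
                                        "flagleaf", "seedling_leaf")) {
  cfg <- list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_families_per_superfamily = as.integer(n_families_per_superfamily),
    family_size_distribution = family_size_distribution,
    nesting_probability = nesting_probability, mu = mu,
    age_effect_spec = age_effect_spec, noise_sd = noise_sd,
    tissue_names = tissue_names
  )
  if (cfg$mu <= 0) abort("mu must be positive")
  if (cfg$nesting_probability < 0 || cfg$nesting_probability > 1) {
    abort("nesting_probability must lie in [0, 1]")
  }
  if (cfg$chrom_length < 10 * 10000) {
    abort("chrom_length must be at least 10x the longest TE (100 kb)")
  }
  if (cfg$noise_sd < 0) abort("noise_sd must be non-negative")
  structure(cfg, class = "sim_config")
}

# superfamily-specific length profiles (bp)
sf_profiles <- function() {
  tribble(
    ~superfamily, ~min_len, ~max_len, ~ltr_frac,
    "DHH", 500, 3000, NA,
    "DTA", 150, 800, NA,
    "DTC", 300, 1500, NA,
    "DTH", 150, 600, NA,
    "DTM", 200, 1500, NA,
    "DTT", 150, 500, NA,
    "DTX", 150, 800, NA,
    "RLC", 2500, 8000, 0.1,
    "RLG", 3000, 10000, 0.1,
    "RLX", 2000, 7000, 0.1,
    "RIL", 1000, 4000, NA,
    "RIT", 800, 3000, NA,
    "RST", 100, 400, NA
  )
}

random_seq <- function(n, gc = 0.46) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# deaminate CG dinucleotides: each CG becomes TG or CA with probability
# delta (models methylation-driven C->T transitions, enriching TG/CA while
# depleting CG)
deaminate_cg <- function(seq, delta) {
  if (delta <= 0) return(seq)
  x <- seq_chars(seq)
  n <- length(x)
  if (n < 2) return(seq)
  cg <- which(x[-n] == "C" & x[-1] == "G")
  hit <- cg[runif(length(cg)) < delta]
  if (length(hit) > 0) {
    to_tg <- runif(length(hit)) < 0.5
    x[hit[to_tg]] <- "T"
    x[hit[!to_tg] + 1L] <- "A"
  }
  paste(x, collapse = "")
}

# Evolve a sequence along a branch of length b (expected substitutions per
# site) under K80 with transition:transversion ratio 2:1 (kappa = 4).
# Closed-form per-site change probabilities make divergences exact in
# expectation, so K2P is the matched estimator.
evolve_seq <- function(seq, b) {
  if (b < 0) abort("branch length must be non-negative")
  x <- seq_chars(seq)
  if (b == 0) return(seq)
  p_ts <- 0.25 + 0.25 * exp(-4 * b / 6) - 0.5 * exp(-10 * b / 6)
  p_tv <- 0.5 - 0.5 * exp(-4 * b / 6)
  n <- length(x)
  u <- runif(n)
  ts <- u < p_ts
  tv <- !ts & u < p_ts + p_tv
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  if (any(ts)) x[ts] <- transition[x[ts]]
  if (any(tv)) {
    tv_map <- list(
      A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G")
    )
    pick <- 1L + (runif(sum(tv)) < 0.5)
    x[tv] <- mapply(function(base, k) tv_map[[base]][k], x[tv], pick)
  }
  paste(x, collapse = "")
}

#' Simulate aligned copies and a tree for one TE family
#'
#' Emits an ancestral-sequence alignment in which each copy has diverged by
#' its own terminal branch b = mu * age (K80 process, ti:tv 2:1), together
#' with a star newick tree whose terminal branch lengths are exactly
#' mu * age. The simulation writes the truth directly, standing in for an
#' aligner and tree builder.
#'
#' @param n_copies Number of copies (>= 2).
#' @param true_ages Ages in years, length `n_copies`, non-negative.
#' @param mu Mutation rate (substitutions/site/year).
#' @param seed Integer seed.
#' @param labels Copy labels (default `copy_1` ...).
#' @param seq_length Alignment length in bp (default 1000).
#' @return List `alignment` (named character vector), `tree` (newick
#'   string), `branch_lengths` (tibble `copy_id`, `b`).
#' @export
generate_family_alignments <- function(n_copies, true_ages, mu, seed,
                                       labels = NULL, seq_length = 1000) {
  if (n_copies < 2) abort("need at least 2 copies")
  if (length(true_ages) != n_copies) abort("true_ages must have length n_copies")
  if (any(true_ages < 0)) abort("ages must be non-negative")
  if (is.null(labels)) labels <- paste0("copy_", seq_len(n_copies))
  set.seed(as.integer(seed))
  anc <- random_seq(seq_length)
  b <- mu * true_ages
  aln <- setNames(vapply(b, function(bi) evolve_seq(anc, bi), character(1)), labels)
  tree <- paste0(
    "(", paste0(labels, ":", format(b, digits = 12, scientific = FALSE,
                                    trim = TRUE), collapse = ","), ");"
  )
  list(alignment = aln, tree = tree,
       branch_lengths = tibble(copy_id = labels, b = b))
}

#' Simulate a feature table with a known age function
#'
#' Recovery harness for the model stage: `n` rows of independent standard
#' normal features, of which those named in `age_effect_spec` contribute to
#' age through their stated shape and coefficient, plus `n_decoys` decoy
#' features independent of age, a non-causal `superfamily` label, and
#' Gaussian noise.
#'
#' @param n Number of rows (>= 100).
#' @param age_effect_spec Named list: feature name -> `list(shape, coef)`,
#'   shape one of `"linear"`, `"quadratic"`, `"step"`.
#' @param noise_sd Noise standard deviation (years).
#' @param seed Integer seed.
#' @param n_decoys Decoy feature count (default 47).
#' @return List `features` (tibble with `copy_id`, causal and decoy columns,
#'   `superfamily`), `ages` (numeric), `spec` (the echoed effect spec).
#' @export
generate_age_features <- function(n, age_effect_spec, noise_sd, seed,
                                  n_decoys = 47) {
  if (n < 100) abort("n must be at least 100")
  shapes <- c("linear", "quadratic", "step")
  for (f in names(age_effect_spec)) {
    if (!age_effect_spec[[f]]$shape %in% shapes) {
      abort(paste0("unknown effect shape: ", age_effect_spec[[f]]$shape))
    }
  }
  set.seed(as.integer(seed))
  causal <- names(age_effect_spec)
  feats <- as_tibble(setNames(
    lapply(seq_len(length(causal) + n_decoys), function(i) rnorm(n)),
    c(causal, sprintf("decoy_%02d", seq_len(n_decoys)))
  ))
  signal <- rep(0, n)
  for (f in causal) {
    sp <- age_effect_spec[[f]]
    signal <- signal + switch(sp$shape,
      linear = sp$coef * feats[[f]],
      quadratic = sp$coef * feats[[f]]^2,
      step = sp$coef * (feats[[f]] > 0)
    )
  }
  ages <- signal + rnorm(n, sd = noise_sd)
  feats <- feats %>%
    mutate(
      superfamily = sample(te_superfamilies()$superfamily, n, replace = TRUE),
      copy_id = sprintf("sim_%05d", seq_len(n)),
      .before = 1
    ) %>%
    select("copy_id", dplyr::everything())
  list(features = feats, ages = ages, spec = age_effect_spec)
}

# --- TE placement ----------------------------------------------------------

# place copies in arrival (age-descending) order; returns chrom/start/end/
# parent index per copy. Any two intervals are disjoint or strictly nested.
place_copies <- function(lens, ages, chrom_names, chrom_length,
                         nesting_probability, force_chain = TRUE) {
  n <- length(lens)
  if (sum(lens) > 0.75 * length(chrom_names) * chrom_length) {
    abort("capacity error: total TE length exceeds what the genome can hold")
  }
  chrom <- character(n); start <- integer(n); end <- integer(n)
  parent <- rep(NA_integer_, n)
  placed <- integer(0)

  # force one nesting chain of depth >= 3 among the earliest suitable copies
  chain <- integer(0)
  if (force_chain && nesting_probability > 0) {
    a <- which(lens >= 1200)[1]
    if (!is.na(a)) {
      b <- which(seq_len(n) > a & lens <= lens[a] - 400)[1]
      if (!is.na(b)) {
        cc <- which(seq_len(n) > b & lens <= lens[b] - 200)[1]
        if (!is.na(cc)) chain <- c(a, b, cc)
      }
    }
  }

  for (i in seq_len(n)) {
    len <- lens[i]
    done <- FALSE
    if (length(chain) > 0 && i == chain[1]) {
      chrom[i] <- chrom_names[1]
      start[i] <- as.integer(chrom_length %/% 3)
      end[i] <- start[i] + len
      done <- TRUE
    } else if (length(chain) > 0 && i %in% chain[-1]) {
      p <- chain[match(i, chain) - 1]
      chrom[i] <- chrom[p]
      start[i] <- as.integer(start[p] + (end[p] - start[p] - len) %/% 2)
      end[i] <- start[i] + len
      parent[i] <- p
      done <- TRUE
    }
    if (!done && length(placed) > 0 && runif(1) < nesting_probability) {
      hosts <- placed[lens[placed] >= len + 2 & !(placed %in% chain)]
      if (length(hosts) > 0) {
        for (try in seq_len(50)) {
          h <- hosts[sample.int(length(hosts), 1)]
          s <- start[h] + sample.int(end[h] - start[h] - len - 1, 1)
          e <- s + len
          same <- placed[chrom[placed] == chrom[h]]
          ov <- same[start[same] < e & end[same] > s]
          # accept if every overlapping placed copy strictly contains [s, e)
          if (all(start[ov] <= s & end[ov] >= e) &&
              !any(start[ov] >= s & end[ov] <= e)) {
            chrom[i] <- chrom[h]; start[i] <- s; end[i] <- e
            inner <- ov[which.max(start[ov])]
            parent[i] <- inner
            done <- TRUE
            break
          }
        }
      }
    }
    if (!done) {
      for (try in seq_len(400)) {
        ch <- chrom_names[sample.int(length(chrom_names), 1)]
        s <- sample.int(chrom_length - len, 1) - 1L
        e <- s + len
        same <- placed[chrom[placed] == ch]
        if (!any(start[same] < e & end[same] > s)) {
          chrom[i] <- ch; start[i] <- s; end[i] <- e
          done <- TRUE
          break
        }
      }
    }
    if (!done) {
      abort("capacity error: could not place a TE copy without illegal overlap")
    }
    placed <- c(placed, i)
  }
  tibble(chrom = chrom, start = start, end = end, parent_idx = parent)
}

# --- full dataset ----------------------------------------------------------

#' Generate a self-consistent synthetic TE dataset
#'
#' Builds every input layer of the analysis from one seed: a multi-
#' chromosome genome with TE copies of all 13 superfamilies, nested
#' insertions with known arrival order (a nested child is always younger
#' than its parent; at least one chain of depth 3 is present whenever
#' nesting is on), sequences diverged from family consensus under a K80
#' process at the configured mutation rate, paired-LTR alignments and
#' per-superfamily trees consistent with the true ages, and methylation /
#' expression / genetic-map / MNase / variant / subgenome / protein-domain
#' layers with family-level structure.
#'
#' @param config A [sim_config()].
#' @return Object of class `synthetic_te_dataset`; see the package vignette
#'   for the layer-by-layer description.
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(config$seed, 12)
  tax <- te_superfamilies()
  prof <- sf_profiles()

  # 1. families and copies -------------------------------------------------
  set.seed(seeds[1])
  fams <- tidyr::crossing(superfamily = tax$superfamily,
                          idx = seq_len(config$n_families_per_superfamily)) %>%
    mutate(
      family_id = sprintf("%s%05d", .data$superfamily, .data$idx),
      n_copies = 2 + rnbinom(dplyr::n(),
        size = config$family_size_distribution$size,
        mu = config$family_size_distribution$mu
      ),
      mean_age = exp(runif(dplyr::n(), log(8e4), log(1.2e6))),
      deamination = ifelse(runif(dplyr::n()) < 0.5, runif(dplyr::n(), 0.3, 0.9), 0),
      silenced = runif(dplyr::n()) < 0.6,
      gc_bias = runif(dplyr::n(), 0.40, 0.60)
    ) %>%
    left_join(prof, by = "superfamily")

  copies <- fams %>%
    rowwise() %>%
    reframe(
      family_id = rep(.data$family_id, .data$n_copies),
      superfamily = rep(.data$superfamily, .data$n_copies),
      length = as.integer(round(runif(.data$n_copies, .data$min_len, .data$max_len))),
      age_years = pmin(pmax(.data$mean_age * rlnorm(.data$n_copies, 0, 0.5), 2e3), 2.5e6)
    ) %>%
    arrange(desc(.data$age_years)) %>% # arrival order: oldest first
    group_by(.data$family_id) %>%
    mutate(copy_id = paste0(.data$family_id, "_", sprintf("%03d", row_number()))) %>%
    ungroup()

  chrom_names <- paste0("chr", seq_len(config$n_chromosomes))

  set.seed(seeds[2])
  pl <- place_copies(copies$length, copies$age_years, chrom_names,
                     config$chrom_length, config$nesting_probability)
  copies <- bind_cols(copies, pl) %>%
    mutate(
      parent_te = ifelse(is.na(.data$parent_idx), NA_character_,
                         .data$copy_id[.data$parent_idx]),
      strand = sample(c("+", "-"), dplyr::n(), replace = TRUE)
    )

  # 2. genes (can overlap TEs: intronic TEs exist) ---------------------------
  set.seed(seeds[3])
  n_genes_per_chr <- 15
  genes <- tidyr::crossing(chrom = chrom_names, i = seq_len(n_genes_per_chr)) %>%
    mutate(
      len = as.integer(round(runif(dplyr::n(), 1000, 4000))),
      start = vapply(.data$len, function(l) {
        sample.int(config$chrom_length - l, 1) - 1L
      }, integer(1)),
      end = .data$start + .data$len,
      gene_id = sprintf("gene%04d", row_number())
    ) %>%
    select("gene_id", "chrom", "start", "end")
  syntenic_ids <- sort(sample(genes$gene_id, round(0.7 * nrow(genes))))

  # 3. genome sequence with TE copies written in arrival order ---------------
  set.seed(seeds[4])
  genome_chars <- lapply(chrom_names, function(ch) {
    seq_chars(random_seq(config$chrom_length))
  })
  names(genome_chars) <- chrom_names

  consensus <- list()
  for (k in seq_len(nrow(fams))) {
    fam <- fams$family_id[k]
    max_len <- max(copies$length[copies$family_id == fam], fams$min_len[k])
    cs <- random_seq(max_len, gc = fams$gc_bias[k])
    consensus[[fam]] <- deaminate_cg(cs, fams$deamination[k])
  }

  ltr_alignments <- list()
  ltr_len <- integer(nrow(copies))
  for (i in seq_len(nrow(copies))) { # arrival order: children overwrite parents
    fam <- copies$family_id[i]
    len <- copies$length[i]
    b <- config$mu * copies$age_years[i]
    body <- evolve_seq(substr(consensus[[fam]], 1, len), b)
    if (copies$superfamily[i] %in% c("RLC", "RLG", "RLX")) {
      L <- max(150L, as.integer(round(len * 0.1)))
      ltr_len[i] <- L
      anc_ltr <- substr(consensus[[fam]], 1, L)
      ltr5 <- evolve_seq(anc_ltr, b)
      ltr3 <- evolve_seq(anc_ltr, b)
      body <- paste0(ltr5, substr(body, L + 1, len - L), ltr3)
      ltr_alignments[[copies$copy_id[i]]] <- c(ltr5, ltr3)
    }
    idx <- (copies$start[i] + 1):copies$end[i]
    genome_chars[[copies$chrom[i]]][idx] <- seq_chars(body)
  }
  genome <- vapply(genome_chars, paste, character(1), collapse = "")

  # 4. per-superfamily star trees with b = mu * age --------------------------
  trees <- list()
  for (sf in unique(copies$superfamily)) {
    sub <- copies[copies$superfamily == sf, ]
    if (nrow(sub) < 2) next
    b <- config$mu * sub$age_years
    trees[[sf]] <- paste0(
      "(", paste0(sub$copy_id, ":",
                  format(b, digits = 12, scientific = FALSE, trim = TRUE),
                  collapse = ","), ");"
    )
  }

  # 5. methylation windows ---------------------------------------------------
  set.seed(seeds[5])
  methylation <- simulate_methylation(
    genome_chars, copies, fams, config$tissue_names
  )

  # 6. expression ------------------------------------------------------------
  set.seed(seeds[6])
  expression <- simulate_expression(fams, genes, config$tissue_names)

  # 7. genetic map -----------------------------------------------------------
  set.seed(seeds[7])
  genetic_map <- map(chrom_names, function(ch) {
    pos <- seq(0, config$chrom_length, by = 10000)
    tibble(
      chrom = ch, pos = pos,
      cM = cumsum(c(0, rgamma(length(pos) - 1, shape = 4, scale = 0.05)))
    )
  }) %>% list_rbind()

  # 8. MNase hypersensitive intervals ---------------------------------------
  set.seed(seeds[8])
  mnase <- lapply(c(root = "root", shoot = "shoot"), function(t) {
    map(chrom_names, function(ch) {
      n <- 30
      len <- as.integer(round(runif(n, 50, 300)))
      s <- vapply(len, function(l) sample.int(config$chrom_length - l, 1) - 1L,
                  integer(1))
      tibble(chrom = ch, start = sort(s), end = sort(s) + len[order(s)])
    }) %>% list_rbind()
  })

  # 9. variant positions ------------------------------------------------------
  set.seed(seeds[9])
  variants <- map(chrom_names, function(ch) {
    n <- round(config$chrom_length / 250)
    tibble(chrom = ch, pos = sort(sample.int(config$chrom_length, n) - 1L))
  }) %>% list_rbind()

  # 10. subgenome blocks -------------------------------------------------------
  set.seed(seeds[10])
  subgenomes <- map(chrom_names, function(ch) {
    n_blocks <- 4
    bounds <- round(seq(0, config$chrom_length, length.out = n_blocks + 1))
    gap <- 5000
    tibble(
      chrom = ch,
      start = as.integer(head(bounds, -1)),
      end = as.integer(pmax(head(bounds, -1), tail(bounds, -1) - gap)),
      subgenome = sample(c("A", "B"), n_blocks, replace = TRUE)
    )
  }) %>% list_rbind()

  # 11. protein-domain hits ----------------------------------------------------
  set.seed(seeds[11])
  domain_hits <- simulate_domains(copies, fams)

  # 12. ages (optionally rewritten as a known function of features) -----------
  if (!is.null(config$age_effect_spec)) {
    set.seed(seeds[12])
    supported <- c("length_bp", "dist_gene")
    bad <- setdiff(names(config$age_effect_spec), supported)
    if (length(bad) > 0) {
      abort(paste0("age_effect_spec supports only ", paste(supported, collapse = ", ")))
    }
    dg <- nearest_gene_features(
      copies %>% select("copy_id", "chrom", "start", "end"), genes
    )$dist_gene
    vals <- list(length_bp = as.numeric(copies$length), dist_gene = dg)
    sig <- rep(5e5, nrow(copies))
    for (f in names(config$age_effect_spec)) {
      sp <- config$age_effect_spec[[f]]
      if (!sp$shape %in% c("linear", "quadratic", "step")) {
        abort(paste0("unknown effect shape: ", sp$shape))
      }
      v <- scale(vals[[f]])[, 1]
      sig <- sig + switch(sp$shape,
        linear = sp$coef * v, quadratic = sp$coef * v^2,
        step = sp$coef * (v > 0)
      )
    }
    new_age <- pmax(2e3, sig + rnorm(nrow(copies), sd = config$noise_sd))
    # preserve nesting consistency: a child stays younger than its parent
    for (i in seq_len(nrow(copies))) {
      p <- copies$parent_idx[i]
      if (!is.na(p)) new_age[i] <- min(new_age[i], 0.9 * new_age[p])
    }
    copies$age_years <- new_age
  }

  te_copies <- copies %>%
    left_join(tax[, c("superfamily", "order", "te_class")], by = "superfamily") %>%
    select(
      "copy_id", "family_id", "superfamily", "order", "te_class",
      "chrom", "start", "end", "strand", "parent_te"
    ) %>%
    left_join(domain_hits$orf, by = "copy_id")

  structure(
    list(
      config = config,
      te_copies = te_copies,
      genes = genes,
      syntenic_ids = syntenic_ids,
      genome = genome,
      true_ages = copies %>% select("copy_id", "age_years"),
      trees = trees,
      ltr_alignments = ltr_alignments,
      methylation = methylation,
      expression = expression,
      genetic_map = genetic_map,
      mnase = mnase,
      variants = variants,
      subgenomes = subgenomes,
      domain_hits = domain_hits$hits,
      family_truth = fams %>%
        select("family_id", "mean_age", "deamination", "silenced", "gc_bias")
    ),
    class = "synthetic_te_dataset"
  )
}

#' @export
print.synthetic_te_dataset <- function(x, ...) {
  cat("<synthetic_te_dataset> seed ", x$config$seed, "\n", sep = "")
  cat("  ", length(x$genome), " chromosomes x ",
      format(x$config$chrom_length, big.mark = ","), " bp; ",
      nrow(x$te_copies), " TE copies in ",
      length(unique(x$te_copies$family_id)), " families\n", sep = "")
  invisible(x)
}

# per-position cytosine context counts per 100 bp window, both strands
window_context_counts <- function(chars, window_bp = 100) {
  n <- length(chars)
  label_positions <- function(x) {
    m <- length(x)
    nxt <- c(x[-1], "")
    nxt2 <- if (m >= 3) c(x[-(1:2)], "", "") else rep("", m)
    h <- c("A", "C", "T")
    isC <- x == "C"
    list(
      CG = which(isC & nxt == "G"),
      CHG = which(isC & nxt %in% h & nxt2 == "G"),
      CHH = which(isC & nxt %in% h & nxt2 %in% h)
    )
  }
  fwd <- label_positions(chars)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rev <- label_positions(unname(comp[rev(chars)]))
  rev <- lapply(rev, function(p) n + 1L - p) # map back to genome coordinates
  n_win <- ceiling(n / window_bp)
  out <- list()
  for (ctx in METH_CONTEXTS) {
    pos <- c(fwd[[ctx]], rev[[ctx]])
    out[[ctx]] <- tabulate((pos - 1L) %/% window_bp + 1L, nbins = n_win)
  }
  out
}

# methylation layer: binomial counts per 100 bp window, context and tissue,
# with TE bodies elevated according to a family-level propensity
simulate_methylation <- function(genome_chars, copies, fams, tissues,
                                 window_bp = 100) {
  base_p <- c(CG = 0.08, CHG = 0.05, CHH = 0.015)
  te_p <- list(
    CG = setNames(runif(nrow(fams), 0.6, 0.95), fams$family_id),
    CHG = setNames(runif(nrow(fams), 0.4, 0.9), fams$family_id),
    CHH = setNames(runif(nrow(fams), 0.03, 0.15), fams$family_id)
  )
  tissue_shift <- setNames(rnorm(length(tissues), 0, 0.03), tissues)
  out <- list()
  for (ch in names(genome_chars)) {
    chars <- genome_chars[[ch]]
    n <- length(chars)
    counts <- window_context_counts(chars, window_bp)
    # base-level family ownership, children overwrite parents (arrival order)
    owner <- integer(n)
    sub <- which(copies$chrom == ch)
    fam_idx <- match(copies$family_id, fams$family_id)
    for (i in sub) owner[(copies$start[i] + 1):copies$end[i]] <- fam_idx[i]
    n_win <- ceiling(n / window_bp)
    win_start <- (seq_len(n_win) - 1L) * window_bp
    te_frac <- numeric(n_win)
    win_fam <- integer(n_win)
    for (w in seq_len(n_win)) {
      o <- owner[(win_start[w] + 1):min(win_start[w] + window_bp, n)]
      te_frac[w] <- mean(o > 0)
      if (te_frac[w] > 0) {
        tb <- tabulate(o[o > 0], nbins = nrow(fams))
        win_fam[w] <- which.max(tb)
      }
    }
    for (ctx in METH_CONTEXTS) {
      p_win <- rep(base_p[[ctx]], n_win)
      hit <- win_fam > 0
      p_win[hit] <- base_p[[ctx]] +
        te_frac[hit] * (te_p[[ctx]][fams$family_id[win_fam[hit]]] - base_p[[ctx]])
      for (t in tissues) {
        p_t <- pmin(pmax(p_win + tissue_shift[[t]], 0.005), 0.995)
        total <- counts[[ctx]]
        meth <- rbinom(n_win, total, p_t)
        keep <- runif(n_win) > 0.03 # ~3% of windows drop out per tissue
        out[[length(out) + 1]] <- tibble(
          chrom = ch, start = win_start[keep], end = win_start[keep] + window_bp,
          context = ctx, tissue = t,
          methylated_c = meth[keep], total_c = total[keep],
          fraction = ifelse(total[keep] > 0, meth[keep] / total[keep], NA_real_)
        )
      }
    }
  }
  bind_rows(out)
}

# expression layer: negative-binomial family x tissue x replicate counts with
# a silenced indicator; most active families are tissue-specific. Genes are
# broadly expressed.
simulate_expression <- function(fams, genes, tissues) {
  n_reps <- setNames(sample(2:3, length(tissues), replace = TRUE), tissues)
  lib <- tidyr::crossing(tissue = tissues, replicate = 1:3) %>%
    filter(.data$replicate <= n_reps[.data$tissue]) %>%
    mutate(library_size = round(1e6 * runif(dplyr::n(), 0.8, 1.2)))

  te_rows <- list()
  for (k in seq_len(nrow(fams))) {
    lambda <- if (fams$silenced[k]) 0.3 else exp(runif(1, log(20), log(400)))
    active <- sample(tissues, 1)
    for (t in tissues) {
      mu_t <- if (t == active) lambda else lambda * 0.05
      for (r in seq_len(n_reps[[t]])) {
        te_rows[[length(te_rows) + 1]] <- tibble(
          family_id = fams$family_id[k], tissue = t, replicate = r,
          count = rnbinom(1, size = 2, mu = mu_t)
        )
      }
    }
  }
  gene_rows <- list()
  for (g in genes$gene_id) {
    lambda <- exp(runif(1, log(50), log(2000)))
    t_eff <- exp(rnorm(length(tissues), 0, 0.4))
    for (j in seq_along(tissues)) {
      t <- tissues[j]
      for (r in seq_len(n_reps[[t]])) {
        gene_rows[[length(gene_rows) + 1]] <- tibble(
          gene_id = g, tissue = t, replicate = r,
          count = rnbinom(1, size = 5, mu = lambda * t_eff[j])
        )
      }
    }
  }
  list(
    te_counts = bind_rows(te_rows),
    gene_counts = bind_rows(gene_rows),
    library_sizes = lib
  )
}

# protein-domain layer following superfamily autonomy rules
simulate_domains <- function(copies, fams) {
  coding_fam <- setNames(runif(nrow(fams)) < 0.35, fams$family_id)
  rows <- list()
  orf <- integer(nrow(copies))
  ltr_pol <- c("AP", "RT", "RNaseH", "INT")
  for (i in seq_len(nrow(copies))) {
    id <- copies$copy_id[i]
    sf <- copies$superfamily[i]
    fam_coding <- coding_fam[[copies$family_id[i]]]
    doms <- character(0)
    if (sf %in% c("RLC", "RLG", "RLX")) {
      if (fam_coding) {
        u <- runif(1)
        doms <- if (u < 0.6) {
          c("GAG", ltr_pol)
        } else if (u < 0.72) {
          "GAG"
        } else if (u < 0.84) {
          ltr_pol
        } else if (u < 0.92) {
          sample(ltr_pol, 2)
        } else {
          character(0)
        }
      }
    } else if (startsWith(sf, "DT")) {
      if (fam_coding && runif(1) < 0.6) doms <- "TPase"
    } else if (sf == "DHH") {
      if (fam_coding && runif(1) < 0.5) doms <- "RepHel"
    } else if (sf %in% c("RIL", "RIT")) {
      if (fam_coding && runif(1) < 0.5) doms <- "RT"
    }
    orf[i] <- if (length(doms) >= 4) {
      round(runif(1, 600, 1500))
    } else if (length(doms) > 0) {
      round(runif(1, 200, 600))
    } else {
      round(runif(1, 20, 200))
    }
    if (length(doms) > 0) {
      rows[[length(rows) + 1]] <- tibble(copy_id = id, domain = doms)
    }
  }
  list(
    hits = if (length(rows) > 0) bind_rows(rows) else
      tibble(copy_id = character(), domain = character()),
    orf = tibble(copy_id = copies$copy_id, longest_orf_aa = as.integer(orf))
  )
}
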