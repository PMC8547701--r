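# End-to-end orchestration: resolve -> ages -> features -> profiles ->
# model, from a single configuration, with deterministic outputs.

#' Pipeline configuration
#'
#' @param input_dir Directory holding the input layers (the layout written
#'   by [write_dataset()]).
#' @param output_dir Where stage outputs are written.
#' @param mu Mutation rate (substitutions/site/year, default 3.3e-8).
#' @param min_surviving_bp Nesting-resolution survival threshold (default
#'   50 bp).
#' @param min_copies_for_reporting Family-reporting threshold (default 10).
#' @param flank_bp Flank width for composition/context features (default
#'   1000).
#' @param window_bp Methylation window width (default 100).
#' @param n_flank_windows Methylation flank windows per side (default 20).
#' @param seed Master seed for the model stage.
#' @param n_trees Forest size (default 1000).
#' @param train_frac Training fraction (default 0.5).
#' @param importance_repeats Permutation repeats per feature (default 5 for
#'   the toy scale; 20 matches the package's standalone default).
#' @param ice_features Features to trace ICE curves for (default
#'   `length_bp` and `dist_gene`).
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir, output_dir,
                            mu = 3.3e-8, min_surviving_bp = 50,
                            min_copies_for_reporting = 10,
                            flank_bp = 1000, window_bp = 100,
                            n_flank_windows = 20,
                            seed = 1, n_trees = 1000, train_frac = 0.5,
                            importance_repeats = 5,
                            ice_features = c("length_bp", "dist_gene")) {
  cfg <- list(
    input_dir = input_dir, output_dir = output_dir, mu = mu,
    min_surviving_bp = min_surviving_bp,
    min_copies_for_reporting = min_copies_for_reporting,
    flank_bp = flank_bp, window_bp = window_bp,
    n_flank_windows = n_flank_windows, seed = as.integer(seed),
    n_trees = n_trees, train_frac = train_frac,
    importance_repeats = importance_repeats, ice_features = ice_features
  )
  for (f in c("mu", "min_surviving_bp", "flank_bp", "window_bp", "n_trees",
              "train_frac", "importance_repeats")) {
    if (!is_scalar_number(cfg[[f]]) || cfg[[f]] <= 0) {
      abort(paste0("pipeline config: ", f, " must be a positive number"))
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  yaml::write_yaml(unclass(config), f)
  unname(tools::md5sum(f))
}

#' Run the full TE genomic-ecology pipeline
#'
#' Executes the stages in dependency order on the layers under
#' `config$input_dir`: nesting resolution, autonomy classification, LTR-LTR
#' and terminal-branch ages, base-composition, context, methylation-profile
#' and expression features, feature assembly, random-forest age model,
#' permutation importance, per-family correlations and ICE curves. Every
#' table is written to `config$output_dir` along with a deterministic
#' `model_report.json` stamped with the config hash and seed. A rerun with
#' an unchanged config and stamp skips straight to the stored report.
#'
#' @param config A `pipeline_config` (or path to its YAML).
#' @param force Rerun even when an up-to-date report exists.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, force = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  report_path <- file.path(out, "model_report.json")
  if (!force && file.exists(report_path)) {
    prev <- jsonlite::read_json(report_path)
    if (identical(prev$config_hash, hash)) {
      message("pipeline: outputs up to date for this config; skipping (force = TRUE reruns)")
      return(invisible(NULL))
    }
  }
  msg <- function(...) message("pipeline: ", ...)

  msg("reading inputs from ", config$input_dir)
  ds <- read_dataset(config$input_dir)
  chrom_lengths <- vapply(ds$genome, nchar, numeric(1))

  msg("resolving nested insertions")
  resolved <- resolve_nesting(ds$te_copies, config$min_surviving_bp)
  readr::write_tsv(resolved$segments, file.path(out, "segments.tsv"))
  readr::write_tsv(
    resolved$copies %>% select(-"longest_orf_aa"),
    file.path(out, "copy_summary.tsv")
  )
  kept <- resolved$copies %>% filter(!.data$dropped)

  msg("classifying autonomy")
  autonomy <- classify_autonomy(
    ds$te_copies, ds$domain_hits,
    dropped = resolved$copies$copy_id[resolved$copies$dropped]
  )

  msg("estimating ages")
  tbl_ages <- bind_rows(lapply(ds$trees, terminal_branch_ages, mu = config$mu))
  ltr <- if (length(ds$ltr_alignments) > 0) {
    ltr_ages(ds$ltr_alignments, mu = config$mu)
  } else {
    NULL
  }
  ages <- tbl_ages %>% select("copy_id", "age_years")
  readr::write_tsv(
    bind_rows(
      tbl_ages %>% select("copy_id", "method", "age_years"),
      if (!is.null(ltr)) ltr %>% select("copy_id", "method", "age_years")
    ),
    file.path(out, "ages.tsv")
  )

  msg("composition features")
  comp <- composition_features(resolved, ds$genome, config$flank_bp)

  msg("context features")
  ctx <- context_features(
    resolved, ds$genes, ds$syntenic_ids, ds$genetic_map, ds$mnase,
    ds$variants, ds$subgenomes, config$flank_bp, chrom_lengths
  )

  msg("methylation profiles")
  prof <- te_methylation_profile(
    resolved, ds$methylation, chrom_lengths,
    window_bp = config$window_bp, n_flank = config$n_flank_windows
  )
  prof <- impute_missing(prof, kept)
  readr::write_tsv(prof, file.path(out, "methylation_profiles.tsv"))
  meth_feats <- methylation_feature_table(prof)

  msg("expression summaries")
  genic <- ctx %>% select("copy_id", genic = "within_transcript")
  copy_fams <- kept %>%
    select("copy_id", "family_id") %>%
    left_join(genic, by = "copy_id")
  te_rpm <- per_copy_family_rpm(
    ds$expression$te_counts, ds$expression$library_sizes, copy_fams
  )
  te_summary <- summarize_expression(
    te_rpm %>% select(entity_id = "family_id", "tissue", value = "per_copy_rpm")
  )
  gene_rpm <- per_copy_family_rpm(
    ds$expression$gene_counts %>% rename(family_id = "gene_id"),
    ds$expression$library_sizes,
    tibble(family_id = ds$genes$gene_id, n_copies = 1L)
  )
  gene_summary <- summarize_expression(
    gene_rpm %>% select(entity_id = "family_id", "tissue", value = "per_copy_rpm")
  )
  readr::write_tsv(
    bind_rows(
      te_summary %>% mutate(kind = "te_family"),
      gene_summary %>% mutate(kind = "gene")
    ),
    file.path(out, "expression_summary.tsv")
  )
  expr_feats <- kept %>%
    select("copy_id", "family_id") %>%
    left_join(te_summary %>%
                rename(te_median_expr = "median_expr", te_tau = "tau"),
              by = c("family_id" = "entity_id")) %>%
    left_join(
      ctx %>% select("copy_id", "closest_gene_id") %>%
        left_join(gene_summary %>%
                    rename(gene_median_expr = "median_expr", gene_tau = "tau"),
                  by = c("closest_gene_id" = "entity_id")) %>%
        select(-"closest_gene_id"),
      by = "copy_id"
    ) %>%
    select(-"family_id")

  msg("family summaries")
  fam_sum <- family_summary(
    resolved, ages, ctx %>% select("copy_id", "dist_gene", "subgenome"),
    autonomy, config$min_copies_for_reporting
  )
  readr::write_tsv(fam_sum, file.path(out, "family_summary.tsv"))
  readr::write_tsv(
    family_age_histogram(ages %>%
                           left_join(kept[, c("copy_id", "family_id")],
                                     by = "copy_id")),
    file.path(out, "age_histogram.tsv")
  )

  msg("assembling feature table")
  autonomy_feats <- autonomy %>%
    transmute(
      .data$copy_id,
      status_coding = as.numeric(.data$status == "autonomous_coding"),
      status_partial = as.numeric(.data$status == "partial_coding"),
      family_has_coding_member = as.numeric(.data$family_has_coding_member)
    )
  orf <- ds$te_copies %>% select("copy_id", "longest_orf_aa")
  table <- assemble_features(
    resolved, comp, ctx, meth_feats, expr_feats, autonomy_feats, orf
  )
  readr::write_tsv(table$features, file.path(out, "feature_table.tsv"))
  readr::write_tsv(table$categories, file.path(out, "feature_categories.tsv"))

  msg("fitting age model (", config$n_trees, " trees)")
  model <- fit_age_model(
    table, ages,
    seed = config$seed, n_trees = config$n_trees,
    train_frac = config$train_frac
  )

  msg("permutation importance")
  imp <- permutation_importance(model, n_repeats = config$importance_repeats,
                                seed = config$seed)
  readr::write_tsv(imp$features, file.path(out, "importance.tsv"))
  readr::write_tsv(imp$categories, file.path(out, "category_importance.tsv"))

  msg("family correlations")
  top_feats <- head(imp$features$feature[!imp$features$zero_variance], 30)
  top_feats <- setdiff(top_feats, c("superfamily", "family"))
  fams_for_r <- fam_sum %>% filter(.data$reportable) %>% pull(.data$family_id)
  corr <- family_feature_correlations(
    table$features %>%
      left_join(kept[, c("copy_id", "family_id")], by = "copy_id"),
    ages, families = head(fams_for_r, 5), feature_names = top_feats
  )
  readr::write_tsv(corr, file.path(out, "family_correlations.tsv"))

  msg("ICE curves")
  ice <- list()
  for (f in intersect(config$ice_features, names(model$x))) {
    ice[[f]] <- ice_curves(model, f)
    readr::write_tsv(ice[[f]]$curves,
                     file.path(out, paste0("ice_", f, ".tsv")))
  }

  report <- list(
    config_hash = hash,
    seed = config$seed,
    n_copies = nrow(ds$te_copies),
    n_copies_kept = nrow(kept),
    n_copies_dropped = sum(resolved$copies$dropped),
    n_features = ncol(table$features) - 1,
    n_trees = config$n_trees,
    n_train = length(model$train),
    n_test = length(model$test),
    mse_test = model$mse_test,
    rmse_test_kya = sqrt(model$mse_test) / 1000,
    variance_explained = model$variance_explained,
    top_features = head(imp$features$feature, 10),
    category_importance = setNames(
      as.list(imp$categories$delta_mse), imp$categories$category
    )
  )
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  msg("done; report at ", report_path)
  invisible(list(
    resolved = resolved, autonomy = autonomy, ages = ages, ltr_ages = ltr,
    composition = comp, context = ctx, methylation = prof,
    expression = list(te = te_summary, gene = gene_summary),
    family_summary = fam_sum, features = table, model = model,
    importance = imp, correlations = corr, ice = ice, report = report
  ))
}
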