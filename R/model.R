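# Random-forest model of TE age and its interpretation suite: permutation
# importance (scaled by its standard deviation and as RMSE increase in kya),
# category aggregation, per-family Pearson correlations, and individual
# conditional expectation (ICE) curves.

FEATURE_CATEGORIES <- c(
  "TE taxonomy", "TE base composition",
  "TE methylation and chromatin accessibility", "TE expression",
  "TE-encoded proteins", "nearest gene expression",
  "regional base composition",
  "regional methylation and chromatin accessibility",
  "regional recombination and selection"
)

#' Default feature-to-category map
#'
#' Assigns each feature name to one of the nine interpretation categories by
#' naming convention: `_te` / `_flank` suffixes separate TE-level from
#' regional measures, `m{CG,CHG,CHH}_` prefixes are methylation profile
#' slots (`_body` = TE, flank slots = regional), `mnase_*` chromatin
#' accessibility, `gene_*` nearest-gene expression, etc.
#'
#' @param feature_names Character vector of feature column names.
#' @return Tibble `feature`, `category`; errors on a name it cannot place.
#' @export
default_feature_categories <- function(feature_names) {
  cat_of <- function(f) {
    if (f %in% c("superfamily", "family", "te_order", "te_class",
                 "length_bp", "span_bp", "n_segments", "disrupted",
                 "within_te", "nesting_depth")) {
      return("TE taxonomy")
    }
    if (str_detect(f, "^(gc|p_cg|p_chg|p_chh|p_tgca)_te$")) {
      return("TE base composition")
    }
    if (str_detect(f, "^(gc|p_cg|p_chg|p_chh|p_tgca)_flank$")) {
      return("regional base composition")
    }
    if (str_detect(f, "^m(CG|CHG|CHH)_.*_body$")) {
      return("TE methylation and chromatin accessibility")
    }
    if (str_detect(f, "^m(CG|CHG|CHH)_.*_(up|dn)[0-9]+$")) {
      return("regional methylation and chromatin accessibility")
    }
    if (str_detect(f, "^mnase_(count|prop)_te")) {
      return("TE methylation and chromatin accessibility")
    }
    if (str_detect(f, "^mnase_(count|prop)_flank")) {
      return("regional methylation and chromatin accessibility")
    }
    if (f %in% c("te_median_expr", "te_tau") || str_starts(f, "te_expr")) {
      return("TE expression")
    }
    if (str_starts(f, "gene_") || str_starts(f, "syntenic_gene_") ||
        f %in% c("dist_gene", "dist_syntenic_gene", "within_transcript")) {
      return("nearest gene expression")
    }
    if (f %in% c("status_coding", "status_partial", "family_has_coding_member",
                 "longest_orf_aa") || str_starts(f, "domain_")) {
      return("TE-encoded proteins")
    }
    if (f %in% c("cm_mb", "segsites_per_bp_te", "segsites_per_bp_flank") ||
        str_starts(f, "subgenome")) {
      return("regional recombination and selection")
    }
    NA_character_
  }
  out <- tibble(
    feature = feature_names,
    category = vapply(feature_names, cat_of, character(1))
  )
  if (anyNA(out$category)) {
    abort(paste0(
      "no category for feature(s): ",
      paste(head(out$feature[is.na(out$category)], 5), collapse = ", ")
    ))
  }
  out
}

#' Assemble the per-copy feature matrix for the age model
#'
#' Left-joins stage outputs on the non-dropped copies of a resolved
#' annotation, codes every missing numeric cell as -1, converts logical
#' columns to 0/1, and caps the `family` factor at the `max_family_levels`
#' largest families (by copy number, ties by id) plus a `"smaller"` level.
#' Every feature is assigned to exactly one interpretation category.
#'
#' @param resolved A `resolved_annotation` (or a copies tibble with
#'   `copy_id`, `family_id`, `superfamily` and no `dropped` rows).
#' @param ... Stage output tibbles, each keyed by `copy_id`.
#' @param categories Optional tibble `feature`, `category`; defaults to
#'   [default_feature_categories()] over the assembled columns.
#' @param max_family_levels Number of family levels kept (default 31).
#' @return Object of class `te_feature_table`: list with `features` (tibble,
#'   first column `copy_id`, no missing cells) and `categories`.
#' @export
assemble_features <- function(resolved, ..., categories = NULL,
                              max_family_levels = 31) {
  base <- if (inherits(resolved, "resolved_annotation")) {
    resolved$copies %>%
      filter(!.data$dropped) %>%
      select("copy_id", "family_id", "superfamily", "surviving_bp", "span_bp",
             "n_segments", "disrupted", "within_te") %>%
      rename(length_bp = "surviving_bp")
  } else {
    as_tibble(resolved)
  }
  if (anyDuplicated(base$copy_id)) abort("duplicate copy_ids in feature input")
  stages <- list(...)
  df <- base
  for (s in stages) {
    if (is.null(s)) next
    if (!"copy_id" %in% names(s)) abort("every stage table must have a copy_id column")
    if (anyDuplicated(s$copy_id)) abort("duplicate copy_ids in a stage table")
    df <- df %>% left_join(s, by = "copy_id")
  }
  # family capped at the largest levels
  fam_rank <- df %>%
    count(.data$family_id, sort = TRUE) %>%
    arrange(desc(.data$n), .data$family_id)
  keep_fams <- head(fam_rank$family_id, max_family_levels)
  df <- df %>%
    mutate(
      family = ifelse(.data$family_id %in% keep_fams, .data$family_id, "smaller")
    ) %>%
    select(-"family_id")
  # logical -> numeric, subgenome -> indicators, character categoricals kept
  df <- df %>% mutate(across(where(is.logical), as.numeric))
  if ("subgenome" %in% names(df)) {
    df <- df %>%
      mutate(
        subgenome_A = as.numeric(.data$subgenome == "A"),
        subgenome_B = as.numeric(.data$subgenome == "B")
      ) %>%
      select(-"subgenome")
    }
  # drop id-like helper columns that are not features
  drop_cols <- intersect(
    c("closest_gene_id", "closest_syntenic_gene_id", "chrom", "start", "end",
      "strand", "parent_te", "order", "te_class", "nesting_depth"),
    names(df)
  )
  df <- df %>% select(-dplyr::all_of(drop_cols))
  num_cols <- setdiff(names(df)[vapply(df, is.numeric, logical(1))], "copy_id")
  df <- df %>% mutate(across(dplyr::all_of(num_cols), ~ replace_na(.x, -1)))
  if (anyNA(df)) abort("non-numeric feature column contains missing values")
  feature_names <- setdiff(names(df), "copy_id")
  if (is.null(categories)) categories <- default_feature_categories(feature_names)
  missing_cat <- setdiff(feature_names, categories$feature)
  if (length(missing_cat) > 0) {
    abort(paste0("feature without category: ", paste(head(missing_cat, 5), collapse = ", ")))
  }
  structure(
    list(features = df, categories = categories[categories$feature %in% feature_names, ]),
    class = "te_feature_table"
  )
}

#' @export
print.te_feature_table <- function(x, ...) {
  cat("<te_feature_table> ", nrow(x$features), " copies x ",
      ncol(x$features) - 1, " features in ",
      length(unique(x$categories$category)), " categories\n", sep = "")
  invisible(x)
}

# feature tibble -> model-ready data.frame (factors for categoricals)
features_to_frame <- function(features) {
  df <- as.data.frame(features[, setdiff(names(features), "copy_id")])
  for (j in seq_along(df)) {
    if (is.character(df[[j]])) df[[j]] <- factor(df[[j]])
  }
  df
}

#' Fit the random-forest TE age model
#'
#' Trains a regression forest of `n_trees` trees on a uniform random
#' `train_frac` split of copies; the held-out copies form the test set on
#' which variance explained and MSE are reported and all interpretation
#' (permutation importance, ICE) is evaluated.
#'
#' @param table A `te_feature_table` or plain tibble of features (may
#'   include `copy_id`).
#' @param ages Numeric vector aligned to rows, or tibble `copy_id`,
#'   `age_years`.
#' @param seed Integer seed controlling the split and the forest.
#' @param n_trees Number of trees (default 1000).
#' @param train_frac Training fraction (default 0.5).
#' @param split_seed Seed for the train/test split only (defaults to `seed`;
#'   set separately to vary the forest while holding the split fixed).
#' @return Object of class `te_age_model`.
#' @export
fit_age_model <- function(table, ages, seed = 1, n_trees = 1000,
                          train_frac = 0.5, split_seed = seed) {
  categories <- NULL
  if (inherits(table, "te_feature_table")) {
    categories <- table$categories
    table <- table$features
  }
  copy_ids <- if ("copy_id" %in% names(table)) table$copy_id else
    as.character(seq_len(nrow(table)))
  if (is.data.frame(ages)) {
    ages <- ages$age_years[match(copy_ids, ages$copy_id)]
  }
  if (length(ages) != nrow(table)) abort("ages must align with feature rows")
  if (anyNA(ages)) abort("missing ages")
  n <- nrow(table)
  if (n < 50) abort("need at least 50 copies to fit the age model")
  x <- features_to_frame(table)
  set.seed(as.integer(split_seed))
  train <- sort(sample.int(n, size = floor(n * train_frac)))
  test <- setdiff(seq_len(n), train)
  set.seed(as.integer(seed))
  forest <- randomForest::randomForest(
    x = x[train, , drop = FALSE], y = ages[train], ntree = n_trees
  )
  pred_test <- predict(forest, x[test, , drop = FALSE])
  mse_test <- mean((pred_test - ages[test])^2)
  ve <- 1 - mse_test / mean((ages[test] - mean(ages[test]))^2)
  structure(
    list(
      forest = forest, x = x, ages = ages, copy_ids = copy_ids,
      train = train, test = test, predictions_test = pred_test,
      mse_test = mse_test, variance_explained = ve,
      n_trees = n_trees, train_frac = train_frac, seed = seed,
      categories = categories
    ),
    class = "te_age_model"
  )
}

#' @export
print.te_age_model <- function(x, ...) {
  cat("<te_age_model> ", x$n_trees, " trees; ", length(x$train), " train / ",
      length(x$test), " test copies\n", sep = "")
  cat("  test MSE: ", signif(x$mse_test, 4),
      "; variance explained: ", signif(x$variance_explained, 4), "\n", sep = "")
  invisible(x)
}

#' Permutation importance of every feature
#'
#' For each feature, its test-set column is permuted `n_repeats` times and
#' the model MSE recomputed. Reported per feature: `delta_mse` (mean MSE
#' increase), `importance` (delta_mse scaled by its standard deviation over
#' repeats) and `delta_rmse_kya` (sqrt(mean permuted MSE) - sqrt(baseline
#' MSE), in thousands of years). Per-category importance is the sum of
#' member features' `delta_mse`.
#'
#' @param model A `te_age_model`.
#' @param n_repeats Permutations per feature (default 20).
#' @param seed Seed for the permutations.
#' @return Object of class `te_importance`: list of tibbles `features`
#'   (one row per feature, sorted) and `categories`.
#' @export
permutation_importance <- function(model, n_repeats = 20, seed = 1) {
  stopifnot(inherits(model, "te_age_model"))
  xt <- model$x[model$test, , drop = FALSE]
  yt <- model$ages[model$test]
  base_mse <- model$mse_test
  set.seed(as.integer(seed))
  feats <- names(model$x)
  rows <- vector("list", length(feats))
  for (k in seq_along(feats)) {
    f <- feats[k]
    col <- xt[[f]]
    if (length(unique(col)) <= 1) {
      rows[[k]] <- tibble(
        feature = f, delta_mse = 0, importance = 0,
        delta_rmse_kya = 0, zero_variance = TRUE
      )
      next
    }
    mse_perm <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      xp <- xt
      xp[[f]] <- col[sample.int(length(col))]
      mse_perm[r] <- mean((predict(model$forest, xp) - yt)^2)
    }
    delta <- mse_perm - base_mse
    s <- sd(delta)
    rows[[k]] <- tibble(
      feature = f,
      delta_mse = mean(delta),
      importance = if (s > 0) mean(delta) / s else 0,
      delta_rmse_kya = (sqrt(mean(mse_perm)) - sqrt(base_mse)) / 1000,
      zero_variance = FALSE
    )
  }
  features <- bind_rows(rows) %>% arrange(desc(.data$delta_mse))
  categories <- NULL
  if (!is.null(model$categories)) {
    categories <- features %>%
      left_join(model$categories, by = "feature") %>%
      group_by(.data$category) %>%
      summarise(delta_mse = sum(.data$delta_mse), .groups = "drop") %>%
      arrange(desc(.data$delta_mse))
  }
  structure(
    list(features = features, categories = categories,
         base_mse = base_mse, n_repeats = n_repeats),
    class = "te_importance"
  )
}

#' @export
print.te_importance <- function(x, ...) {
  cat("<te_importance> top features by MSE increase:\n")
  print(head(x$features, 10), ...)
  invisible(x)
}

#' Per-family Pearson correlations of features with age
#'
#' For each (family, feature) pair with at least `min_copies` copies, the
#' Pearson correlation of the feature with copy age. Features with zero
#' variance within a family give a missing value.
#'
#' @param features Tibble with `copy_id`, `family` (or `family_id`) and
#'   numeric feature columns, or a `te_feature_table`.
#' @param ages Numeric vector aligned to rows or tibble `copy_id`,
#'   `age_years`.
#' @param families Families to include (default: all with enough copies).
#' @param feature_names Features to include (default: all numeric columns).
#' @param min_copies Minimum copies per family (default 3).
#' @return Tibble `family`, `feature`, `r`, `n`.
#' @export
family_feature_correlations <- function(features, ages, families = NULL,
                                        feature_names = NULL, min_copies = 3) {
  if (inherits(features, "te_feature_table")) features <- features$features
  fam_col <- if ("family" %in% names(features)) "family" else "family_id"
  if (!fam_col %in% names(features)) abort("features must carry a family column")
  if (is.data.frame(ages)) {
    ages <- ages$age_years[match(features$copy_id, ages$copy_id)]
  }
  df <- features %>% mutate(.age = ages, .family = .data[[fam_col]])
  if (is.null(feature_names)) {
    feature_names <- setdiff(
      names(df)[vapply(df, is.numeric, logical(1))],
      c(".age", "copy_id")
    )
  }
  if (is.null(families)) {
    fams <- df %>% count(.data$.family) %>% filter(.data$n >= min_copies)
    families <- fams$.family
  }
  out <- tidyr::crossing(family = families, feature = feature_names)
  out$r <- NA_real_
  out$n <- NA_integer_
  for (i in seq_len(nrow(out))) {
    sub <- df[df$.family == out$family[i], , drop = FALSE]
    out$n[i] <- nrow(sub)
    v <- sub[[out$feature[i]]]
    if (nrow(sub) >= min_copies && sd(v) > 0 && sd(sub$.age) > 0) {
      out$r[i] <- cor(v, sub$.age)
    }
  }
  out
}

#' Individual conditional expectation (ICE) curves
#'
#' For one numeric feature, predictions are generated for every test-set
#' copy at each of `n_grid` evenly spaced values spanning the central
#' `coverage` share of the observed feature (2.5th to 97.5th percentile for
#' the default 0.95), holding all other features at the copy's observed
#' values. Deviations are prediction minus the copy's observed age;
#' per-superfamily mean curves are included.
#'
#' @param model A `te_age_model`.
#' @param feature Name of a numeric feature.
#' @param n_grid Grid size (default 20).
#' @param coverage Central share of observed values spanned (default 0.95).
#' @return Object of class `te_ice`: list with `curves` (long tibble
#'   `copy_id`, `superfamily`, `grid_value`, `prediction`, `deviation`),
#'   `group_means`, `grid`, `feature`.
#' @export
ice_curves <- function(model, feature, n_grid = 20, coverage = 0.95) {
  stopifnot(inherits(model, "te_age_model"))
  if (!feature %in% names(model$x)) abort(paste0("no such feature: ", feature))
  if (!is.numeric(model$x[[feature]])) {
    abort("ICE curves are defined for numeric features (categorical substitution is out of scope)")
  }
  obs <- model$x[[feature]]
  alpha <- (1 - coverage) / 2
  qs <- quantile(obs, c(alpha, 1 - alpha), names = FALSE, type = 7)
  grid <- seq(qs[1], qs[2], length.out = n_grid)
  xt <- model$x[model$test, , drop = FALSE]
  ids <- model$copy_ids[model$test]
  yt <- model$ages[model$test]
  sf <- if ("superfamily" %in% names(xt)) as.character(xt$superfamily) else "all"
  curves <- map(seq_along(grid), function(g) {
    xp <- xt
    xp[[feature]] <- grid[g]
    tibble(
      copy_id = ids, superfamily = sf, grid_value = grid[g],
      prediction = as.numeric(predict(model$forest, xp)),
      observed_age = yt
    )
  }) %>%
    list_rbind() %>%
    mutate(deviation = .data$prediction - .data$observed_age)
  group_means <- curves %>%
    group_by(.data$superfamily, .data$grid_value) %>%
    summarise(
      mean_prediction = mean(.data$prediction),
      mean_deviation = mean(.data$deviation),
      .groups = "drop"
    )
  structure(
    list(curves = curves, group_means = group_means, grid = grid,
         feature = feature, coverage = coverage),
    class = "te_ice"
  )
}

#' @export
print.te_ice <- function(x, ...) {
  cat("<te_ice> feature '", x$feature, "', ", length(x$grid),
      " grid values over the central ", x$coverage * 100,
      "% of observed data\n", sep = "")
  invisible(x)
}
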