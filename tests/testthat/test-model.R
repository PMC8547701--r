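# compact recovery harness shared by the model tests
harness <- function(n = 600, seed = 1, noise_sd = 5e4, n_decoys = 10) {
  generate_age_features(
    n,
    list(x1 = list(shape = "linear", coef = 2e5)),
    noise_sd = noise_sd, seed = seed, n_decoys = n_decoys
  )
}

test_that("feature assembly codes missing as -1 and caps family levels", {
  set.seed(71)
  n_fam <- 40
  fams <- sprintf("RLG%05d", 1:n_fam)
  sizes <- c(rep(5, 5), rep(2, 35)) # 40 families, 31 kept + 9 "smaller"
  copies <- mk_copies(
    sprintf("c%03d", seq_len(sum(sizes))),
    rep(fams, sizes),
    seq(0, by = 2000, length.out = sum(sizes)),
    seq(0, by = 2000, length.out = sum(sizes)) + 1000
  )
  r <- resolve_nesting(copies)
  stage <- tibble::tibble(
    copy_id = copies$copy_id[1:50], # the rest are missing
    gc_te = runif(50)
  )
  ft <- assemble_features(r, stage)
  expect_s3_class(ft, "te_feature_table")
  expect_equal(sum(ft$features$gc_te == -1), nrow(copies) - 50)
  expect_equal(dplyr::n_distinct(ft$features$family), 32)
  expect_equal(sum(ft$features$family == "smaller"), 9 * 2)
  expect_setequal(ft$categories$feature, setdiff(names(ft$features), "copy_id"))
  expect_false(anyNA(ft$features))

  dup <- dplyr::bind_rows(stage, stage[1, ])
  expect_error(assemble_features(r, dup), "duplicate copy_ids")
  expect_error(default_feature_categories("mystery_feature"), "no category")
})

test_that("the forest recovers a noiseless signal and not pure noise", {
  h <- harness(n = 2000, noise_sd = 0, n_decoys = 5)
  m <- fit_age_model(h$features, h$ages, seed = 1, n_trees = 300)
  expect_gte(m$variance_explained, 0.9)

  h0 <- generate_age_features(
    500, list(x1 = list(shape = "linear", coef = 0)),
    noise_sd = 1e5, seed = 4, n_decoys = 10
  )
  m0 <- fit_age_model(h0$features, h0$ages, seed = 1, n_trees = 200)
  expect_lte(m0$variance_explained, 0.05)

  expect_error(fit_age_model(h$features[1:20, ], h$ages[1:20]), "at least 50")
})

test_that("the same seed reproduces split and predictions exactly", {
  h <- harness(n = 300, seed = 2)
  m1 <- fit_age_model(h$features, h$ages, seed = 7, n_trees = 100)
  m2 <- fit_age_model(h$features, h$ages, seed = 7, n_trees = 100)
  expect_identical(m1$train, m2$train)
  expect_identical(m1$predictions_test, m2$predictions_test)
  m3 <- fit_age_model(h$features, h$ages, seed = 8, n_trees = 100)
  expect_false(identical(m1$train, m3$train))
})

test_that("permutation importance separates causal from decoy features", {
  h <- harness(n = 600, seed = 3, noise_sd = 3e4)
  m <- fit_age_model(h$features, h$ages, seed = 1, n_trees = 150)
  imp <- permutation_importance(m, n_repeats = 5, seed = 1)
  expect_setequal(imp$features$feature, names(m$x))
  expect_equal(imp$features$feature[1], "x1")
  decoys <- imp$features[grepl("^decoy", imp$features$feature), ]
  expect_lt(max(abs(decoys$delta_rmse_kya)), imp$features$delta_rmse_kya[1] / 5)

  # a constant column is flagged with zero importance
  h2 <- h
  h2$features$flat <- 1
  m2 <- fit_age_model(h2$features, h2$ages, seed = 1, n_trees = 50)
  imp2 <- permutation_importance(m2, n_repeats = 3, seed = 1)
  flat <- imp2$features[imp2$features$feature == "flat", ]
  expect_true(flat$zero_variance)
  expect_equal(flat$delta_mse, 0)
})

test_that("category importances cover the manifest and sum by construction", {
  ds <- toy_dataset()
  r <- resolve_nesting(ds$te_copies)
  comp <- composition_features(r, ds$genome)
  ft <- assemble_features(r, comp)
  ages <- dplyr::bind_rows(lapply(ds$trees, terminal_branch_ages))
  m <- fit_age_model(ft, ages %>% dplyr::select(copy_id, age_years),
                     seed = 1, n_trees = 100)
  imp <- permutation_importance(m, n_repeats = 3, seed = 1)
  joined <- imp$features %>%
    dplyr::left_join(ft$categories, by = "feature") %>%
    dplyr::group_by(category) %>%
    dplyr::summarise(s = sum(delta_mse))
  expect_equal(
    sort(imp$categories$delta_mse),
    sort(joined$s),
    tolerance = 1e-9
  )
})

test_that("family correlations match the closed-form Pearson formula", {
  set.seed(72)
  feats <- tibble::tibble(
    copy_id = sprintf("c%03d", 1:60),
    family = rep(c("RLG00001", "RLG00002", "RLC00001"), each = 20),
    x = rnorm(60), const = 5
  )
  ages <- 2 * feats$x + rnorm(60, sd = 0.1)
  ages[feats$family == "RLG00002"] <- -3 * feats$x[feats$family == "RLG00002"] +
    rnorm(20, sd = 0.1)
  r <- family_feature_correlations(feats, ages, feature_names = c("x", "const"))
  # exact linear relation within a family gives r near +-1 with correct sign
  expect_gt(r$r[r$family == "RLG00001" & r$feature == "x"], 0.99)
  expect_lt(r$r[r$family == "RLG00002" & r$feature == "x"], -0.99)
  expect_true(all(is.na(r$r[r$feature == "const"])))

  # closed-form covariance oracle
  sub <- feats[feats$family == "RLC00001", ]
  a_sub <- ages[feats$family == "RLC00001"]
  oracle <- sum((sub$x - mean(sub$x)) * (a_sub - mean(a_sub))) /
    sqrt(sum((sub$x - mean(sub$x))^2) * sum((a_sub - mean(a_sub))^2))
  expect_equal(r$r[r$family == "RLC00001" & r$feature == "x"], oracle,
               tolerance = 1e-12)

  # exact relation age = 2 * feature
  feats2 <- tibble::tibble(copy_id = as.character(1:10),
                           family = "DTA00001", x = 1:10)
  r2 <- family_feature_correlations(feats2, 2 * feats2$x)
  expect_equal(r2$r[r2$feature == "x"], 1.0)
})

test_that("ICE grids span the central 95% and recover a linear slope", {
  h <- harness(n = 1500, seed = 5, noise_sd = 0, n_decoys = 5)
  m <- fit_age_model(h$features, h$ages, seed = 1, n_trees = 200)
  ice <- ice_curves(m, "x1", n_grid = 20)
  obs <- m$x$x1
  expect_equal(min(ice$grid), unname(quantile(obs, 0.025)))
  expect_equal(max(ice$grid), unname(quantile(obs, 0.975)))

  # slope read over the interior of the grid (ensemble predictions flatten
  # at the edges of the feature support)
  interior <- ice$group_means %>%
    dplyr::filter(grid_value > ice$grid[3], grid_value < ice$grid[18])
  slopes <- interior %>%
    dplyr::group_by(superfamily) %>%
    dplyr::summarise(slope = coef(lm(mean_prediction ~ grid_value))[2])
  expect_equal(mean(slopes$slope), 2e5, tolerance = 0.15)

  expect_error(ice_curves(m, "superfamily"), "numeric features")
  expect_error(ice_curves(m, "nope"), "no such feature")
})

test_that("importance rankings are stable across forest seeds on a fixed split", {
  h <- harness(n = 600, seed = 6, noise_sd = 3e4)
  ranks <- lapply(c(11, 22), function(s) {
    m <- fit_age_model(h$features, h$ages, seed = s, n_trees = 200,
                       split_seed = 99)
    imp <- permutation_importance(m, n_repeats = 8, seed = 1)
    imp$features %>% dplyr::arrange(feature) %>% dplyr::pull(delta_mse)
  })
  expect_gt(cor(ranks[[1]], ranks[[2]], method = "kendall"), 0.5)
})

test_that("tidiers return the documented shapes", {
  h <- harness(n = 300, seed = 7)
  m <- fit_age_model(h$features, h$ages, seed = 1, n_trees = 50)
  g <- glance(m)
  expect_equal(nrow(g), 1)
  expect_named(g, c("n_trees", "n_train", "n_test", "mse_test",
                    "rmse_test_kya", "variance_explained"))
  td <- tidy(m)
  expect_true("x1" %in% td$term)
  imp <- permutation_importance(m, n_repeats = 2, seed = 1)
  expect_true(all(c("term", "delta_rmse_kya") %in% names(tidy(imp))))
  ice <- ice_curves(m, "x1", n_grid = 5)
  expect_true(all(c("superfamily", "grid_value") %in% names(tidy(ice))))
  expect_s3_class(plot_ice(ice), "ggplot")
  expect_s3_class(autoplot(imp), "ggplot")
})
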