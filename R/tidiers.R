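# broom-style tidiers for fitted objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted TE age model
#'
#' One row per feature with the forest's internal node-purity importance.
#' For the permutation importance used for interpretation, see
#' [permutation_importance()] and its own [tidy()] method.
#'
#' @param x A `te_age_model`.
#' @param ... Unused.
#' @return Tibble `term`, `node_purity`.
#' @export
tidy.te_age_model <- function(x, ...) {
  imp <- randomForest::importance(x$forest)
  tibble(term = rownames(imp), node_purity = imp[, 1]) %>%
    arrange(desc(.data$node_purity))
}

#' One-row summary of a fitted TE age model
#'
#' @param x A `te_age_model`.
#' @param ... Unused.
#' @return Tibble with `n_trees`, `n_train`, `n_test`, `mse_test`,
#'   `rmse_test_kya`, `variance_explained`.
#' @export
glance.te_age_model <- function(x, ...) {
  tibble(
    n_trees = x$n_trees,
    n_train = length(x$train),
    n_test = length(x$test),
    mse_test = x$mse_test,
    rmse_test_kya = sqrt(x$mse_test) / 1000,
    variance_explained = x$variance_explained
  )
}

#' Tidy a permutation-importance result
#'
#' @param x A `te_importance`.
#' @param ... Unused.
#' @return Tibble `term`, `delta_mse`, `importance`, `delta_rmse_kya`,
#'   `zero_variance`.
#' @export
tidy.te_importance <- function(x, ...) {
  x$features %>% rename(term = "feature")
}

#' Tidy ICE curves to their per-superfamily means
#'
#' @param x A `te_ice`.
#' @param ... Unused.
#' @return Tibble `superfamily`, `grid_value`, `mean_prediction`,
#'   `mean_deviation`.
#' @export
tidy.te_ice <- function(x, ...) {
  x$group_means
}
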