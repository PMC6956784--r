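#' Random-forest regression of p-affinity
#'
#' A bagged ensemble of CART regression trees with per-node feature
#' subsampling, the field's workhorse for QSAR-style tabular regression.
#' The single tuned hyperparameter is `mtry` (features tried per split);
#' candidates are scored by repeated stratified cross-validation at the
#' ligand level and the RMSE-minimizing value is refit on the full table.
#' Importance is the total impurity (SSE) decrease credited to each feature,
#' normalized so the top feature scores 100.
#'
#' @name learner
NULL

default_mtry_grid <- function(p)
  sort(unique(pmax(1L, c(p %/% 3L, floor(sqrt(p)), p %/% 2L))))

dataset_matrix <- function(table, features = NULL) {
  features <- features %||% feature_names(table)
  miss <- setdiff(features, names(table))
  if (length(miss))
    stop_dockrf("missing feature column(s): %s", paste(miss, collapse = ", "),
                class = "dockrf_schema_error")
  X <- as.matrix(table[, features, drop = FALSE])
  if (!is.numeric(X))
    stop_dockrf("non-numeric feature column(s): %s",
                paste(features[!vapply(table[features], is.numeric, TRUE)],
                      collapse = ", "),
                class = "dockrf_validation_error")
  na_cols <- features[colSums(is.na(X)) > 0]
  if (length(na_cols))
    stop_dockrf("missing values in feature column(s): %s",
                paste(na_cols, collapse = ", "),
                class = "dockrf_validation_error")
  X
}

rf_engine <- function(n_trees, min_node, sample_fraction, replace) {
  list(
    fit = function(X, y, mtry, seed)
      .rf_fit_cpp(X, y, n_trees, mtry, min_node, sample_fraction, replace,
                  as.integer(seed %% .Machine$integer.max)),
    predict = function(fit, X) .rf_predict_cpp(fit, X),
    importance = function(fit) fit$importance)
}

#' Train a random-forest affinity model
#'
#' @param table a `dockrf_dataset` (label column `p_affinity`).
#' @param k,repeats,n_bins cross-validation layout used for `mtry`
#'   selection (defaults 10-fold; `repeats` defaults to 3 for tuning --
#'   the full 10x10 protocol is available but slow).
#' @param mtry_grid candidate `mtry` values; default
#'   `{p/3, sqrt(p), p/2}` (floored, deduplicated). A length-1 grid skips
#'   cross-validation.
#' @param n_trees trees in the final forest (default 500).
#' @param cv_trees trees per cross-validation fit (default
#'   `min(n_trees, 150)`; tuning needs many fits).
#' @param min_node minimum node size to attempt a split (default 5).
#' @param sample_fraction,replace bootstrap controls (defaults 1, TRUE).
#' @param seed integer; fits are fully reproducible from it.
#' @param engine optional plug-in regressor: a list with `fit(X, y, mtry,
#'   seed)`, `predict(fit, X)` and optionally `importance(fit)`, letting any
#'   regressor honoring those contracts slot into the pipeline.
#' @return a `dockrf_rf` model with `cv_summary` (per-mtry mean/sd of CV
#'   RMSE and R2), frozen feature schema and training metadata.
#' @export
train_rf <- function(table, k = 10, repeats = 3, n_bins = 5,
                     mtry_grid = NULL, n_trees = 500, cv_trees = NULL,
                     min_node = 5, sample_fraction = 1, replace = TRUE,
                     seed = 1, engine = NULL) {
  stopifnot(is.data.frame(table), "p_affinity" %in% names(table))
  feats <- feature_names(table)
  X <- dataset_matrix(table, feats)
  y <- table$p_affinity
  if (anyNA(y) || !all(is.finite(y)))
    stop_dockrf("missing values in p_affinity", class = "dockrf_validation_error")
  if (length(unique(y)) < 2L)
    stop_dockrf("constant label: nothing to learn",
                class = "dockrf_validation_error")
  p <- ncol(X)
  mtry_grid <- sort(unique(as.integer(mtry_grid %||% default_mtry_grid(p))))
  if (any(mtry_grid < 1L | mtry_grid > p))
    stop_dockrf("mtry values must lie in [1, %d]", p,
                class = "dockrf_validation_error")
  cv_trees <- cv_trees %||% min(n_trees, 150L)
  eng_cv <- engine %||% rf_engine(cv_trees, min_node, sample_fraction, replace)
  eng_final <- engine %||% rf_engine(n_trees, min_node, sample_fraction,
                                     replace)

  cv_summary <- NULL
  best_mtry <- mtry_grid[1L]
  if (length(mtry_grid) > 1L) {
    folds <- make_cv_folds(table, k = k, repeats = repeats, n_bins = n_bins,
                           seed = seed)
    res <- list()
    for (r in seq_along(folds)) {
      fold_of <- folds[[r]]
      for (f in sort(unique(fold_of))) {
        hold <- fold_of == f
        # leakage guard: a ligand must never straddle the fit/hold boundary
        if (length(intersect(table$ligand_id[hold], table$ligand_id[!hold])))
          stop_dockrf("internal error: ligand straddles a CV fold",
                      class = "dockrf_internal_error")
        for (m in mtry_grid) {
          fit <- eng_cv$fit(X[!hold, , drop = FALSE], y[!hold], m,
                            seed + 7919L * r + 131L * f + m)
          pred <- eng_cv$predict(fit, X[hold, , drop = FALSE])
          res[[length(res) + 1L]] <- data.frame(
            repeat_ = r, fold = f, mtry = m,
            rmse = sqrt(mean((y[hold] - pred)^2)),
            r2 = 1 - sum((y[hold] - pred)^2) /
                     sum((y[hold] - mean(y[hold]))^2))
        }
      }
    }
    res <- do.call(rbind, res)
    cv_summary <- do.call(rbind, lapply(split(res, res$mtry), function(g)
      data.frame(mtry = g$mtry[1L], mean_rmse = mean(g$rmse),
                 sd_rmse = sd(g$rmse), mean_r2 = mean(g$r2),
                 sd_r2 = sd(g$r2))))
    rownames(cv_summary) <- NULL
    best_mtry <- cv_summary$mtry[which.min(cv_summary$mean_rmse)]
  }

  fit <- eng_final$fit(X, y, best_mtry, seed)
  structure(list(
    algorithm = if (is.null(engine)) "random_forest" else "custom_engine",
    fit = fit,
    engine = eng_final,
    features = feats,
    mtry = best_mtry,
    n_trees = if (is.null(engine)) n_trees else NA_integer_,
    label_range = range(y),
    cv_summary = cv_summary,
    meta = list(n = nrow(X), seed = seed, k = k, repeats = repeats,
                feature_mode = attr(table, "feature_mode"))),
    class = "dockrf_rf")
}

#' @export
print.dockrf_rf <- function(x, ...) {
  cat(sprintf("<dockrf random forest> %d features, mtry = %d, trees = %s, n = %d\n",
              length(x$features), x$mtry, x$n_trees, x$meta$n))
  if (!is.null(x$cv_summary)) {
    cat("cv_summary (mtry selection):\n")
    print(x$cv_summary, row.names = FALSE)
  }
  invisible(x)
}

#' Predict p-affinity for new feature rows
#'
#' @param object a `dockrf_rf` model.
#' @param newdata a dataset/feature table carrying the model's feature
#'   columns, or a numeric matrix with matching column names.
#' @param ... unused.
#' @return numeric predictions, one per row, in row order; always inside
#'   the training label range (ensemble averages of training labels).
#' @export
predict.dockrf_rf <- function(object, newdata, ...) {
  if (is.matrix(newdata)) {
    miss <- setdiff(object$features, colnames(newdata))
    if (length(miss))
      stop_dockrf("missing feature column(s): %s", paste(miss, collapse = ", "),
                  class = "dockrf_schema_error")
    X <- newdata[, object$features, drop = FALSE]
  } else {
    extra <- setdiff(feature_names(newdata), object$features)
    if (length(extra))
      stop_dockrf("unexpected feature column(s): %s",
                  paste(extra, collapse = ", "), class = "dockrf_schema_error")
    X <- dataset_matrix(newdata, object$features)
  }
  as.numeric(object$engine$predict(object$fit, X))
}

#' Variable importance, normalized to max = 100
#'
#' Total decrease in node impurity (SSE) credited to each feature across
#' all trees and splits, scaled so the most important feature reads 100.
#'
#' @param model a fitted `dockrf_rf`.
#' @param normalize scale to max = 100 (default TRUE).
#' @return data frame `feature`, `importance`, sorted descending.
#' @export
variable_importance <- function(model, normalize = TRUE) {
  if (!inherits(model, "dockrf_rf") || is.null(model$fit))
    stop_dockrf("not a fitted dockrf_rf model", class = "dockrf_validation_error")
  if (is.null(model$engine$importance))
    stop_dockrf("engine does not expose importance",
                class = "dockrf_validation_error")
  imp <- as.numeric(model$engine$importance(model$fit))
  if (normalize && max(imp) > 0) imp <- 100 * imp / max(imp)
  out <- data.frame(feature = model$features, importance = imp,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Save / load a trained model (single versioned archive)
#'
#' The archive is an RDS file with a format-version stamp, the feature
#' schema, hyperparameters and ensemble state.
#'
#' @param model a `dockrf_rf`.
#' @param path file path.
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = "dockrf_rf/1", model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "dockrf_rf/1"))
    stop_dockrf("unrecognized model archive format",
                class = "dockrf_io_error")
  obj$model
}
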