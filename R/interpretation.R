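#' Gain-based feature importance of a fitted gradient-boosted model
#'
#' Total split gain per feature across all boosting iterations, normalized
#' so the shares sum to one. Provenance class tags from the feature table
#' are attached when supplied.
#'
#' @param fit a `fit_predict()` result for a GBDT backend (or a raw
#'   `xgb.Booster`).
#' @param classes optional named character vector of per-feature provenance
#'   classes (from a `feature_table`).
#' @return data.frame `feature`, `share`, `class`, sorted by share.
#' @export
gain_importance <- function(fit, classes = NULL) {
  model <- if (inherits(fit, "xgb.Booster")) fit else fit$model
  if (!inherits(model, "xgb.Booster"))
    stop("gain importance requires a fitted gradient-boosted tree model")
  imp <- tryCatch(xgboost::xgb.importance(model = model),
                  error = function(e) NULL)
  if (is.null(imp)) {
    # aggregate split gain from the tree dump (covers single-feature
    # models, where the engine's importance accessor fails)
    tr <- xgboost::xgb.model.dt.tree(model = model)
    tr <- tr[tr$Feature != "Leaf", , drop = FALSE]
    if (nrow(tr) == 0) stop("model contains no splits")
    g <- tapply(tr$Gain, tr$Feature, sum)
    imp <- data.frame(Feature = names(g), Gain = as.numeric(g))
    imp <- imp[order(-imp$Gain), ]
  }
  if (nrow(imp) == 0) stop("model contains no splits")
  share <- imp$Gain / sum(imp$Gain)
  out <- data.frame(feature = imp$Feature, share = share,
                    stringsAsFactors = FALSE)
  if (is.null(classes) && !inherits(fit, "xgb.Booster"))
    classes <- fit$classes
  out$class <- if (!is.null(classes))
    unname(classes[out$feature]) else NA_character_
  out[order(-out$share), ]
}

#' Partial dependence profile (Friedman estimator)
#'
#' For each grid value of the feature subset, every reference row has the
#' subset overwritten with that value and the model predictions are
#' averaged: `f_S(x_S) = mean_i f(x_S, x_iC)`. The grid defaults to 25
#' quantile-spaced points of the reference data, which keeps the profile
#' inside the observed region. When the feature was standardized, stored
#' transform parameters can map the axis back to original units.
#'
#' @param fit `fit_predict()` result (any backend) or a function
#'   `f(matrix) -> numeric`.
#' @param feature feature name (single feature, or character vector for a
#'   joint profile evaluated on a shared grid index).
#' @param reference numeric matrix of reference observations (training
#'   rows).
#' @param grid optional numeric vector (or matrix for joint profiles) of
#'   grid values; default 25 quantile points.
#' @param n_grid grid size when `grid` is not given.
#' @param transform optional `list(center, scale)` (named vectors) used to
#'   report `grid_original` alongside the standardized grid.
#' @return data.frame `feature`, `grid`, `yhat` (+ `grid_original` when a
#'   transform is given), with the per-observation feature values as the
#'   `ticks` attribute.
#' @export
partial_dependence <- function(fit, feature, reference, grid = NULL,
                               n_grid = 25, transform = NULL) {
  if (nrow(reference) == 0) stop("empty reference data")
  predict_fun <- if (is.function(fit)) fit else function(m) {
    if (fit$backend %in% c("gbdt_a", "gbdt_b"))
      stats::predict(fit$model, xgboost::xgb.DMatrix(m))
    else as.numeric(stats::predict(fit$model, m))
  }
  stopifnot(all(feature %in% colnames(reference)))
  if (is.null(grid)) {
    grid <- matrix(NA_real_, n_grid, length(feature))
    for (j in seq_along(feature))
      grid[, j] <- unname(stats::quantile(reference[, feature[j]],
                                          probs = seq(0.02, 0.98,
                                                      length.out = n_grid)))
  } else grid <- matrix(grid, ncol = length(feature))
  yhat <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    m <- reference
    for (j in seq_along(feature)) m[, feature[j]] <- grid[g, j]
    yhat[g] <- mean(predict_fun(m))
  }
  out <- data.frame(feature = paste(feature, collapse = ":"),
                    grid = grid[, 1], yhat = yhat)
  if (!is.null(transform) && length(feature) == 1 &&
      feature %in% names(transform$center)) {
    out$grid_original <- grid[, 1] * transform$scale[feature] +
      transform$center[feature]
  }
  attr(out, "ticks") <- reference[, feature[1]]
  out
}
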