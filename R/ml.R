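#' Assemble the machine-learning feature table
#'
#' Columns are marker principal-component scores, optionally the EC columns,
#' one-hot year indicators and optionally the geographic coordinates.
#' Near-zero-variance columns are removed; continuous columns are
#' standardized with statistics computed on the training rows only, and the
#' fitted transform is retained so test rows are mapped with train-time
#' means and SDs. Each column carries a provenance class used by the
#' interpretation module.
#'
#' @param pcs per-observation marker PC scores.
#' @param W EC matrix aligned with observations (`NULL` to exclude).
#' @param years per-observation year.
#' @param coords per-observation data.frame `longitude`, `latitude`
#'   (`NULL` to exclude).
#' @param include_W,include_coords inclusion flags.
#' @param train_index rows used to fit the standardization (default all).
#' @return list of class `feature_table`: `x` (numeric matrix), `classes`
#'   (per-column provenance), `transform` (center/scale/kept columns).
#' @export
build_feature_table <- function(pcs, W = NULL, years, coords = NULL,
                                include_W = TRUE, include_coords = TRUE,
                                train_index = NULL) {
  n <- nrow(pcs)
  stopifnot(length(years) == n)
  blocks <- list(as.matrix(pcs))
  classes <- rep("genomic_pc", ncol(pcs))
  if (include_W) {
    if (is.null(W)) stop("include_W = TRUE but no EC matrix supplied")
    Wm <- as.matrix(W)
    if (nrow(Wm) != n) stop("misaligned EC matrix")
    blocks <- c(blocks, list(Wm))
    cls <- ifelse(grepl("\\.SC$", colnames(Wm)), "soil",
           ifelse(colnames(Wm) %in% c("longitude", "latitude"), "coordinate",
           ifelse(grepl("\\.V$", colnames(Wm)), "weather_V",
           ifelse(grepl("\\.F$", colnames(Wm)), "weather_F", "weather_G"))))
    classes <- c(classes, cls)
  }
  yf <- factor(years)
  Ymat <- stats::model.matrix(~ 0 + yf)
  colnames(Ymat) <- paste0("year_", levels(yf))
  blocks <- c(blocks, list(Ymat))
  classes <- c(classes, rep("year", ncol(Ymat)))
  if (include_coords && !is.null(coords) &&
      !(include_W && !is.null(W) && "longitude" %in% colnames(W))) {
    cm <- as.matrix(coords[, c("longitude", "latitude")])
    blocks <- c(blocks, list(cm))
    classes <- c(classes, rep("coordinate", 2))
  }
  x <- do.call(cbind, blocks)
  if (is.null(train_index)) train_index <- seq_len(n)
  ctr <- colMeans(x[train_index, , drop = FALSE])
  scl <- apply(x[train_index, , drop = FALSE], 2, stats::sd)
  keep <- is.finite(scl) & scl > 1e-10
  is_indicator <- classes == "year"
  ctr[is_indicator] <- 0; scl[is_indicator] <- 1
  x <- x[, keep, drop = FALSE]
  classes <- classes[keep]
  ctr <- ctr[keep]; scl <- scl[keep]
  x <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  structure(list(x = x, classes = stats::setNames(classes, colnames(x)),
                 transform = list(center = ctr, scale = scl,
                                  keep = colnames(x))),
            class = "feature_table")
}

#' Fit a backend and predict
#'
#' Thin adapter over the supported model families so every engine satisfies
#' the same contract. `"elastic_net"` is a glmnet fit at a fixed penalty and
#' mixing parameter; `"gbdt_a"` and `"gbdt_b"` are gradient-boosted decision
#' trees using the two histogram-based split-finding algorithms of the
#' xgboost engine (`hist` and `approx`).
#'
#' @param backend one of `"elastic_net"`, `"gbdt_a"`, `"gbdt_b"`.
#' @param hyperparams named list; elastic net: `penalty`, `mixing`; GBDT:
#'   `learning_rate`, `max_depth`, `n_trees`, `min_child_weight`,
#'   `feature_fraction`, `subsample`.
#' @param xtrain,ytrain training data.
#' @param xtest matrix of rows to predict (`NULL` for none).
#' @param seed integer seed.
#' @return list: `pred`, `model` (fitted handle), `backend`,
#'   `feature_names`.
#' @export
fit_predict <- function(backend, hyperparams, xtrain, ytrain, xtest = NULL,
                        seed = 1L) {
  hp <- hyperparams
  if (backend == "elastic_net") {
    fit <- glmnet::glmnet(xtrain, ytrain, alpha = hp$mixing %||% 0.5,
                          lambda = hp$penalty %||% 0.01)
    pred <- if (!is.null(xtest))
      as.numeric(stats::predict(fit, xtest)) else NULL
  } else if (backend %in% c("gbdt_a", "gbdt_b")) {
    set.seed(seed)
    params <- list(
      objective = "reg:squarederror",
      eta = hp$learning_rate %||% 0.05,
      max_depth = as.integer(hp$max_depth %||% 6),
      min_child_weight = hp$min_child_weight %||% 1,
      colsample_bytree = hp$feature_fraction %||% 1,
      subsample = hp$subsample %||% 1,
      tree_method = if (backend == "gbdt_a") "hist" else "approx",
      nthread = 1
    )
    dtrain <- xgboost::xgb.DMatrix(xtrain, label = ytrain)
    fit <- xgboost::xgb.train(params, dtrain,
                              nrounds = as.integer(hp$n_trees %||% 300),
                              verbose = 0)
    pred <- if (!is.null(xtest))
      stats::predict(fit, xgboost::xgb.DMatrix(xtest)) else NULL
  } else stop("unknown backend: ", backend)
  list(pred = pred, model = fit, backend = backend,
       feature_names = colnames(xtrain))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default hyperparameter search space per backend
#'
#' @param backend backend id.
#' @return named list of dimensions `list(type, range, log)`.
#' @export
default_space <- function(backend) {
  if (backend == "elastic_net") {
    list(penalty = list(type = "num", range = c(1e-4, 1), log = TRUE),
         mixing = list(type = "num", range = c(0, 1), log = FALSE))
  } else {
    list(learning_rate = list(type = "num", range = c(1e-3, 0.3), log = TRUE),
         max_depth = list(type = "int", range = c(1, 12), log = FALSE),
         n_trees = list(type = "int", range = c(100, 2000), log = FALSE),
         min_child_weight = list(type = "num", range = c(1, 20), log = FALSE),
         feature_fraction = list(type = "num", range = c(0.3, 1), log = FALSE),
         subsample = list(type = "num", range = c(0.5, 1), log = FALSE))
  }
}

space_to_unit <- function(space, assign) {
  vapply(names(space), function(p) {
    d <- space[[p]]; v <- assign[[p]]
    r <- if (isTRUE(d$log)) log(d$range) else d$range
    x <- if (isTRUE(d$log)) log(v) else v
    if (r[2] == r[1]) 0.5 else (x - r[1]) / (r[2] - r[1])
  }, numeric(1))
}

unit_to_assign <- function(space, u) {
  out <- list()
  for (i in seq_along(space)) {
    d <- space[[i]]
    r <- if (isTRUE(d$log)) log(d$range) else d$range
    x <- r[1] + u[i] * (r[2] - r[1])
    if (isTRUE(d$log)) x <- exp(x)
    if (d$type == "int") x <- as.integer(round(x))
    out[[names(space)[i]]] <- x
  }
  out
}

inner_cv_rmse <- function(backend, assign, x, y, folds = 5, repeats = 2,
                          seed = 1L) {
  n <- length(y)
  errs <- numeric(0)
  for (r in seq_len(repeats)) {
    set.seed(seed + r)
    fold_id <- sample(rep_len(seq_len(folds), n))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- fit_predict(backend, assign, x[tr, , drop = FALSE], y[tr],
                         x[!tr, , drop = FALSE], seed = seed)
      errs <- c(errs, (fit$pred - y[!tr])^2)
    }
  }
  sqrt(mean(errs))
}

# Gaussian-process surrogate: RBF kernel on the unit cube, median-heuristic
# length scale, small nugget; expected improvement acquisition evaluated on
# random candidates.
gp_expected_improvement <- function(Xu, y, cand) {
  ys <- (y - mean(y)) / max(stats::sd(y), 1e-12)
  D2 <- as.matrix(stats::dist(Xu))^2
  ell2 <- stats::median(D2[D2 > 0])
  if (!is.finite(ell2) || ell2 <= 0) ell2 <- 1
  Kf <- exp(-0.5 * D2 / ell2) + diag(1e-4, nrow(Xu))
  L <- chol(Kf)
  alpha <- backsolve(L, forwardsolve(t(L), ys))
  # squared distances candidate-to-train
  d2 <- outer(rowSums(cand^2), rep(1, nrow(Xu))) +
    outer(rep(1, nrow(cand)), rowSums(Xu^2)) - 2 * cand %*% t(Xu)
  kx <- exp(-0.5 * pmax(d2, 0) / ell2)
  mu <- as.numeric(kx %*% alpha)
  v <- forwardsolve(t(L), t(kx))
  s2 <- pmax(1 - colSums(v^2), 1e-10)
  s <- sqrt(s2)
  best <- min(ys)
  z <- (best - mu) / s
  ei <- s * (z * stats::pnorm(z) + stats::dnorm(z))
  ei
}

#' Bayesian hyperparameter tuning with a Gaussian-process surrogate
#'
#' An initial space-filling (Latin hypercube) design is evaluated by
#' repeated inner cross-validation RMSE; a Gaussian-process surrogate then
#' proposes `n_iter` further configurations by maximizing expected
#' improvement over random candidates. Inner folds are drawn from the
#' training rows only, so nested cross-validation hygiene is preserved by
#' construction. Degenerate spaces (a single point) are evaluated once.
#'
#' @param backend backend id.
#' @param space search space (see [default_space()]).
#' @param x,y training features and response.
#' @param n_iter acquisition iterations after the initial design
#'   (default 30).
#' @param n_init initial design size (default 10).
#' @param folds,repeats inner-CV settings (default fivefold, two repeats).
#' @param seed integer seed.
#' @return list: `best` (hyperparameter assignment), `best_rmse`, `trials`
#'   (data.frame: one row per trial with the assignment and its inner-CV
#'   RMSE).
#' @export
tune_bayes_gp <- function(backend, space, x, y, n_iter = 30, n_init = 10,
                          folds = 5, repeats = 2, seed = 1L) {
  if (!length(space)) stop("empty search space")
  d <- length(space)
  degenerate <- all(vapply(space, function(s) s$range[1] == s$range[2],
                           logical(1)))
  set.seed(seed)
  if (degenerate) {
    assign <- unit_to_assign(space, rep(0.5, d))
    rmse <- inner_cv_rmse(backend, assign, x, y, folds, repeats, seed)
    trials <- cbind(as.data.frame(assign), rmse = rmse, iteration = 1L)
    return(list(best = assign, best_rmse = rmse, trials = trials))
  }
  U <- lhs::randomLHS(n_init, d)
  trials <- NULL
  Xu <- NULL
  rmses <- numeric(0)
  eval_point <- function(u, it) {
    assign <- unit_to_assign(space, u)
    rmse <- inner_cv_rmse(backend, assign, x, y, folds, repeats, seed)
    trials <<- rbind(trials, cbind(as.data.frame(assign), rmse = rmse,
                                   iteration = it))
    Xu <<- rbind(Xu, u)
    rmses <<- c(rmses, rmse)
  }
  for (i in seq_len(n_init)) eval_point(U[i, ], i)
  for (it in seq_len(n_iter)) {
    cand <- matrix(stats::runif(500 * d), ncol = d)
    ei <- gp_expected_improvement(Xu, rmses, cand)
    eval_point(cand[which.max(ei), ], n_init + it)
  }
  best <- which.min(rmses)
  list(best = unit_to_assign(space, Xu[best, ]), best_rmse = rmses[best],
       trials = trials)
}

#' Hyperparameter importance by fANOVA over a random-forest surrogate
#'
#' Fits a random forest to the tuning log (hyperparameters, encoded to the
#' unit cube, explaining the inner-CV RMSE) and decomposes each tree's
#' variance over its axis-aligned leaf partition: the marginal of a subset
#' of hyperparameters is piecewise constant, so main-effect and pairwise
#' interaction variance shares are computed exactly per tree from the leaf
#' boxes and averaged across trees. Shares are nonnegative and the reported
#' (main + pairwise) shares sum to at most 1.
#'
#' @param trials tuning log from [tune_bayes_gp()] (needs >= 20 rows).
#' @param num_trees forest size (default 100).
#' @param seed integer seed.
#' @return data.frame `term` (hyperparameter or `a:b` pair), `share`.
#' @export
fanova_importance <- function(trials, num_trees = 100, seed = 1L) {
  hp_names <- setdiff(names(trials), c("rmse", "iteration"))
  if (nrow(trials) < 20) stop("need at least 20 tuning trials")
  y <- trials$rmse
  if (stats::sd(y) < 1e-12) {
    warning("constant RMSE across trials; all shares zero")
    terms <- c(hp_names, utils::combn(hp_names, 2, paste, collapse = ":"))
    return(data.frame(term = terms, share = 0))
  }
  X <- as.data.frame(lapply(trials[hp_names], function(v) {
    v <- as.numeric(v)
    r <- range(v)
    if (r[2] == r[1]) rep(0.5, length(v)) else (v - r[1]) / (r[2] - r[1])
  }))
  set.seed(seed)
  rf <- ranger::ranger(y = y, x = X, num.trees = num_trees,
                       min.node.size = 2, mtry = ncol(X), seed = seed)
  d <- length(hp_names)
  pair_idx <- if (d >= 2) utils::combn(d, 2) else
    matrix(integer(0), nrow = 2)
  acc_main <- matrix(0, 0, d)
  acc_pair <- matrix(0, 0, ncol(pair_idx))
  for (t in seq_len(num_trees)) {
    ti <- ranger::treeInfo(rf, t)
    boxes <- .tree_boxes(ti, d)
    if (nrow(boxes$lo) == 1) next  # no splits
    dec <- .fanova_tree(boxes, d, pair_idx)
    if (dec$vtot <= 1e-14) next
    acc_main <- rbind(acc_main, dec$main / dec$vtot)
    if (ncol(pair_idx))
      acc_pair <- rbind(acc_pair, dec$pair / dec$vtot)
  }
  share_main <- if (nrow(acc_main)) colMeans(acc_main) else rep(0, d)
  share_pair <- if (nrow(acc_pair) && ncol(pair_idx))
    colMeans(acc_pair) else rep(0, ncol(pair_idx))
  terms <- c(hp_names,
             if (ncol(pair_idx))
               apply(pair_idx, 2, function(ij)
                 paste(hp_names[ij], collapse = ":")))
  data.frame(term = terms, share = pmax(c(share_main, share_pair), 0))
}

# Leaf boxes of one ranger tree on [0,1]^d.
.tree_boxes <- function(ti, d) {
  nn <- nrow(ti)
  lo <- matrix(0, nn, d); hi <- matrix(1, nn, d)
  val <- rep(NA_real_, nn)
  # nodeID is 0-based in treeInfo
  for (i in seq_len(nn)) {
    if (ti$terminal[i]) { val[i] <- ti$prediction[i]; next }
    sv <- ti$splitvarID[i] + 1L
    spl <- ti$splitval[i]
    l <- ti$leftChild[i] + 1L; r <- ti$rightChild[i] + 1L
    lo[l, ] <- lo[i, ]; hi[l, ] <- hi[i, ]
    lo[r, ] <- lo[i, ]; hi[r, ] <- hi[i, ]
    hi[l, sv] <- min(hi[l, sv], spl)
    lo[r, sv] <- max(lo[r, sv], spl)
  }
  leaves <- which(ti$terminal)
  list(lo = lo[leaves, , drop = FALSE], hi = hi[leaves, , drop = FALSE],
       val = val[leaves])
}

# Exact fANOVA decomposition of a single tree over the unit cube.
.fanova_tree <- function(boxes, d, pair_idx) {
  lo <- boxes$lo; hi <- boxes$hi; val <- boxes$val
  len <- hi - lo
  vol <- apply(len, 1, prod)
  f0 <- sum(val * vol)
  vtot <- sum(val^2 * vol) - f0^2
  main <- numeric(d)
  main_fun <- vector("list", d)
  for (j in seq_len(d)) {
    brk <- sort(unique(c(0, 1, lo[, j], hi[, j])))
    mids <- (brk[-1] + brk[-length(brk)]) / 2
    wseg <- diff(brk)
    # marginal value on each segment: sum over leaves containing the segment
    # in dim j of val * volume of the leaf in the other dims
    other_vol <- vol / pmax(len[, j], 1e-300)
    fj <- vapply(mids, function(m) {
      inside <- lo[, j] <= m & m < hi[, j]
      sum(val[inside] * other_vol[inside])
    }, numeric(1))
    main[j] <- sum((fj - f0)^2 * wseg)
    main_fun[[j]] <- list(brk = brk, f = fj)
  }
  pair <- numeric(ncol(pair_idx))
  if (ncol(pair_idx)) {
    for (k in seq_len(ncol(pair_idx))) {
      a <- pair_idx[1, k]; b <- pair_idx[2, k]
      brka <- main_fun[[a]]$brk; brkb <- main_fun[[b]]$brk
      mida <- (brka[-1] + brka[-length(brka)]) / 2
      midb <- (brkb[-1] + brkb[-length(brkb)]) / 2
      wa <- diff(brka); wb <- diff(brkb)
      other_vol <- vol / pmax(len[, a] * len[, b], 1e-300)
      vab <- 0
      for (ia in seq_along(mida)) {
        in_a <- lo[, a] <= mida[ia] & mida[ia] < hi[, a]
        fab <- vapply(midb, function(mb) {
          inside <- in_a & lo[, b] <= mb & mb < hi[, b]
          sum(val[inside] * other_vol[inside])
        }, numeric(1))
        resid <- fab - main_fun[[a]]$f[ia] - main_fun[[b]]$f + f0
        vab <- vab + sum(resid^2 * wb) * wa[ia]
      }
      pair[k] <- vab
    }
  }
  list(vtot = vtot, main = main, pair = pair)
}
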