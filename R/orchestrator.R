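#' Configuration for an end-to-end experiment run
#'
#' @param models list of model descriptors. A linear random effects model
#'   is a label string (e.g. `"G+E"`, `"G+E+W+GxW+GxE"`); a machine
#'   learning model is `list(backend =, include_W =, include_coords =,
#'   tune = FALSE, hyperparams = list(...))`.
#' @param schemes cross-validation schemes to run, subset of
#'   `c("CV0-Year", "CV00-Year", "CV0-Site", "CV00-Site")`.
#' @param trait trait id (`"grain_yield"` or `"plant_height"`).
#' @param n_pcs number of marker principal components for the ML feature
#'   table.
#' @param scaled_down use short MCMC chains and minimal tuning (default
#'   `TRUE`; full-length chains mirror a production analysis).
#' @param seed integer seed.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(models = list("G+E", "G+E+W+GxW+GxE"),
                              schemes = c("CV0-Year", "CV00-Year"),
                              trait = "grain_yield", n_pcs = 50,
                              scaled_down = TRUE, seed = 1L) {
  structure(list(models = models, schemes = schemes, trait = trait,
                 n_pcs = n_pcs, scaled_down = scaled_down,
                 seed = as.integer(seed)), class = "experiment_config")
}

model_label <- function(m) {
  if (is.character(m)) return(m)
  paste0(toupper(m$backend), "-G",
         if (isTRUE(m$include_W)) "+W" else "",
         "+Y", if (isTRUE(m$include_coords %||% TRUE)) "+Lon+Lat" else "")
}

scheme_splits <- function(scheme, obs) {
  switch(scheme,
         "CV0-Year" = make_cv0_splits(obs, "year"),
         "CV00-Year" = make_cv00_splits(obs, "year"),
         "CV0-Site" = make_cv0_splits(obs, "site"),
         "CV00-Site" = make_cv00_splits(obs, "site"),
         stop("unknown scheme: ", scheme))
}

#' Run the model x scheme experiment grid on a dataset
#'
#' Executes the pipeline stages in order: stage-1 BLUEs from the plot table,
#' genotype processing (filters, imputation, pruning, hybrids, GRM, marker
#' PCs), kernel/feature construction, forward cross-validation per scheme,
#' and per-environment plus weighted predictive abilities. With a synthetic
#' dataset from [simulate_met()] the run is fully reproducible from
#' `(config, seed)`.
#'
#' @param cfg an [experiment_config()].
#' @param data a [simulate_met()] result (or a list with the same
#'   elements).
#' @return list: `results` (long data.frame scheme/model/environment/r/n/V),
#'   `summary` (r_w per scheme and model), `blues`, `geno`.
#' @export
run_experiment <- function(cfg, data) {
  s1 <- stage1_blues(data$plots)
  blues <- s1$blues
  geno <- geno_pipeline(data$inbreds, data$pedigree,
                        allele_counts = attr(data$inbreds, "allele_counts"))
  # analysis observations: BLUE rows with genotype and EC data
  oid <- paste(blues$environment, blues$hybrid, sep = ":")
  keep <- blues$hybrid %in% rownames(geno$grm) & oid %in% rownames(data$W)
  blues <- blues[keep, , drop = FALSE]
  oid <- oid[keep]
  meta <- data$obs[match(oid, paste(data$obs$environment, data$obs$hybrid,
                                    sep = ":")), ]
  W <- as.matrix(data$W)[oid, , drop = FALSE]
  y <- blues$blue
  factors <- data.frame(hybrid = blues$hybrid,
                        environment = blues$environment,
                        site = meta$site, year = meta$year)
  coords <- data.frame(
    longitude = data$sites$longitude[match(meta$site, data$sites$site)],
    latitude = data$sites$latitude[match(meta$site, data$sites$site)])
  n_pcs <- min(cfg$n_pcs, nrow(geno$grm) - 1)
  pcs_hyb <- marker_pcs(geno$hybrids, n_pcs)
  pcs <- pcs_hyb[blues$hybrid, , drop = FALSE]

  gibbs_opts <- if (cfg$scaled_down)
    list(iters = 4000, burnin = 500, thin = 2) else
      list(iters = 42000, burnin = 2000, thin = 5)

  results <- NULL
  for (scheme in cfg$schemes) {
    splits <- scheme_splits(scheme, factors)
    for (m in cfg$models) {
      lbl <- model_label(m)
      pred <- rep(NA_real_, length(y))
      for (sp in splits) {
        if (is.character(m)) {
          spec <- parse_model_spec(m)
          rows <- c(sp$train, sp$test)
          kern <- build_kernels(spec, geno$grm, W[rows, , drop = FALSE],
                                factors[rows, , drop = FALSE])
          ym <- y[rows]
          ym[seq_along(sp$test) + length(sp$train)] <- NA
          fit <- do.call(fit_gibbs, c(list(y = ym, kernels = kern,
                                           seed = cfg$seed), gibbs_opts))
          pred[sp$test] <- fit$fitted[seq_along(sp$test) +
                                        length(sp$train)]
        } else {
          ft <- build_feature_table(pcs, W, factors$year, coords,
                                    include_W = isTRUE(m$include_W),
                                    include_coords =
                                      isTRUE(m$include_coords %||% TRUE),
                                    train_index = sp$train)
          hp <- m$hyperparams %||% list(learning_rate = 0.05,
                                        max_depth = 4, n_trees = 400,
                                        feature_fraction = 0.8,
                                        subsample = 0.8)
          if (isTRUE(m$tune)) {
            tuned <- tune_bayes_gp(m$backend, default_space(m$backend),
                                   ft$x[sp$train, , drop = FALSE],
                                   y[sp$train],
                                   n_iter = if (cfg$scaled_down) 5 else 30,
                                   n_init = if (cfg$scaled_down) 5 else 10,
                                   seed = cfg$seed)
            hp <- tuned$best
          }
          fit <- fit_predict(m$backend, hp,
                             ft$x[sp$train, , drop = FALSE], y[sp$train],
                             ft$x[sp$test, , drop = FALSE],
                             seed = cfg$seed)
          pred[sp$test] <- fit$pred
        }
      }
      done <- !is.na(pred)
      ec <- env_correlations(pred[done], y[done],
                             factors$environment[done])
      if (is.null(ec) || nrow(ec) == 0) next
      ec$scheme <- scheme; ec$model <- lbl
      results <- rbind(results, ec)
    }
  }
  summary <- do.call(rbind, lapply(split(results,
                                         list(results$scheme,
                                              results$model),
                                         drop = TRUE), function(d)
    data.frame(scheme = d$scheme[1], model = d$model[1],
               r_w = weighted_predictive_ability(d),
               n_env = nrow(d))))
  rownames(summary) <- NULL
  list(results = results, summary = summary, blues = s1, geno = geno)
}

#' Rank models against the baseline
#'
#' Percentage change of the weighted predictive ability relative to the
#' `G+E` baseline, per scheme, ordered by descending `r_w`.
#'
#' @param summary the `summary` element of a [run_experiment()] result.
#' @param baseline baseline model label (default `"G+E"`).
#' @return data.frame `scheme`, `model`, `r_w`, `pct_vs_baseline`.
#' @export
compare_models <- function(summary, baseline = "G+E") {
  out <- NULL
  for (scheme in unique(summary$scheme)) {
    d <- summary[summary$scheme == scheme, , drop = FALSE]
    b <- d$r_w[d$model == baseline]
    if (!length(b)) stop("baseline model ", baseline,
                         " missing for scheme ", scheme)
    d$pct_vs_baseline <- 100 * (d$r_w - b) / abs(b)
    out <- rbind(out, d[order(-d$r_w), ])
  }
  rownames(out) <- NULL
  out
}
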