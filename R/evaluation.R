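#' Forward cross-validation splits masking a whole year or site (CV0)
#'
#' One split per unit: every observation of the held-out year (or site) is
#' test, everything else is training. Genotype overlap between training and
#' test is allowed, so the model can borrow information about a predicted
#' genotype's performance in other tested environments. Units are
#' enumerated in sorted order; the construction is deterministic.
#'
#' @param obs observation table with columns `year`, `site`, `environment`,
#'   `hybrid`.
#' @param unit `"year"` or `"site"`.
#' @return list of splits, each `list(scheme, held_out, train, test)` with
#'   integer row indices.
#' @export
make_cv0_splits <- function(obs, unit = c("year", "site")) {
  unit <- match.arg(unit)
  u <- obs[[unit]]
  levels <- sort(unique(u))
  if (length(levels) < 2) stop("need at least 2 ", unit, "s for CV0")
  lapply(levels, function(l) {
    test <- which(u == l)
    list(scheme = paste0("CV0-", tools::toTitleCase(unit)), held_out = l,
         train = which(u != l), test = test)
  })
}

#' CV00 splits: new environments and new genotypes
#'
#' Starts from the CV0 split for each held-out unit and additionally removes
#' from the training set every observation of a genotype that occurs in the
#' test set, so predicted genotypes are entirely unobserved.
#'
#' @inheritParams make_cv0_splits
#' @return list of splits as in [make_cv0_splits()], scheme `CV00-*`.
#' @export
make_cv00_splits <- function(obs, unit = c("year", "site")) {
  unit <- match.arg(unit)
  base <- make_cv0_splits(obs, unit)
  lapply(base, function(sp) {
    test_geno <- unique(obs$hybrid[sp$test])
    train <- sp$train[!(obs$hybrid[sp$train] %in% test_geno)]
    if (!length(train))
      stop("empty training set after genotype masking for unit ",
           sp$held_out)
    list(scheme = sub("CV0", "CV00", sp$scheme), held_out = sp$held_out,
         train = train, test = sp$test)
  })
}

#' Per-environment predictive correlations
#'
#' Pearson correlation between predictions and observations computed on a
#' trial (environment) basis, with the sample size and the sampling variance
#' `V(r) = (1 - r^2)/(n - 2)`. Environments with fewer than `min_n`
#' observations, or with zero variance in predictions or observations, are
#' skipped with a warning.
#'
#' @param pred,obs aligned numeric vectors.
#' @param env environment labels.
#' @param min_n minimum per-environment sample size (default 3).
#' @return data.frame `environment`, `r`, `n`, `V`.
#' @export
env_correlations <- function(pred, obs, env, min_n = 3) {
  stopifnot(length(pred) == length(obs), length(obs) == length(env))
  out <- NULL
  for (e in sort(unique(env))) {
    sel <- env == e & !is.na(pred) & !is.na(obs)
    n <- sum(sel)
    if (n < min_n) {
      warning("environment ", e, " has fewer than ", min_n,
              " observations; skipped")
      next
    }
    if (stats::sd(pred[sel]) < 1e-12 || stats::sd(obs[sel]) < 1e-12) {
      warning("zero-variance predictions or observations in ", e,
              "; skipped")
      next
    }
    r <- stats::cor(pred[sel], obs[sel])
    out <- rbind(out, data.frame(environment = e, r = r, n = n,
                                 V = (1 - r^2) / (n - 2)))
  }
  out
}

#' Weighted average predictive ability across environments
#'
#' Inverse-sampling-variance weighted mean of the per-environment
#' correlations, `r_w = sum(r_j / V_j) / sum(1 / V_j)` with
#' `V_j = (1 - r_j^2)/(n_j - 2)`. Perfect correlations (`|r| = 1`, zero
#' variance) are capped at 0.9999 with a warning so the weight stays finite.
#'
#' @param envs data.frame from [env_correlations()].
#' @return scalar weighted predictive ability.
#' @export
weighted_predictive_ability <- function(envs) {
  if (is.null(envs) || nrow(envs) == 0)
    stop("no environments with defined sampling variance")
  r <- envs$r; n <- envs$n
  cap <- abs(r) >= 1
  if (any(cap)) {
    warning(sum(cap), " environment(s) with |r| = 1 capped at 0.9999")
    r[cap] <- sign(r[cap]) * 0.9999
  }
  V <- (1 - r^2) / (n - 2)
  sum(r / V) / sum(1 / V)
}
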