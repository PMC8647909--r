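#' Split environments whose replicates were planted far apart
#'
#' Replicates of one experiment planted seven or more days apart experienced
#' different weather at matching phenological stages and are therefore
#' treated as distinct, unreplicated environments. Replicates are grouped by
#' planting date: scanning dates in increasing order, a replicate starts a
#' new group when its planting date is 7 or more days after the first date of
#' the current group. Plots without a planting date are dropped with a
#' warning.
#'
#' @param plots plot table: data.frame with columns `environment`, `site`,
#'   `year`, `hybrid`, `replicate`, `planting_date` (`Date`),
#'   `silking_date`, and one trait column (default name `trait`).
#' @return the plot table with environment labels rewritten where a split
#'   occurred (suffix `_p2`, `_p3`, ...).
#' @export
split_environments <- function(plots) {
  miss <- is.na(plots$planting_date)
  if (any(miss)) {
    warning(sum(miss), " plot(s) without planting date dropped")
    plots <- plots[!miss, , drop = FALSE]
  }
  out <- plots
  for (env in unique(plots$environment)) {
    sel <- plots$environment == env
    reps <- unique(plots[sel, c("replicate", "planting_date")])
    reps <- reps[order(reps$planting_date, reps$replicate), , drop = FALSE]
    grp <- integer(nrow(reps)); grp[1] <- 1L
    anchor <- reps$planting_date[1]
    for (i in seq_len(nrow(reps))[-1]) {
      if (as.numeric(reps$planting_date[i] - anchor) >= 7) {
        grp[i] <- grp[i - 1] + 1L
        anchor <- reps$planting_date[i]
      } else grp[i] <- grp[i - 1]
    }
    if (max(grp) > 1L) {
      for (g in 2:max(grp)) {
        in_g <- reps$replicate[grp == g]
        rows <- sel & plots$replicate %in% in_g
        out$environment[rows] <- paste0(env, "_p", g)
      }
    }
  }
  out
}

# Profiled REML for y = X beta + Z u + e with a single random effect.
# lambda = sigma2_u / sigma2_e; returns estimates and studentized
# conditional residuals.
reml_one_random <- function(y, X, Z, tol = 1e-8) {
  n <- length(y); p <- qr(X)$rank
  ZZt <- tcrossprod(Z)
  profile <- function(loglam) {
    lam <- 10^loglam
    V <- diag(n) + lam * ZZt
    cV <- chol(V)
    Vi <- chol2inv(cV)
    XtViX <- crossprod(X, Vi %*% X)
    beta <- solve(XtViX, crossprod(X, Vi %*% y))
    r <- y - X %*% beta
    s2 <- as.numeric(crossprod(r, Vi %*% r)) / (n - p)
    ll <- -0.5 * ((n - p) * log(s2) + 2 * sum(log(diag(cV))) +
                    determinant(XtViX, logarithm = TRUE)$modulus)
    list(ll = as.numeric(ll), lam = lam, beta = beta, s2 = s2, Vi = Vi,
         XtViX = XtViX)
  }
  # golden-section search on log10(lambda)
  lo <- -8; hi <- 8
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- profile(c1)$ll; f2 <- profile(c2)$ll
  while (b - a > tol) {
    if (f1 < f2) {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- profile(c2)$ll
    } else {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- profile(c1)$ll
    }
  }
  best <- profile((a + b) / 2)
  sigma2_e <- best$s2
  sigma2_u <- best$lam * sigma2_e
  Vi <- best$Vi
  # P on the scale of (I + lambda ZZ'): conditional residuals e = P y and
  # Var(e) = sigma2_e * P, so the studentized residual is e / sqrt(s2 * P_ii)
  P <- Vi - Vi %*% X %*% solve(best$XtViX, crossprod(X, Vi))
  cond_res <- as.numeric(P %*% y)
  stud <- cond_res / sqrt(pmax(sigma2_e * diag(P), 1e-12))
  list(beta = as.numeric(best$beta), sigma2_e = sigma2_e, sigma2_u = sigma2_u,
       studentized = stud, loglik = best$ll)
}

#' Per-environment hybrid BLUEs from a fixed-genotype mixed model
#'
#' Within each environment the trait is modeled as a general mean plus a
#' fixed hybrid-genotype effect, a random replicate effect and a residual.
#' The model is fitted by REML, profiling the likelihood over the ratio of
#' the replicate to residual variance (golden-section search). The genotype
#' BLUEs use a cell-means parameterization so each coefficient is directly
#' the hybrid's estimate. For unreplicated environments the BLUE is the
#' observed value and residuals are undefined (flagged `unreplicated`).
#' Environments with a single hybrid are skipped with a warning.
#'
#' @param plots plot table (one or more environments), trait column named by
#'   `trait_col`.
#' @param trait_col name of the trait column (default `"trait"`).
#' @return list with `blues` (data.frame `environment`, `hybrid`, `blue`,
#'   `n_plots`, `unreplicated`), `residuals` (data.frame `environment`,
#'   `hybrid`, `replicate`, `row`, `studentized`) and `varcomp` (per
#'   environment replicate/residual variance estimates).
#' @export
fit_env_blues <- function(plots, trait_col = "trait") {
  blues <- NULL; resids <- NULL; varcomp <- NULL
  for (env in unique(plots$environment)) {
    d <- plots[plots$environment == env, , drop = FALSE]
    y <- d[[trait_col]]
    ok <- !is.na(y)
    d <- d[ok, , drop = FALSE]; y <- y[ok]
    hy <- factor(d$hybrid)
    if (nlevels(hy) < 2) {
      warning("environment ", env, " has fewer than 2 hybrids; skipped")
      next
    }
    reps <- factor(d$replicate)
    unrep <- nlevels(reps) < 2 || !any(duplicated(d$hybrid))
    if (unrep) {
      agg <- tapply(y, hy, mean)
      blues <- rbind(blues, data.frame(
        environment = env, hybrid = names(agg), blue = as.numeric(agg),
        n_plots = as.integer(table(hy)), unreplicated = TRUE))
      next
    }
    X <- stats::model.matrix(~ 0 + hy)
    Z <- stats::model.matrix(~ 0 + reps)
    fit <- reml_one_random(y, X, Z)
    blues <- rbind(blues, data.frame(
      environment = env, hybrid = levels(hy), blue = fit$beta,
      n_plots = as.integer(table(hy)), unreplicated = FALSE))
    resids <- rbind(resids, data.frame(
      environment = env, hybrid = as.character(d$hybrid),
      replicate = d$replicate, row = rownames(d),
      studentized = fit$studentized))
    varcomp <- rbind(varcomp, data.frame(
      environment = env, sigma2_rep = fit$sigma2_u,
      sigma2_resid = fit$sigma2_e))
  }
  list(blues = blues, residuals = resids, varcomp = varcomp)
}

#' Remove outlying plots and refit the environment models once
#'
#' Plots whose absolute studentized conditional residual exceeds the
#' threshold are flagged as potential outliers and removed; the BLUEs are
#' then refit once on the cleaned data (flag, remove, refit - not iterated).
#'
#' @param plots plot table.
#' @param residuals residual table from [fit_env_blues()].
#' @param threshold absolute studentized-residual cutoff (default 3).
#' @param trait_col trait column name.
#' @return list with `plots` (cleaned), `outliers` (log of removed plots)
#'   and `fit` (the refit [fit_env_blues()] result).
#' @export
remove_outliers <- function(plots, residuals, threshold = 3,
                            trait_col = "trait") {
  if (is.null(residuals) || nrow(residuals) == 0) {
    return(list(plots = plots, outliers = NULL,
                fit = fit_env_blues(plots, trait_col)))
  }
  bad <- residuals[abs(residuals$studentized) > threshold, , drop = FALSE]
  keep <- !(rownames(plots) %in% bad$row)
  cleaned <- plots[keep, , drop = FALSE]
  list(plots = cleaned, outliers = bad,
       fit = fit_env_blues(cleaned, trait_col))
}

#' Stage-1 analysis: split, fit, screen outliers, refit
#'
#' Convenience wrapper running [split_environments()], [fit_env_blues()],
#' and [remove_outliers()] with a single refit.
#'
#' @inheritParams fit_env_blues
#' @param threshold studentized-residual cutoff (default 3).
#' @return list with `blues`, `outliers`, `varcomp`, `plots` (cleaned).
#' @export
stage1_blues <- function(plots, trait_col = "trait", threshold = 3) {
  plots <- split_environments(plots)
  first <- fit_env_blues(plots, trait_col)
  res <- remove_outliers(plots, first$residuals, threshold, trait_col)
  list(blues = res$fit$blues, outliers = res$outliers,
       varcomp = res$fit$varcomp, plots = res$plots)
}
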