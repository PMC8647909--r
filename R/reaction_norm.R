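#' Parse a linear random effects model label
#'
#' Labels such as `"G+E+W+GxW+GxE"` list main effects (`G`, `E`, `S`, `Y`,
#' `W`) and interactions (`GxE`, `GxS`, `GxY`, `GxW`). Every interaction's
#' constituents must be present as main effects.
#'
#' @param label model label string.
#' @return list with `main`, `interactions`, `label`.
#' @export
parse_model_spec <- function(label) {
  parts <- strsplit(gsub("\\s", "", label), "+", fixed = TRUE)[[1]]
  mains <- parts[!grepl("x", parts)]
  inters <- parts[grepl("x", parts)]
  ok_main <- c("G", "E", "S", "Y", "W")
  ok_int <- c("GxE", "GxS", "GxY", "GxW")
  if (!all(mains %in% ok_main))
    stop("unknown main effect(s): ", paste(setdiff(mains, ok_main),
                                           collapse = ", "))
  if (!all(inters %in% ok_int))
    stop("unknown interaction(s): ", paste(setdiff(inters, ok_int),
                                           collapse = ", "))
  for (it in inters) {
    need <- strsplit(it, "x")[[1]]
    if (!all(need %in% mains))
      stop("interaction ", it, " requires main effects ",
           paste(need, collapse = " and "))
  }
  list(main = mains, interactions = inters, label = label)
}

#' Build observation-level covariance kernels for a reaction-norm model
#'
#' Expands the hybrid genomic relationship matrix and the factor incidence
#' structures to observation level and forms the requested kernels:
#' `K_G = Z_g G Z_g'`, block kernels `Z Z'` for environment, site and year,
#' `K_W = Omega = W W' / q` (q = number of EC columns, so the diagonal
#' averages about 1), and interaction kernels as Hadamard (elementwise)
#' products of the expanded main-effect kernels, e.g.
#' `K_GxE = K_G o K_E`. Hadamard products of positive semidefinite kernels
#' are positive semidefinite (Schur product theorem).
#'
#' @param spec model spec from [parse_model_spec()] (or a label string).
#' @param grm genomic relationship matrix over hybrids (named).
#' @param W standardized EC matrix aligned with the observations (`NULL` if
#'   the model has no `W` term).
#' @param factors data.frame with per-observation `hybrid`, `environment`,
#'   `site`, `year`.
#' @return named list of n x n kernels (class `kernel_set`).
#' @export
build_kernels <- function(spec, grm, W = NULL, factors) {
  if (is.character(spec)) spec <- parse_model_spec(spec)
  n <- nrow(factors)
  ker <- list()
  need <- union(spec$main, unlist(strsplit(spec$interactions, "x")))
  if ("G" %in% need) {
    idx <- match(factors$hybrid, rownames(grm))
    if (anyNA(idx)) stop("observations reference hybrids missing from GRM")
    ker$G <- grm[idx, idx, drop = FALSE]
  }
  block_kernel <- function(f) {
    Z <- stats::model.matrix(~ 0 + factor(f))
    tcrossprod(Z)
  }
  if ("E" %in% need) ker$E <- block_kernel(factors$environment)
  if ("S" %in% need) ker$S <- block_kernel(factors$site)
  if ("Y" %in% need) ker$Y <- block_kernel(factors$year)
  if ("W" %in% need) {
    if (is.null(W)) stop("model includes W but no EC matrix supplied")
    Wm <- as.matrix(W)
    if (nrow(Wm) != n) stop("W rows not aligned with observations")
    ker$W <- tcrossprod(Wm) / ncol(Wm)
  }
  out <- ker[intersect(spec$main, names(ker))]
  for (it in spec$interactions) {
    ab <- strsplit(it, "x")[[1]]
    out[[it]] <- ker[[ab[1]]] * ker[[ab[2]]]
  }
  structure(out, class = "kernel_set", label = spec$label)
}

# eigendecomposition with PSD policy: eigenvalues in (-tol, 0) are clipped
# to zero; anything more negative is a hard error.
kernel_eigen <- function(K, name = "kernel", tol = 1e-6) {
  e <- eigen(K, symmetric = TRUE)
  scale_ref <- max(abs(e$values), 1)
  bad <- e$values < -tol * scale_ref
  if (any(bad))
    stop(name, " is not positive semidefinite (min eigenvalue ",
         format(min(e$values)), ")")
  e$values[e$values < 0] <- 0
  keep <- e$values > 1e-10 * scale_ref
  list(vectors = e$vectors[, keep, drop = FALSE], values = e$values[keep])
}

#' Fit a multi-kernel Bayesian linear random effects model by Gibbs sampling
#'
#' The response is modeled as an overall mean plus one random effect vector
#' per kernel, `u_k ~ N(0, sigma2_k K_k)`, plus residual noise. Each kernel
#' is reparameterized through its eigendecomposition `K = U D U'` with
#' `u = U delta`, `delta_j ~ N(0, sigma2_k d_j)`; because the eigenvectors
#' are orthonormal the full conditional of `delta` is diagonal and the whole
#' vector is sampled in one block per iteration. Variance components get
#' scaled-inverse-chi-square conjugate updates (df 5, scale set so the prior
#' modes split half the phenotypic variance equally among the kernels);
#' missing responses are sampled each iteration, so their posterior means
#' are the predictions.
#'
#' @param y response vector, `NA` for masked entries.
#' @param kernels `kernel_set` (or named list of PSD matrices).
#' @param iters,burnin,thin chain settings. The defaults mirror a
#'   full-length analysis (42000/2000/5); tests and scaled-down runs use
#'   shorter chains.
#' @param seed integer seed.
#' @param fix_variances optional named list (kernel names plus
#'   `sigma2_resid`) freezing the variance components, used for oracle
#'   checks.
#' @param prior_df prior degrees of freedom for every variance component.
#' @return list of class `rn_fit`: `mu`, `varcomp` (posterior mean and SD
#'   per kernel and residual), `fitted` (posterior mean linear predictor),
#'   `predictions` (for masked rows), `ess` (effective sample sizes),
#'   `samples` (thinned variance-component draws).
#' @export
fit_gibbs <- function(y, kernels, iters = 42000, burnin = 2000, thin = 5,
                      seed = 1L, fix_variances = NULL, prior_df = 5) {
  if (iters <= burnin) stop("iters must exceed burnin")
  if (length(kernels) < 1) stop("at least one kernel required")
  set.seed(seed)
  n <- length(y)
  obs <- !is.na(y)
  K <- length(kernels)
  kn <- names(kernels)
  eig <- lapply(seq_len(K), function(k)
    kernel_eigen(kernels[[k]], kn[k]))
  vy <- stats::var(y[obs])
  if (!is.finite(vy) || vy <= 0) vy <- 1e-6
  nu <- prior_df
  # prior mode nu*S/(nu+2) = 0.5 * vy / K  (residual prior mode 0.5 * vy)
  S_k <- 0.5 * vy / K * (nu + 2) / nu
  S_e <- 0.5 * vy * (nu + 2) / nu
  fixed <- function(nm) !is.null(fix_variances) && !is.null(fix_variances[[nm]])

  yc <- y
  yc[!obs] <- mean(y[obs])
  mu <- mean(y[obs])
  delta <- lapply(eig, function(e) numeric(length(e$values)))
  u <- lapply(eig, function(e) numeric(n))
  s2 <- stats::setNames(rep(vy / (2 * K), K), kn)
  s2e <- vy / 2
  for (k in seq_len(K)) if (fixed(kn[k])) s2[k] <- fix_variances[[kn[k]]]
  if (fixed("sigma2_resid")) s2e <- fix_variances$sigma2_resid

  n_save <- floor((iters - burnin) / thin)
  vc_draws <- matrix(NA_real_, n_save, K + 1,
                     dimnames = list(NULL, c(kn, "sigma2_resid")))
  mu_draws <- numeric(n_save)
  lin_sum <- numeric(n)
  pred_sum <- numeric(n)
  saved <- 0L
  lin <- mu + Reduce(`+`, u)
  for (it in seq_len(iters)) {
    # mean (flat prior)
    resid_no_mu <- yc - Reduce(`+`, u)
    mu <- stats::rnorm(1, mean(resid_no_mu), sqrt(s2e / n))
    # each kernel's effects in eigenspace, one block per kernel
    for (k in seq_len(K)) {
      e_k <- yc - mu - Reduce(`+`, u[-k], accumulate = FALSE)
      if (K == 1) e_k <- yc - mu
      Ue <- crossprod(eig[[k]]$vectors, e_k)
      d <- eig[[k]]$values
      prec <- 1 / s2e + 1 / (s2[k] * d)
      mean_j <- (Ue / s2e) / prec
      delta[[k]] <- as.numeric(mean_j + stats::rnorm(length(d)) /
                                 sqrt(prec))
      u[[k]] <- as.numeric(eig[[k]]$vectors %*% delta[[k]])
      if (!fixed(kn[k])) {
        ss <- sum(delta[[k]]^2 / d)
        s2[k] <- (ss + nu * S_k) /
          stats::rchisq(1, length(d) + nu)
      }
    }
    lin <- mu + Reduce(`+`, u)
    resid <- yc - lin
    if (!fixed("sigma2_resid"))
      s2e <- (sum(resid[obs]^2) + nu * S_e) /
        stats::rchisq(1, sum(obs) + nu)
    # impute masked responses
    if (any(!obs))
      yc[!obs] <- lin[!obs] + stats::rnorm(sum(!obs), 0, sqrt(s2e))
    if (it > burnin && (it - burnin) %% thin == 0) {
      saved <- saved + 1L
      vc_draws[saved, ] <- c(s2, s2e)
      mu_draws[saved] <- mu
      lin_sum <- lin_sum + lin
      pred_sum <- pred_sum + lin
    }
  }
  fitted <- lin_sum / saved
  ess <- apply(vc_draws, 2, function(x) {
    if (stats::sd(x) < 1e-14) return(length(x))
    a <- stats::acf(x, plot = FALSE, lag.max = min(100, saved - 1))$acf[-1]
    a <- a[seq_len(max(which(a > 0.05), 1))]
    length(x) / (1 + 2 * sum(a))
  })
  structure(list(
    mu = mean(mu_draws),
    varcomp = data.frame(component = colnames(vc_draws),
                         mean = colMeans(vc_draws),
                         sd = apply(vc_draws, 2, stats::sd),
                         row.names = NULL),
    fitted = fitted,
    predictions = if (any(!obs)) fitted[!obs] else numeric(0),
    test_index = which(!obs),
    ess = ess,
    samples = vc_draws,
    label = attr(kernels, "label")), class = "rn_fit")
}

#' Closed-form BLUP solver at fixed variance components
#'
#' Deterministic mixed-model oracle: with `V = sum_k sigma2_k K_k +
#' sigma2_resid I` over the observed rows, the mean is the generalized
#' least squares estimate and each kernel's effects are
#' `u_k = sigma2_k K_k[, obs] V^-1 (y_obs - mu)`. Rows with missing
#' responses receive predictions through the kernel covariances.
#'
#' @param y response vector (`NA` allowed for rows to predict).
#' @param kernels named list of kernels over all rows.
#' @param variances named list/vector: one `sigma2_*` per kernel (matched by
#'   kernel name) plus `sigma2_resid`.
#' @return list: `mu`, `effects` (per kernel, full length), `fitted`
#'   (mu + sum of effects for all rows), `predictions` (masked rows).
#' @export
blup_oracle <- function(y, kernels, variances) {
  obs <- !is.na(y)
  n <- length(y)
  kn <- names(kernels)
  s2e <- variances[["sigma2_resid"]]
  if (is.null(s2e)) stop("variances must include sigma2_resid")
  V <- diag(s2e, sum(obs))
  for (k in kn) {
    s2k <- variances[[k]]
    if (is.null(s2k)) stop("no variance supplied for kernel ", k)
    V <- V + s2k * kernels[[k]][obs, obs, drop = FALSE]
  }
  cV <- tryCatch(chol(V), error = function(e) stop("singular V"))
  Vi_y <- backsolve(cV, forwardsolve(t(cV), y[obs]))
  one <- rep(1, sum(obs))
  Vi_1 <- backsolve(cV, forwardsolve(t(cV), one))
  mu <- sum(Vi_y) / sum(Vi_1)
  r <- y[obs] - mu
  Vi_r <- backsolve(cV, forwardsolve(t(cV), r))
  effects <- lapply(kn, function(k)
    as.numeric(variances[[k]] * kernels[[k]][, obs, drop = FALSE] %*% Vi_r))
  names(effects) <- kn
  fitted <- mu + Reduce(`+`, effects)
  list(mu = mu, effects = effects, fitted = fitted,
       predictions = fitted[!obs], test_index = which(!obs))
}

#' Predict masked responses with a reaction-norm model
#'
#' Fits the model with the test responses masked (they stay inside the
#' kernel rows, so information flows only through the covariance structure)
#' and returns the predictions for the masked rows.
#'
#' @param spec model label or parsed spec.
#' @param kernels kernel set built over train and test observations.
#' @param y full response vector.
#' @param test_index rows to mask and predict.
#' @param method `"gibbs"` (default) or `"blup"` (requires `variances`).
#' @param variances fixed variance components for the BLUP path.
#' @param ... passed to [fit_gibbs()].
#' @return numeric vector of predictions for `test_index` (in order).
#' @export
predict_masked <- function(spec, kernels, y, test_index,
                           method = c("gibbs", "blup"), variances = NULL,
                           ...) {
  method <- match.arg(method)
  ym <- y
  ym[test_index] <- NA
  if (method == "blup") {
    fit <- blup_oracle(ym, kernels, variances)
    return(fit$fitted[test_index])
  }
  fit <- fit_gibbs(ym, kernels, ...)
  fit$fitted[test_index]
}
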