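#' @title Marker matrix conventions
#' @description Marker data are plain numeric matrices, samples in rows and
#'   markers in columns, holding minor-allele dosages 0/1/2 with `NA` for
#'   missing calls (hybrids may carry the half-integer dosages that arise
#'   from averaging two parents). An optional `map` attribute carries a
#'   data.frame with `marker`, `chrom`, `pos` (1-based, nondecreasing within
#'   chromosome).
#' @name marker-matrix
NULL

#' Remove markers with more than two observed alleles
#'
#' @param m marker matrix.
#' @param allele_counts integer vector, number of distinct alleles observed
#'   per marker (aligned with columns of `m`).
#' @return marker matrix restricted to biallelic markers.
#' @export
filter_biallelic <- function(m, allele_counts) {
  stopifnot(length(allele_counts) == ncol(m))
  m[, allele_counts <= 2, drop = FALSE]
}

#' Remove low-coverage or highly heterozygous taxa
#'
#' Samples with less than `min_coverage` of sites called, or with more than
#' `max_het` heterozygous calls among their called sites, are discarded.
#' The heterozygosity bound is strict: a taxon at exactly `max_het` is kept.
#'
#' @param m marker matrix (inbred parents).
#' @param min_coverage minimum fraction of non-missing calls (default 0.70).
#' @param max_het maximum heterozygosity fraction (default 0.08).
#' @return filtered marker matrix.
#' @export
filter_taxa <- function(m, min_coverage = 0.70, max_het = 0.08) {
  called <- !is.na(m)
  coverage <- rowMeans(called)
  het <- rowSums(m == 1, na.rm = TRUE) / pmax(rowSums(called), 1)
  keep <- coverage >= min_coverage & het <= max_het
  if (!any(keep)) stop("all taxa removed by coverage/heterozygosity filters")
  m[keep, , drop = FALSE]
}

minor_allele_freq <- function(m) {
  f <- colMeans(m, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Filter markers on the parental panel
#'
#' Removes monomorphic markers, markers missing or heterozygous in more than
#' `max_missing_het` of the parental lines, and markers with minor allele
#' frequency (computed on non-missing calls) below `maf_min`.
#'
#' @param m marker matrix of parental inbreds.
#' @param max_missing_het maximum fraction missing, and separately maximum
#'   fraction heterozygous (default 0.05 each).
#' @param maf_min minimum minor allele frequency (default 0.02); markers with
#'   MAF strictly below it are removed.
#' @return filtered marker matrix.
#' @export
filter_parent_markers <- function(m, max_missing_het = 0.05, maf_min = 0.02) {
  n <- nrow(m)
  miss <- colMeans(is.na(m))
  het <- colMeans(m == 1, na.rm = TRUE)
  het[is.nan(het)] <- 0
  mono <- apply(m, 2, function(x) length(unique(x[!is.na(x)])) <= 1)
  maf <- minor_allele_freq(m)
  keep <- !mono & miss <= max_missing_het & het <= max_missing_het &
    maf >= maf_min & !is.na(maf)
  m[, keep, drop = FALSE]
}

#' Impute missing dosages by the per-marker mode
#'
#' Observed calls are never altered. Ties between equally frequent dosage
#' classes break toward the smaller dosage for determinism.
#'
#' @param m marker matrix with no fully missing marker.
#' @param seed unused by the mode rule; kept so alternative imputers sharing
#'   this interface can be seeded.
#' @return marker matrix with no missing values.
#' @export
impute_missing <- function(m, seed = 1L) {
  nmiss <- colSums(is.na(m))
  if (any(colSums(!is.na(m)) == 0))
    stop("fully missing marker encountered; filter before imputing")
  for (j in which(nmiss > 0)) {
    x <- m[, j]
    tab <- table(x[!is.na(x)])
    mode_val <- as.numeric(names(tab)[which.max(tab)])  # ties -> first = smallest
    x[is.na(x)] <- mode_val
    m[, j] <- x
  }
  m
}

prune_rule <- function(maf, i, j) {
  # drop the member with lower MAF; ties -> larger column index
  if (maf[i] < maf[j]) i else if (maf[j] < maf[i]) j else max(i, j)
}

#' Prune markers in high linkage disequilibrium
#'
#' Sliding-window LD pruning: within each window of `window` markers, while
#' any retained pair has squared Pearson correlation of dosages above
#' `r2_max`, the member of the pair with the lower minor allele frequency is
#' removed (ties break to the larger column index); the window then slides by
#' `step` markers.
#'
#' @param m imputed marker matrix (no missing values).
#' @param window window size in markers (default 100).
#' @param step window step in markers (default 5).
#' @param r2_max squared-correlation threshold (default 0.99).
#' @return pruned marker matrix.
#' @export
ld_prune <- function(m, window = 100, step = 5, r2_max = 0.99) {
  p <- ncol(m)
  keep <- rep(TRUE, p)
  maf <- minor_allele_freq(m)
  start <- 1L
  repeat {
    end <- min(start + window - 1L, p)
    idx <- which(keep[start:end]) + start - 1L
    if (length(idx) > 1) {
      r2 <- suppressWarnings(stats::cor(m[, idx, drop = FALSE]))^2
      r2[!is.finite(r2)] <- 0
      changed <- TRUE
      while (changed) {
        changed <- FALSE
        live <- which(keep[idx])
        for (a in seq_along(live)) {
          if (changed) break
          for (b in seq_along(live)) {
            if (b <= a) next
            if (r2[live[a], live[b]] > r2_max) {
              drop_local <- prune_rule(maf[idx], live[a], live[b])
              keep[idx[drop_local]] <- FALSE
              changed <- TRUE
              break
            }
          }
        }
      }
    }
    if (end == p) break
    start <- start + step
  }
  m[, keep, drop = FALSE]
}

#' Construct in-silico hybrid genotypes from parental lines
#'
#' The hybrid dosage at each locus is the mean of the two parents' dosages
#' (for fully homozygous parents this lies in 0/1/2). A final minor allele
#' frequency filter on the hybrid panel removes near-fixed markers.
#'
#' @param parents imputed, filtered parental marker matrix with row names.
#' @param pedigree data.frame with columns `hybrid`, `parent1`, `parent2`.
#' @param maf_min minimum hybrid-panel MAF (default 0.02).
#' @return hybrid marker matrix (rows named by hybrid).
#' @export
build_hybrid_genotypes <- function(parents, pedigree, maf_min = 0.02) {
  unknown <- setdiff(unique(c(pedigree$parent1, pedigree$parent2)),
                     rownames(parents))
  if (length(unknown))
    stop("pedigree references unknown parent(s): ",
         paste(unknown, collapse = ", "))
  h <- (parents[pedigree$parent1, , drop = FALSE] +
          parents[pedigree$parent2, , drop = FALSE]) / 2
  rownames(h) <- pedigree$hybrid
  maf <- minor_allele_freq(h)
  h[, maf >= maf_min & !is.na(maf), drop = FALSE]
}

#' Genomic relationship matrix
#'
#' `G = XX'/p` with `X` the column-centered, unit-variance-scaled dosage
#' matrix (sample standard deviation, n-1 denominator) and `p` the number of
#' markers with nonzero variance. All entries of `G` sum to approximately
#' zero because the columns of `X` are centered.
#'
#' @param m marker matrix with no missing values, `p >= 2`.
#' @return square symmetric matrix over samples with attribute `p`.
#' @export
compute_grm <- function(m) {
  v <- apply(m, 2, stats::var)
  X <- m[, v > 1e-12, drop = FALSE]
  p <- ncol(X)
  if (p == 0) stop("no polymorphic markers left for the GRM")
  X <- scale(X, center = TRUE, scale = TRUE)
  G <- tcrossprod(X) / p
  dimnames(G) <- list(rownames(m), rownames(m))
  attr(G, "p") <- p
  G
}

#' Principal components of the marker matrix
#'
#' Scores of the first `k` principal components of the centered, scaled
#' dosage matrix, with a deterministic sign convention (the largest-magnitude
#' loading of each component is positive).
#'
#' @param m marker matrix, no missing values.
#' @param k number of components, `k <= min(n - 1, p)`.
#' @return n x k score matrix with attribute `variance_fraction`.
#' @export
marker_pcs <- function(m, k) {
  v <- apply(m, 2, stats::var)
  X <- scale(m[, v > 1e-12, drop = FALSE])
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (k > kmax) stop(sprintf("k = %d exceeds the available rank %d", k, kmax))
  pc <- stats::prcomp(X, center = FALSE, scale. = FALSE, rank. = k)
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(m)
  attr(scores, "variance_fraction") <- pc$sdev^2 / sum(pc$sdev^2)
  scores
}

#' Full genotype processing pipeline
#'
#' Applies the filters in their canonical order: biallelic markers, taxa
#' coverage/heterozygosity, parent-panel marker filters (monomorphic,
#' missing/heterozygous, MAF), mode imputation, LD pruning, in-silico hybrid
#' construction and the final hybrid-panel MAF filter.
#'
#' @param parents raw parental marker matrix.
#' @param pedigree hybrid pedigree (`hybrid`, `parent1`, `parent2`).
#' @param allele_counts observed allele count per marker (default all 2).
#' @param params list of thresholds overriding the defaults
#'   (`min_coverage`, `max_het`, `max_missing_het`, `maf_min`, `window`,
#'   `step`, `r2_max`).
#' @return list with `parents` (processed), `hybrids`, `grm`, and `log`
#'   (data.frame of marker/taxa counts after each step).
#' @export
geno_pipeline <- function(parents, pedigree, allele_counts = NULL,
                          params = list()) {
  p0 <- list(min_coverage = 0.70, max_het = 0.08, max_missing_het = 0.05,
             maf_min = 0.02, window = 100, step = 5, r2_max = 0.99)
  p0[names(params)] <- params
  if (is.null(allele_counts)) allele_counts <- rep(2L, ncol(parents))
  log <- data.frame(step = character(0), taxa = integer(0),
                    markers = integer(0))
  note <- function(step, m) rbind(log, data.frame(step = step,
                                                  taxa = nrow(m),
                                                  markers = ncol(m)))
  m <- filter_biallelic(parents, allele_counts); log <- note("biallelic", m)
  m <- filter_taxa(m, p0$min_coverage, p0$max_het); log <- note("taxa", m)
  m <- filter_parent_markers(m, p0$max_missing_het, p0$maf_min)
  log <- note("parent_markers", m)
  m <- impute_missing(m); log <- note("impute", m)
  m <- ld_prune(m, p0$window, p0$step, p0$r2_max); log <- note("ld_prune", m)
  pedigree <- pedigree[pedigree$parent1 %in% rownames(m) &
                         pedigree$parent2 %in% rownames(m), , drop = FALSE]
  h <- build_hybrid_genotypes(m, pedigree, p0$maf_min)
  log <- note("hybrids", h)
  list(parents = m, hybrids = h, grm = compute_grm(h), log = log)
}
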