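#' Read a plot-level phenotype table
#'
#' @param path CSV with columns `environment`, `site`, `year`, `hybrid`,
#'   `replicate`, `planting_date`, `silking_date` and one or more trait
#'   columns. Dates are ISO-8601.
#' @return data.frame with `Date` columns parsed.
#' @export
read_plot_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("planting_date", "silking_date"))
    if (col %in% names(d)) d[[col]] <- as.Date(d[[col]])
  d
}

#' Read a dosage matrix from CSV
#'
#' @param path CSV with sample ids in the first column and one column per
#'   marker; entries 0/1/2 or empty/NA for missing.
#' @return marker matrix (samples x markers).
#' @export
read_dosage_csv <- function(path) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(d)
}

#' Write a dosage matrix to CSV
#'
#' @param m marker matrix.
#' @param path output path.
#' @export
write_dosage_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
}

#' Read biallelic genotypes from a VCF into a dosage matrix
#'
#' GT fields are converted to counts of the alternate allele and then
#' recoded to minor-allele dosage per marker (the allele with frequency
#' below one half is counted). Positions are 1-based as in the VCF.
#'
#' @param path VCF file (uncompressed or bgzipped).
#' @return marker matrix with a `map` attribute (`marker`, `chrom`, `pos`).
#' @export
read_dosage_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_integer_,
           vapply(strsplit(gsub("\\|", "/", g), "/"), function(a)
             sum(a == "1"), integer(1)))
  }
  dos <- apply(gt, 2, count_alt)
  dos <- t(dos)  # samples x markers
  # recode to minor allele
  f <- colMeans(dos, na.rm = TRUE) / 2
  flip <- which(f > 0.5)
  dos[, flip] <- 2 - dos[, flip]
  colnames(dos) <- rownames(gt)
  attr(dos, "map") <- data.frame(marker = rownames(gt),
                                 chrom = v@fix[, "CHROM"],
                                 pos = as.integer(v@fix[, "POS"]))
  dos
}

#' Write a results bundle to CSV files
#'
#' @param run a [run_experiment()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_results <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "per_environment.csv")
  p2 <- file.path(dir, "summary.csv")
  utils::write.csv(run$results, p1, row.names = FALSE)
  utils::write.csv(run$summary, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
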