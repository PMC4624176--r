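#' Single-variant association tests on line means
#'
#' Simplified panel-style genome-wide association for fully inbred,
#' homozygous lines: covariates are regressed out of the line means
#' first, then each variant passing the minor-allele-frequency filter is
#' tested by regressing the adjusted means on allele dosage (for
#' homozygous 0/1 lines this is identical to a two-group equal-variance
#' t-test between allele classes).  No genomic-relatedness term is
#' fitted; the covariate matrix is a generic stand-in for systematic
#' adjustments such as endosymbiont infection status or segregating
#' inversions.
#'
#' @param line_means named numeric vector of per-line phenotypes.
#' @param genotypes a `founder_panel`-style object or a lines x sites
#'   0/1 matrix with rownames = line ids.
#' @param covariates optional lines x k numeric matrix (rownames = line
#'   ids) regressed out of the phenotype before testing.
#' @param maf_min minor-allele-frequency filter; sites are kept only if
#'   MAF is strictly greater than this (default 0.05).
#' @param min_class minimum number of lines per allele class (default
#'   3); sites failing it are skipped and listed in the `skipped`
#'   attribute.
#' @return `data.frame` with `site` (column index), `chrom`/`pos` when
#'   available, `maf`, `effect` (regression slope per alt allele), `t`,
#'   `p`.  Attribute `skipped`: indices of sites excluded after the MAF
#'   filter (monomorphic or thin classes).
#' @export
single_variant_tests <- function(line_means, genotypes, covariates = NULL,
                                 maf_min = 0.05, min_class = 3L) {
  if (inherits(genotypes, "founder_panel")) {
    G <- t(genotypes$geno)
    rownames(G) <- genotypes$line_ids
    site_info <- genotypes$sites[c("chrom", "pos")]
  } else {
    G <- as.matrix(genotypes)
    site_info <- NULL
  }
  if (is.null(names(line_means)) || is.null(rownames(G)))
    stop("line_means and genotype rows must be named by line")
  common <- intersect(names(line_means), rownames(G))
  if (length(common) < 2 * min_class) stop("too few lines with phenotype and genotype")
  y <- line_means[common]
  G <- G[common, , drop = FALSE]

  if (!is.null(covariates)) {
    X <- as.matrix(covariates)[common, , drop = FALSE]
    y <- residuals(lm(y ~ X))
  }
  nl <- length(y)

  af <- colMeans(G)
  maf <- pmin(af, 1 - af)
  pass_maf <- which(maf > maf_min)
  n1 <- colSums(G[, pass_maf, drop = FALSE])
  ok <- n1 >= min_class & (nl - n1) >= min_class
  keep <- pass_maf[ok]
  skipped <- pass_maf[!ok]

  ## regression on dosage via the correlation identity:
  ## t = r sqrt((n-2)/(1-r^2)), slope = cov(x,y)/var(x)
  yc <- y - mean(y)
  res <- lapply(keep, function(j) {
    x <- G[, j]
    xc <- x - mean(x)
    sxx <- sum(xc^2)
    sxy <- sum(xc * yc)
    b <- sxy / sxx
    r2 <- sxy^2 / (sxx * sum(yc^2))
    tv <- sign(b) * sqrt(r2 * (nl - 2) / max(1 - r2, .Machine$double.eps))
    c(b, tv)
  })
  res <- do.call(rbind, res)
  out <- data.frame(site = keep, maf = maf[keep],
                    effect = res[, 1], t = res[, 2],
                    p = 2 * pt(-abs(res[, 2]), nl - 2))
  if (!is.null(site_info)) {
    out$chrom <- site_info$chrom[keep]
    out$pos <- site_info$pos[keep]
    out <- out[c("site", "chrom", "pos", "maf", "effect", "t", "p")]
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "n_lines") <- nl
  out
}

#' Sexual-dimorphism phenotype from sex-specific line means
#'
#' @param male_means,female_means named numeric vectors over the same
#'   line set.
#' @return named vector of per-line male minus female differences.
#' @export
dimorphism_phenotype <- function(male_means, female_means) {
  if (is.null(names(male_means)) || is.null(names(female_means)))
    stop("line means must be named by line")
  if (!setequal(names(male_means), names(female_means)))
    stop("male and female means must cover the same lines")
  male_means - female_means[names(male_means)]
}

#' Nominally significant variants
#'
#' @param results output of [single_variant_tests()] (or any data frame
#'   with a `p` column).
#' @param threshold nominal p-value threshold; strict `<` (default
#'   `5e-5`).
#' @return the rows with `p < threshold`.
#' @export
nominal_candidates <- function(results, threshold = 5e-5) {
  stopifnot(nrow(results) >= 0, "p" %in% names(results))
  out <- results[results$p < threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}
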