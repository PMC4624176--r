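#' Sites segregating among the founder lines
#'
#' A site is informative for extreme-QTL mapping only if both alleles
#' are present among the founders; fixed sites carry no mapping signal.
#'
#' @param panel a `founder_panel`.
#' @return logical vector over `panel$sites`.
#' @export
segregating_sites <- function(panel) {
  if (nrow(panel$sites) == 0L) stop("empty panel")
  rs <- rowSums(panel$geno)
  rs > 0 & rs < ncol(panel$geno)
}

#' Pooled allele-frequency Z test for extreme pools
#'
#' Compares the alternate-allele frequency estimated from pooled
#' sequencing of a sensitive and a resistant pool.  With
#' `p_S = alt_S / d_S`, `p_R = alt_R / d_R` and the pooled null
#' frequency `p_0 = (p_S + p_R) / 2`,
#' \deqn{Z = (p_S - p_R) / \sqrt{p_0 (1 - p_0) (2/n + 1/d_S + 1/d_R)}}
#' where `n` is the number of chromosomes per pool.  The `2/n` term is
#' the binomial sampling variance of drawing the two pools of
#' individuals from the source population; the `1/d` terms are the read
#' sampling variances at the observed depths.  Two-sided p-values are
#' taken from the standard normal.  Sites with `p_0` of 0 or 1 carry no
#' information and are returned with `Z = 0`, `p = 1` and
#' `degenerate = TRUE`.
#'
#' @param alt_S,d_S alternate count and depth in the sensitive pool.
#' @param alt_R,d_R alternate count and depth in the resistant pool.
#' @param n chromosomes per pool (e.g. 400 for autosomes in 200-fly
#'   pools).  Vectors are recycled across sites.
#' @return `data.frame` with `p_S`, `p_R`, `p_0`, `n`, `Z`, `p`,
#'   `degenerate`.
#' @export
z_test <- function(alt_S, d_S, alt_R, d_R, n) {
  if (any(d_S <= 0) || any(d_R <= 0)) stop("depths must be positive")
  if (any(n <= 0)) stop("n (chromosomes per pool) must be positive")
  if (any(alt_S < 0 | alt_S > d_S) || any(alt_R < 0 | alt_R > d_R))
    stop("allele counts must lie in [0, depth]")
  p_S <- alt_S / d_S
  p_R <- alt_R / d_R
  p_0 <- (p_S + p_R) / 2
  degen <- p_0 <= 0 | p_0 >= 1
  v <- p_0 * (1 - p_0) * (2 / n + 1 / d_S + 1 / d_R)
  Z <- ifelse(degen, 0, (p_S - p_R) / sqrt(ifelse(degen, 1, v)))
  p <- ifelse(degen, 1, 2 * pnorm(-abs(Z)))
  p <- pmax(p, .Machine$double.xmin)   # keep -log10(p) finite
  data.frame(p_S = p_S, p_R = p_R, p_0 = p_0, n = rep(n, length.out =
               length(p_S)), Z = Z, p = p, degenerate = degen)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate (0 < alpha < 1).
#' @param m number of tests (>= 1).
#' @return per-test threshold `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (length(m) == 0 || any(m < 1)) stop("m must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  alpha / m
}

#' Genome scan of pooled extreme counts
#'
#' Runs [z_test()] at every site of a pool-counts table and reports
#' calls at two thresholds: the Bonferroni-corrected level
#' `alpha / m` for the `m` sites tested, and a nominal level
#' (default `1e-5`) useful for ranking sub-threshold candidates.
#'
#' @param counts pool-counts `data.frame` (`chrom`, `pos`, `alt_S`,
#'   `d_S`, `alt_R`, `d_R`).
#' @param n chromosomes per pool; either a single number or a named
#'   vector by chromosome (e.g. halve it for the X in male pools).
#' @param alpha family-wise level for the Bonferroni call.
#' @param nominal nominal per-site threshold reported alongside.
#' @return `data.frame`: the input site columns plus the [z_test()]
#'   columns, `sig_bonferroni` and `sig_nominal`; attributes
#'   `bonferroni_threshold` and `m`.
#' @export
run_xqtl <- function(counts, n, alpha = 0.05, nominal = 1e-5) {
  stopifnot(nrow(counts) > 0,
            all(c("chrom", "pos", "alt_S", "d_S", "alt_R", "d_R") %in%
                  names(counts)))
  n_site <- if (!is.null(names(n))) {
    i <- match(as.character(counts$chrom), names(n))
    if (anyNA(i)) stop("n has no entry for chromosome(s): ",
                       paste(unique(counts$chrom[is.na(i)]), collapse = ", "))
    unname(n[i])
  } else rep(n, nrow(counts))
  zt <- z_test(counts$alt_S, counts$d_S, counts$alt_R, counts$d_R, n_site)
  m <- nrow(counts)
  thr <- bonferroni_threshold(alpha, m)
  out <- cbind(counts[c("chrom", "pos", "alt_S", "d_S", "alt_R", "d_R")], zt)
  out$sig_bonferroni <- out$p < thr
  out$sig_nominal <- out$p < nominal
  attr(out, "bonferroni_threshold") <- thr
  attr(out, "m") <- m
  out
}

#' Truncation-select the phenotypic extremes of a cohort
#'
#' Returns the lowest-scoring fraction (sensitive: flies that succumb
#' early) and the highest-scoring fraction (resistant) of a phenotyped
#' cohort.  Elution times are recorded in discrete collection bins, so
#' ties at the boundary minute are broken by a seeded uniform draw to
#' keep pool sizes exact.
#'
#' @param elutions elution table as from [simulate_elution()], with
#'   attribute `individual_idx` mapping rows to population indices.
#' @param fraction selected proportion per tail (0 < fraction < 0.5).
#' @param seed integer seed for tie-breaking.
#' @return list with `sensitive` and `resistant` vectors of population
#'   row indices (or row indices of `elutions` when no mapping
#'   attribute is present), each of size `floor(fraction * n)`.
#' @export
select_extremes <- function(elutions, fraction = 0.1, seed = 1L) {
  if (fraction <= 0 || fraction >= 0.5)
    stop("fraction must be in (0, 0.5)")
  nfly <- nrow(elutions)
  k <- floor(fraction * nfly)
  if (k < 1) stop("fraction * n is below 1 fly per pool")
  set.seed(derive_seed(seed, "extremes"))
  ord <- order(elutions$minute, runif(nfly))
  idx <- attr(elutions, "individual_idx")
  if (is.null(idx)) idx <- seq_len(nfly)
  list(sensitive = idx[ord[seq_len(k)]],
       resistant = idx[ord[seq(nfly - k + 1L, nfly)]])
}
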