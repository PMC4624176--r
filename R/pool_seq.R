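#' Simulate pooled sequencing of two phenotypic extreme pools
#'
#' Given the individuals selected into the sensitive and resistant
#' pools, computes the true alternate-allele frequency of each pool at
#' every site segregating among the founders, then adds the two layers
#' of sequencing noise of a pool-seq experiment: per-site depth drawn as
#' Poisson(`mean_depth`) independently in each pool, and the alternate
#' read count as Binomial(depth, true pool frequency).  Sites
#' monomorphic across the founder panel are excluded.
#'
#' @param pop the phenotyped `aip_population` cohort.
#' @param selected a list with components `sensitive` and `resistant`,
#'   each a vector of row indices into `pop$individuals`.
#' @param panel the founder panel.
#' @param mean_depth mean haploid sequencing depth per pool (> 0).
#' @param seed integer seed.
#' @return a pool-counts `data.frame`: `chrom`, `pos`, `alt_S`, `d_S`,
#'   `alt_R`, `d_R`, plus true frequencies `p_S_true`, `p_R_true`.
#' @export
simulate_pool_seq <- function(pop, selected, panel, mean_depth, seed = 1L) {
  stopifnot(mean_depth > 0,
            length(selected$sensitive) > 0, length(selected$resistant) > 0)
  set.seed(derive_seed(seed, "poolseq"))
  seg <- which(segregating_sites(panel))
  if (length(seg) == 0L) stop("no sites segregate among the founders")

  sub_pop <- function(idx) {
    new_population(pop$individuals[idx], pop$generation, length(idx),
                   pop$lengths_cM)
  }
  pS <- colSums(dosage_matrix(sub_pop(selected$sensitive), panel, seg)) /
    (2 * length(selected$sensitive))
  pR <- colSums(dosage_matrix(sub_pop(selected$resistant), panel, seg)) /
    (2 * length(selected$resistant))

  m <- length(seg)
  dS <- rpois(m, mean_depth)
  dR <- rpois(m, mean_depth)
  data.frame(chrom = panel$sites$chrom[seg], pos = panel$sites$pos[seg],
             alt_S = rbinom(m, dS, pS), d_S = dS,
             alt_R = rbinom(m, dR, pR), d_R = dR,
             p_S_true = pS, p_R_true = pR,
             stringsAsFactors = FALSE)
}
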