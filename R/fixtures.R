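#' Random interaction-network fixture with planted linkers
#'
#' Builds a reproducible gene–gene interaction edge list containing
#' candidate genes (`C1..Cn`), non-candidate genes (`G1..Gm`), a set of
#' planted linker paths (each planted linker is a non-candidate joined
#' to two distinct candidates — the structure the one-linker subnetwork
#' rule must recover) and additional uniform random edges.
#'
#' @param n_candidates number of candidate genes.
#' @param n_other number of non-candidate genes.
#' @param n_edges number of extra random edges beyond the planted ones.
#' @param n_linkers number of planted linkers (default 0).
#' @param type edge type label(s), `"genetic"` and/or `"physical"`.
#' @param seed integer seed.
#' @return list with `edges` (data.frame `gene_a`, `gene_b`, `type`),
#'   `candidates`, and `planted_linkers`.
#' @export
make_fixture_network <- function(n_candidates, n_other, n_edges,
                                 n_linkers = 0, type = "genetic", seed = 1L) {
  stopifnot(n_candidates >= 0, n_other >= 0, n_edges >= 0, n_linkers >= 0)
  if (n_linkers > 0 && (n_other < n_linkers || n_candidates < 2))
    stop("planting linkers needs n_other >= n_linkers and >= 2 candidates")
  set.seed(derive_seed(seed, "network_fixture"))
  cand <- if (n_candidates) paste0("C", seq_len(n_candidates)) else character(0)
  other <- if (n_other) paste0("G", seq_len(n_other)) else character(0)
  nodes <- c(cand, other)

  a <- character(0); b <- character(0)
  linkers <- character(0)
  if (n_linkers > 0) {
    linkers <- other[seq_len(n_linkers)]
    for (lk in linkers) {
      ends <- sample(cand, 2L)
      a <- c(a, lk, lk); b <- c(b, ends)
    }
  }
  n_try <- 0L
  while (n_edges > 0 && length(a) < n_edges + 2L * n_linkers &&
         n_try < 50L * n_edges) {
    n_try <- n_try + 1L
    e <- sample(nodes, 2L)
    dup <- any((a == e[1] & b == e[2]) | (a == e[2] & b == e[1]))
    if (!dup) { a <- c(a, e[1]); b <- c(b, e[2]) }
  }
  edges <- data.frame(gene_a = a, gene_b = b,
                      type = rep(type, length.out = length(a)),
                      stringsAsFactors = FALSE)
  list(edges = edges, candidates = cand, planted_linkers = linkers)
}

#' Random qPCR Ct-table fixture with planted expression shifts
#'
#' Simulates a sensitive-pool vs resistant-pool qPCR experiment: each
#' gene has a baseline Ct (cycles), the reference gene a lower one, and
#' the resistant pool's Ct for gene *g* is shifted by `effect_sizes[g]`
#' cycles (a planted delta-delta-Ct; positive shift = lower expression
#' in the resistant pool).  Biological-replicate noise is Gaussian on
#' ΔCt scale; technical replicates add smaller Gaussian noise.
#'
#' @param genes character vector of target gene names.
#' @param n_bio_reps biological replicates per pool.
#' @param effect_sizes numeric vector (recycled) of planted resistant −
#'   sensitive Ct shifts, cycles.
#' @param sexes sexes to simulate.
#' @param reference reference (normalizer) gene name.
#' @param bio_sd between-biological-replicate SD, cycles.
#' @param tech_sd technical replicate SD, cycles.
#' @param n_tech technical replicates.
#' @param seed integer seed.
#' @return a Ct table `data.frame`: `gene`, `sex`, `pool`, `bio_rep`,
#'   `tech_rep`, `ct`, with the reference gene present in every stratum.
#' @export
make_fixture_ct_table <- function(genes, n_bio_reps = 6, effect_sizes = 0,
                                  sexes = c("F", "M"), reference = "Gpdh",
                                  bio_sd = 0.3, tech_sd = 0.1, n_tech = 3,
                                  seed = 1L) {
  stopifnot(n_bio_reps >= 1, n_tech >= 1, bio_sd >= 0, tech_sd >= 0)
  set.seed(derive_seed(seed, "ct_fixture"))
  effect_sizes <- rep(effect_sizes, length.out = length(genes))
  base_ct <- setNames(runif(length(genes), 22, 28), genes)
  ref_ct <- 18
  rows <- list()
  for (sx in sexes) for (pool in c("sensitive", "resistant"))
    for (br in seq_len(n_bio_reps)) {
      plate_shift <- rnorm(1, 0, 0.2)   # common to all wells of a stratum
      add_gene <- function(g, mu) {
        data.frame(gene = g, sex = sx, pool = pool, bio_rep = br,
                   tech_rep = seq_len(n_tech),
                   ct = mu + plate_shift + rnorm(n_tech, 0, tech_sd),
                   stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- add_gene(reference, ref_ct)
      for (i in seq_along(genes)) {
        mu <- base_ct[i] + rnorm(1, 0, bio_sd) +
          if (pool == "resistant") effect_sizes[i] else 0
        rows[[length(rows) + 1L]] <- add_gene(genes[i], mu)
      }
    }
  out <- do.call(rbind, rows)
  attr(out, "reference") <- reference
  out
}
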