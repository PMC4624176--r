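#' Assign variants to genes by windowed interval overlap
#'
#' A variant is assigned to every gene whose body, extended by
#' `window_bp` on both sides, contains it.  Variants in gene deserts
#' (no gene within the window) stay unassigned.  Overlap is computed
#' with `GenomicRanges::findOverlaps`.
#'
#' @param variants `data.frame` with `chrom` and `pos` (1-based).
#' @param catalog gene catalog `data.frame` with `gene`, `chrom`,
#'   `start`, `end` (1-based inclusive), as from [read_gene_catalog()].
#' @param window_bp flanking window in bp (default 1000).
#' @return `data.frame` with `variant` (row index into `variants`),
#'   `chrom`, `pos`, `gene`.
#' @export
annotate_variants <- function(variants, catalog, window_bp = 1000) {
  stopifnot(nrow(catalog) > 0, all(c("chrom", "pos") %in% names(variants)),
            all(c("gene", "chrom", "start", "end") %in% names(catalog)))
  if (any(catalog$start > catalog$end))
    stop("malformed gene interval(s): start > end for ",
         paste(catalog$gene[catalog$start > catalog$end], collapse = ", "))
  v <- GenomicRanges::GRanges(variants$chrom,
                              IRanges::IRanges(variants$pos, variants$pos))
  g <- GenomicRanges::GRanges(catalog$chrom,
                              IRanges::IRanges(pmax(1, catalog$start - window_bp),
                                               catalog$end + window_bp))
  hits <- GenomicRanges::findOverlaps(v, g)
  out <- data.frame(variant = S4Vectors::queryHits(hits),
                    chrom = variants$chrom[S4Vectors::queryHits(hits)],
                    pos = variants$pos[S4Vectors::queryHits(hits)],
                    gene = catalog$gene[S4Vectors::subjectHits(hits)],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Genes recurring across analyses
#'
#' Counts, for each gene, how many per-analysis candidate sets it
#' appears in, and returns those reaching `min_analyses`.  Genes hit in
#' several independent sex/exposure analyses are unlikely to all be
#' false positives even when no single analysis is genome-wide
#' significant — this recurrence is the overlap statistic tested by
#' [overlap_permutation_test()].
#'
#' @param sets named list of character vectors (one candidate-gene set
#'   per analysis).
#' @param min_analyses minimum number of sets a gene must occur in
#'   (default 2).
#' @return character vector of recurring genes (sorted).
#' @export
overlap_count <- function(sets, min_analyses = 2) {
  stopifnot(length(sets) >= 2)
  cnt <- table(unlist(lapply(sets, unique)))
  sort(names(cnt)[cnt >= min_analyses])
}

#' Permutation null for cross-analysis gene overlap
#'
#' Replaces each analysis's candidate set by a uniform random draw of
#' the same size from the universe of testable genes, recomputes the
#' number of genes recurring in at least `min_analyses` sets, and
#' reports the add-one empirical p-value
#' `p = (1 + #\{permuted >= observed\}) / (B + 1)` — so the smallest
#' attainable value with `B = 1000` is `1/1001` (0.001 to three
#' decimals).
#'
#' @param sets named list of per-analysis candidate-gene sets.
#' @param universe character vector of all testable genes; must contain
#'   every set.
#' @param B number of permutations (default 1000).
#' @param seed integer seed.
#' @param min_analyses recurrence threshold passed to [overlap_count()].
#' @return list with `observed` (count and gene list), `perm_counts`,
#'   `p`.
#' @export
overlap_permutation_test <- function(sets, universe, B = 1000, seed = 1L,
                                     min_analyses = 2) {
  stopifnot(B >= 1, length(sets) >= 2)
  sizes <- lengths(lapply(sets, unique))
  if (any(sizes > length(universe)))
    stop("candidate set(s) larger than the universe: ",
         paste(names(sets)[sizes > length(universe)], collapse = ", "))
  missing <- setdiff(unique(unlist(sets)), universe)
  if (length(missing))
    stop("genes outside the universe: ", paste(head(missing, 5), collapse = ", "))
  obs_genes <- overlap_count(sets, min_analyses)
  obs <- length(obs_genes)
  set.seed(derive_seed(seed, "overlap_perm"))
  perm <- integer(B)
  for (b in seq_len(B)) {
    rnd <- lapply(sizes, function(k) sample(universe, k))
    perm[b] <- length(overlap_count(rnd, min_analyses))
  }
  list(observed = obs, genes = obs_genes, perm_counts = perm,
       p = (1 + sum(perm >= obs)) / (B + 1))
}

#' Intersection of candidate genes from two mapping populations
#'
#' @param dgrp_genes,xqtl_genes character vectors of candidate genes
#'   from the two analyses (e.g. an inbred reference panel and an
#'   extreme-QTL cross).
#' @return list with `common` (sorted intersection), `n_common`, and the
#'   per-source counts.
#' @export
cross_population_overlap <- function(dgrp_genes, xqtl_genes) {
  common <- sort(intersect(unique(dgrp_genes), unique(xqtl_genes)))
  list(common = common, n_common = length(common),
       n_dgrp = length(unique(dgrp_genes)),
       n_xqtl = length(unique(xqtl_genes)))
}
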