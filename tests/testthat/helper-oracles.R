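## Independent brute-force oracles used across tests.  These deliberately
## avoid the package's own code paths.

## All-pairs interval test: variant i assigned to gene j iff
## start_j - w <= pos_i <= end_j + w on the same chromosome.
brute_annotate <- function(variants, catalog, window_bp) {
  out <- NULL
  for (i in seq_len(nrow(variants))) {
    for (j in seq_len(nrow(catalog))) {
      if (variants$chrom[i] == catalog$chrom[j] &&
          variants$pos[i] >= catalog$start[j] - window_bp &&
          variants$pos[i] <= catalog$end[j] + window_bp) {
        out <- rbind(out, data.frame(variant = i, gene = catalog$gene[j]))
      }
    }
  }
  out
}

## One-linker subnetwork by exhaustive enumeration of length-<=2
## candidate-to-candidate paths over the adjacency matrix.
brute_subnetwork <- function(edges, candidates, allow_missing = 1) {
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  A <- matrix(FALSE, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (k in seq_len(nrow(edges))) {
    a <- edges$gene_a[k]; b <- edges$gene_b[k]
    if (a != b) { A[a, b] <- TRUE; A[b, a] <- TRUE }
  }
  cand <- intersect(candidates, nodes)
  keep_edges <- character(0)
  ekey <- function(a, b) paste(sort(c(a, b)), collapse = "|")
  for (c1 in cand) for (c2 in cand) {
    if (c1 < c2 && A[c1, c2]) keep_edges <- c(keep_edges, ekey(c1, c2))
  }
  if (allow_missing == 1) {
    noncand <- setdiff(nodes, cand)
    for (x in noncand) {
      nb <- cand[A[x, cand]]
      if (length(nb) >= 2) {
        for (c1 in nb) keep_edges <- c(keep_edges, ekey(x, c1))
      }
    }
  }
  sort(unique(keep_edges))
}

edge_keys <- function(g) {
  el <- igraph::as_edgelist(g)
  sort(apply(el, 1, function(e) paste(sort(e), collapse = "|")))
}

## One-sided Fisher p by full enumeration of all 2x2 tables with the
## observed margins: P(X >= x11) under the hypergeometric null.
brute_fisher_greater <- function(tab) {
  x11 <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  ks <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, ks) * choose(r2, c1 - ks) / choose(r1 + r2, c1)
  sum(pr[ks >= x11])
}

## Textbook pooled-variance two-sample t.
brute_student_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  tv <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tv, df = n1 + n2 - 2, p = 2 * pt(-abs(tv), n1 + n2 - 2))
}

## Small balanced AIP test panel shared by several files.
toy_panel <- function(n_lines = 6, n_sites = 20, seed = 11,
                      private_fraction = 0.2) {
  make_founder_panel(n_lines, n_sites, private_fraction, seed = seed)
}
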