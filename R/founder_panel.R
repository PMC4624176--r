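#' Default genetic map for the simulator
#'
#' Three major chromosomes with map lengths and physical lengths in the
#' range typical of *Drosophila melanogaster* (X about 66 cM, the two
#' large autosomes about 108 and 110 cM).  Recombination rate is assumed
#' uniform along each chromosome, so genetic position is a linear rescale
#' of physical position.
#'
#' @param chroms character vector of chromosome names.
#' @param length_cM numeric vector of sex-averaged female map lengths in
#'   centimorgans, one per chromosome.
#' @param length_bp numeric vector of physical lengths in base pairs.
#' @return a `data.frame` with columns `chrom`, `length_cM`, `length_bp`.
#' @export
default_genetic_map <- function(chroms = c("X", "2", "3"),
                                length_cM = c(66, 108, 110),
                                length_bp = c(23e6, 44e6, 50e6)) {
  stopifnot(length(chroms) == length(length_cM),
            length(chroms) == length(length_bp),
            all(length_cM >= 0), all(length_bp > 0))
  data.frame(chrom = as.character(chroms), length_cM = length_cM,
             length_bp = length_bp, stringsAsFactors = FALSE)
}

#' Convert physical to genetic position
#'
#' @param map genetic map as from [default_genetic_map()].
#' @param chrom chromosome names (recycled against `pos`).
#' @param pos 1-based physical positions in bp.
#' @return genetic positions in cM under the uniform-rate map.
#' @export
pos_to_cM <- function(map, chrom, pos) {
  i <- match(as.character(chrom), map$chrom)
  if (anyNA(i)) stop("unknown chromosome: ",
                     paste(unique(chrom[is.na(i)]), collapse = ", "))
  map$length_cM[i] * pos / map$length_bp[i]
}

#' Simulate a panel of fully inbred founder lines
#'
#' Generates a biallelic site panel segregating among `n_lines` fully
#' homozygous inbred lines, the raw material for building a multiparental
#' advanced intercross population (AIP).  A configurable fraction of
#' sites is private (the alternate allele carried by exactly one line);
#' such alleles enter the base AIP at frequency `1/n_lines` (0.167 for
#' six founders).  The remaining sites carry the alternate allele in a
#' random subset of two or more (but not all) lines, so every site
#' segregates and singletons arise only from `private_fraction`.
#'
#' @param n_lines number of founder lines (>= 2).
#' @param n_sites_per_chrom number of segregating sites per chromosome.
#' @param private_fraction fraction of sites private to a single line.
#' @param seed integer seed.
#' @param map genetic map (see [default_genetic_map()]).
#' @param line_ids optional founder labels; default `L1..Ln`.
#' @return an object of class `founder_panel`: a list with `line_ids`,
#'   `sites` (data.frame: chrom, pos, ref, alt), `geno` (sites x lines
#'   0/1 matrix; lines are homozygous so one allele per line suffices)
#'   and `map`.
#' @export
make_founder_panel <- function(n_lines, n_sites_per_chrom,
                               private_fraction = 0.2, seed = 1L,
                               map = default_genetic_map(),
                               line_ids = NULL) {
  stopifnot(n_lines >= 2, private_fraction >= 0, private_fraction <= 1)
  if (n_sites_per_chrom < 1)
    stop("n_sites_per_chrom must be >= 1: an empty panel has no segregating sites")
  if (is.null(line_ids)) line_ids <- paste0("L", seq_len(n_lines))
  stopifnot(length(line_ids) == n_lines)
  set.seed(derive_seed(seed, "founder_panel"))

  sites <- do.call(rbind, lapply(seq_len(nrow(map)), function(k) {
    pos <- sort(sample.int(map$length_bp[k] - 1L, n_sites_per_chrom))
    data.frame(chrom = map$chrom[k], pos = pos, stringsAsFactors = FALSE)
  }))
  nt <- c("A", "C", "G", "T")
  sites$ref <- sample(nt, nrow(sites), replace = TRUE)
  sites$alt <- vapply(sites$ref, function(r) sample(setdiff(nt, r), 1L), "")

  m <- nrow(sites)
  geno <- matrix(0L, m, n_lines, dimnames = list(NULL, line_ids))
  is_private <- runif(m) < private_fraction
  for (j in seq_len(m)) {
    if (is_private[j] || n_lines == 2L) {
      geno[j, sample.int(n_lines, 1L)] <- 1L
    } else {
      ## shared segregating site: alt allele in 2 .. n-1 lines, so the
      ## private fraction is controlled exactly by private_fraction
      k <- if (n_lines == 3L) 2L else sample(2:(n_lines - 1L), 1L)
      geno[j, sample.int(n_lines, k)] <- 1L
    }
  }
  structure(list(line_ids = line_ids, sites = sites, geno = geno, map = map),
            class = "founder_panel")
}

#' @exportS3Method base::print
print.founder_panel <- function(x, ...) {
  cat("Founder panel:", length(x$line_ids), "inbred lines,",
      nrow(x$sites), "biallelic sites on",
      length(unique(x$sites$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Genetic position of every panel site
#' @param panel a `founder_panel`.
#' @return numeric vector of cM positions, parallel to `panel$sites`.
#' @export
site_cM <- function(panel) {
  pos_to_cM(panel$map, panel$sites$chrom, panel$sites$pos)
}

#' Base-population allele frequency of each panel site
#'
#' Frequency of the alternate allele in a base population in which every
#' founder line contributes equally (as under a balanced diallel cross).
#'
#' @param panel a `founder_panel`.
#' @return numeric vector of frequencies in `[0, 1]`.
#' @export
founder_allele_freq <- function(panel) {
  rowMeans(panel$geno)
}
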