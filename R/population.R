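## Haplotypes are founder mosaics: per chromosome a pair of parallel
## vectors, `f` (founder index into panel$line_ids) and `e` (segment end
## positions in cM, strictly increasing, last element = chromosome map
## length).  Segment i covers the half-open genetic interval
## (e[i-1], e[i]], with e[0] = 0.  This is the standard ancestry-tracking
## representation for forward simulation of multiparental populations:
## genotypes at any site are recovered by founder lookup, so the panel's
## site dimension never enters the per-generation cost.

new_haplotype <- function(founder, length_cM) {
  list(f = as.integer(founder), e = as.numeric(length_cM))
}

## Segments of (f, e) overlapping (from, to]; last end clipped to `to`.
extract_interval <- function(f, e, from, to) {
  i1 <- findInterval(from, e) + 1L                  # first end > from
  i2 <- findInterval(to, e, left.open = TRUE) + 1L  # first end >= to
  if (i2 > length(e)) i2 <- length(e)
  idx <- i1:i2
  ee <- e[idx]
  ee[length(ee)] <- to
  list(f = f[idx], e = ee)
}

## One meiotic product for a single chromosome.  Crossover count is
## Poisson with mean = map length in Morgans, positions uniform, no
## interference.  With recomb = FALSE (achiasmatic male meiosis) a
## whole parental chromatid is transmitted.
gamete_chrom <- function(hapA, hapB, length_cM, recomb) {
  if (!recomb || length_cM <= 0) {
    return(if (runif(1) < 0.5) hapA else hapB)
  }
  nco <- rpois(1L, length_cM / 100)
  if (nco == 0L) return(if (runif(1) < 0.5) hapA else hapB)
  br <- sort(runif(nco, 0, length_cM))
  src <- if (runif(1) < 0.5) list(hapA, hapB) else list(hapB, hapA)
  bounds <- c(0, br, length_cM)
  f <- integer(0); e <- numeric(0)
  for (k in seq_len(length(bounds) - 1L)) {
    h <- src[[(k - 1L) %% 2L + 1L]]
    seg <- extract_interval(h$f, h$e, bounds[k], bounds[k + 1L])
    f <- c(f, seg$f); e <- c(e, seg$e)
  }
  keep <- c(f[-1L] != f[-length(f)], TRUE)
  list(f = f[keep], e = e[keep])
}

gamete <- function(ind, lengths_cM, recomb) {
  n <- length(lengths_cM)
  g <- vector("list", n)
  for (k in seq_len(n)) g[[k]] <- gamete_chrom(ind$h1[[k]], ind$h2[[k]],
                                               lengths_cM[k], recomb)
  names(g) <- names(lengths_cM)
  g
}

new_population <- function(individuals, generation, census_size, lengths_cM) {
  structure(list(individuals = individuals, generation = generation,
                 census_size = census_size, lengths_cM = lengths_cM),
            class = "aip_population")
}

#' @exportS3Method base::print
print.aip_population <- function(x, ...) {
  cat("AIP population: ", length(x$individuals), " diploid individuals, ",
      "generation ", x$generation, ", census size ", x$census_size, "\n",
      sep = "")
  invisible(x)
}

#' Found a base population by a balanced partial diallel cross
#'
#' Crosses every unordered pair of distinct founder lines (15 pairs for
#' 6 lines) and produces the same number of F1 offspring per pair, so
#' each founder contributes exactly `1/n_lines` of the haplotypes in the
#' base population and an allele private to one founder starts at
#' frequency `1/n_lines` (0.167 for six founders).  Within-line crosses
#' are excluded.
#'
#' @param panel a [make_founder_panel()] object.
#' @param size number of diploid individuals; must be divisible by the
#'   number of line pairs.
#' @param seed integer seed (used only to shuffle individual order).
#' @return an `aip_population` at generation 0.
#' @export
diallel_base_population <- function(panel, size, seed = 1L) {
  n <- length(panel$line_ids)
  pairs <- t(utils::combn(n, 2L))
  npair <- nrow(pairs)
  if (size %% npair != 0L)
    stop("size must be a multiple of the number of founder pairs (",
         npair, " for ", n, " lines)")
  set.seed(derive_seed(seed, "diallel"))
  lengths_cM <- setNames(panel$map$length_cM, panel$map$chrom)
  per <- size %/% npair
  inds <- vector("list", size)
  k <- 0L
  for (p in seq_len(npair)) {
    h1 <- lapply(lengths_cM, function(L) new_haplotype(pairs[p, 1L], L))
    h2 <- lapply(lengths_cM, function(L) new_haplotype(pairs[p, 2L], L))
    for (r in seq_len(per)) {
      k <- k + 1L
      inds[[k]] <- list(h1 = h1, h2 = h2)
    }
  }
  inds <- inds[sample.int(size)]
  new_population(inds, 0L, size, lengths_cM)
}

#' Advance a population by random mating
#'
#' Each generation draws, for every offspring, an ordered pair of
#' distinct parents uniformly at random (random union of gametes;
#' selfing excluded).  The dam's gamete recombines; the sire's does not
#' when `female_meiosis_only = TRUE` (the default — *Drosophila* males
#' are achiasmatic), so the effective recombination rate is half the
#' female map rate.
#'
#' @param pop an `aip_population`.
#' @param n_gen number of generations to advance (>= 0).
#' @param panel the founder panel (supplies the genetic map).
#' @param seed integer seed.
#' @param census_size per-generation census size; defaults to the
#'   population's current size.
#' @param female_meiosis_only logical; set `FALSE` for recombination in
#'   both sexes.
#' @return the advanced `aip_population`.
#' @export
advance_generations <- function(pop, n_gen, panel, seed = 1L,
                                census_size = NULL,
                                female_meiosis_only = TRUE) {
  if (n_gen < 0) stop("n_gen must be >= 0")
  if (length(pop$individuals) == 0L) stop("population is empty")
  if (n_gen == 0L) return(pop)
  if (is.null(census_size)) census_size <- length(pop$individuals)
  set.seed(derive_seed(seed, "advance"))
  for (g in seq_len(n_gen)) {
    pop <- mate_one_generation(pop, census_size, female_meiosis_only)
  }
  pop
}

#' Draw a single offspring cohort
#'
#' One extra round of random mating producing `n` offspring without
#' replacing the parental population — e.g. the large assay cohort
#' scored for phenotypes and truncation-selected for pooled sequencing.
#'
#' @inheritParams advance_generations
#' @param n cohort size.
#' @return an `aip_population` of `n` individuals, generation + 1.
#' @export
sample_offspring <- function(pop, n, panel, seed = 1L,
                             female_meiosis_only = TRUE) {
  stopifnot(n >= 1, length(pop$individuals) >= 2L)
  set.seed(derive_seed(seed, "offspring"))
  mate_one_generation(pop, n, female_meiosis_only)
}

mate_one_generation <- function(pop, n_off, female_meiosis_only) {
  npar <- length(pop$individuals)
  if (npar < 2L) stop("need at least 2 individuals for selfing-free mating")
  off <- vector("list", n_off)
  L <- pop$lengths_cM
  sire_recomb <- !female_meiosis_only
  for (i in seq_len(n_off)) {
    p <- sample.int(npar, 2L)              # without replacement: no selfing
    off[[i]] <- list(h1 = gamete(pop$individuals[[p[1L]]], L, TRUE),
                     h2 = gamete(pop$individuals[[p[2L]]], L, sire_recomb))
  }
  new_population(off, pop$generation + 1L, n_off, L)
}

hap_founders_at <- function(hap, pos_cM) {
  hap$f[findInterval(pos_cM, hap$e, left.open = TRUE) + 1L]
}

#' Diploid allele dosages at panel sites
#'
#' Looks up founder ancestry of both haplotypes at each requested site
#' and translates it to alternate-allele dosage (0/1/2) through the
#' founder genotypes.
#'
#' @param pop an `aip_population`.
#' @param panel the founder panel.
#' @param site_idx integer indices into `panel$sites`; default all.
#' @return integer matrix, individuals x sites.
#' @export
dosage_matrix <- function(pop, panel, site_idx = NULL) {
  if (is.null(site_idx)) site_idx <- seq_len(nrow(panel$sites))
  cm <- site_cM(panel)[site_idx]
  ch <- panel$sites$chrom[site_idx]
  n <- length(pop$individuals)
  D <- matrix(0L, n, length(site_idx))
  chrom_names <- names(pop$lengths_cM)
  for (chrom in unique(ch)) {
    sel <- which(ch == chrom)
    pos <- cm[sel]
    gsub <- panel$geno[site_idx[sel], , drop = FALSE]
    ci <- match(chrom, chrom_names)
    for (i in seq_len(n)) {
      ind <- pop$individuals[[i]]
      f1 <- hap_founders_at(ind$h1[[ci]], pos)
      f2 <- hap_founders_at(ind$h2[[ci]], pos)
      D[i, sel] <- gsub[cbind(seq_along(sel), f1)] +
                   gsub[cbind(seq_along(sel), f2)]
    }
  }
  D
}

#' Genome-wide founder ancestry fractions
#'
#' Length-weighted share of each founder line over all haplotypes in the
#' population.  Always sums to 1.
#'
#' @param pop an `aip_population`.
#' @param panel the founder panel.
#' @return named numeric vector, one share per founder line.
#' @export
ancestry_fractions <- function(pop, panel) {
  nf <- length(panel$line_ids)
  tot <- numeric(nf)
  for (ind in pop$individuals) {
    for (h in list(ind$h1, ind$h2)) {
      for (hc in h) {
        lens <- diff(c(0, hc$e))
        for (k in seq_along(hc$f)) tot[hc$f[k]] <- tot[hc$f[k]] + lens[k]
      }
    }
  }
  setNames(tot / sum(tot), panel$line_ids)
}
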