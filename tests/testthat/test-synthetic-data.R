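test_that("founder panels are homozygous, biallelic, ordered, and honour private_fraction", {
  panel <- make_founder_panel(6, 50, private_fraction = 0.3, seed = 7)
  expect_true(all(panel$geno %in% c(0L, 1L)))
  expect_true(all(panel$sites$ref != panel$sites$alt))
  for (ch in unique(panel$sites$chrom)) {
    pos <- panel$sites$pos[panel$sites$chrom == ch]
    expect_true(all(diff(pos) > 0))
  }
  ## every site segregates: alt in a non-empty proper subset of lines
  rs <- rowSums(panel$geno)
  expect_true(all(rs >= 1 & rs <= 5))
  ## a private site enters an equal-contribution base population at 1/6
  priv <- which(rs == 1)
  expect_gt(length(priv), 0)
  expect_equal(unique(founder_allele_freq(panel)[priv]), 1 / 6)

  none <- make_founder_panel(6, 40, private_fraction = 0, seed = 8)
  expect_false(any(rowSums(none$geno) == 1))

  two <- make_founder_panel(2, 10, seed = 9)
  ## exhaustive scan: with 2 lines every site must differ between them
  for (j in seq_len(nrow(two$sites)))
    expect_true(two$geno[j, 1] != two$geno[j, 2])

  expect_error(make_founder_panel(6, 0), "empty")
})

test_that("diallel base population represents each founder equally and excludes selfs", {
  panel <- toy_panel()
  expect_error(diallel_base_population(panel, 301), "15")

  pop <- diallel_base_population(panel, 300, seed = 2)
  expect_equal(pop$generation, 0L)
  af <- ancestry_fractions(pop, panel)
  expect_equal(unname(af), rep(1 / 6, 6))
  ## no within-line crosses: the two haplotypes of any F1 differ
  for (ind in pop$individuals)
    expect_false(ind$h1[[1]]$f == ind$h2[[1]]$f)

  ## private allele frequency = 1/6 exactly at generation 0
  priv <- which(rowSums(panel$geno) == 1)
  D <- dosage_matrix(pop, panel, priv)
  expect_equal(unname(colSums(D) / (2 * 300)), rep(1 / 6, length(priv)))

  ## 2 founders: every individual is an F1, heterozygous at every site
  p2 <- make_founder_panel(2, 8, seed = 5)
  f1 <- diallel_base_population(p2, 10, seed = 3)
  D2 <- dosage_matrix(f1, p2)
  expect_true(all(D2 == 1))   # all sites differ between 2 founders
})

test_that("advance_generations: identity at n_gen 0, no recombination on a 0 cM map, drift is unbiased", {
  panel <- toy_panel()
  pop <- diallel_base_population(panel, 60, seed = 1)
  expect_identical(advance_generations(pop, 0, panel), pop)
  expect_error(advance_generations(pop, -1, panel), "n_gen")

  ## 0 cM map: transmitted haplotypes are unrecombined parental copies
  map0 <- default_genetic_map(length_cM = c(0, 0, 0))
  panel0 <- make_founder_panel(6, 10, seed = 2, map = map0)
  pop0 <- diallel_base_population(panel0, 60, seed = 2)
  adv0 <- advance_generations(pop0, 3, panel0, seed = 3)
  for (ind in adv0$individuals) {
    for (h in c(ind$h1, ind$h2)) expect_length(h$f, 1L)
  }

  ## neutral-site frequency is a martingale: over replicate runs the
  ## mean final frequency matches the initial frequency, and the
  ## across-replicate variance grows with time (drift)
  reps <- 60
  p_short <- p_long <- numeric(reps)
  site <- which(rowSums(panel$geno) == 3)[1]   # p0 = 0.5
  for (r in seq_len(reps)) {
    base <- diallel_base_population(panel, 60, seed = 100 + r)
    a <- advance_generations(base, 3, panel, seed = 200 + r)
    p_short[r] <- sum(dosage_matrix(a, panel, site)) / 120
    b <- advance_generations(a, 9, panel, seed = 300 + r)
    p_long[r] <- sum(dosage_matrix(b, panel, site)) / 120
  }
  se <- sd(p_long) / sqrt(reps)
  expect_lt(abs(mean(p_long) - 0.5), 4 * se + 1e-9)
  expect_gt(var(p_long), var(p_short))
})

test_that("achiasmatic males halve the effective recombination rate", {
  ## single 100 cM chromosome; junction count per haplotype grows at
  ## about t * L_Morgan per transmitted female gamete, so with
  ## recombination in females only the population-average junction
  ## count is about half that with recombination in both sexes
  map1 <- default_genetic_map("2", 100, 40e6)
  panel <- make_founder_panel(6, 5, seed = 4, map = map1)
  count_junctions <- function(pop) {
    mean(vapply(pop$individuals,
                function(i) (length(i$h1[[1]]$f) + length(i$h2[[1]]$f)) / 2 - 1,
                numeric(1)))
  }
  jf <- jb <- numeric(12)
  for (r in seq_len(12)) {
    base <- diallel_base_population(panel, 150, seed = r)
    jf[r] <- count_junctions(advance_generations(base, 8, panel, seed = 50 + r,
                                                 female_meiosis_only = TRUE))
    jb[r] <- count_junctions(advance_generations(base, 8, panel, seed = 80 + r,
                                                 female_meiosis_only = FALSE))
  }
  expect_gt(mean(jf) / mean(jb), 0.38)
  expect_lt(mean(jf) / mean(jb), 0.62)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  panel <- toy_panel()
  p1 <- diallel_base_population(panel, 60, seed = 5)
  p2 <- diallel_base_population(panel, 60, seed = 5)
  a1 <- advance_generations(p1, 5, panel, seed = 6)
  a2 <- advance_generations(p2, 5, panel, seed = 6)
  expect_identical(a1, a2)
  e1 <- simulate_elution(a1, phenotype_model(), seed = 7)
  e2 <- simulate_elution(a2, phenotype_model(), seed = 7)
  expect_identical(e1, e2)
})

test_that("haplotype segments tile each chromosome and ancestry sums to one", {
  panel <- toy_panel()
  pop <- advance_generations(diallel_base_population(panel, 90, seed = 1),
                             10, panel, seed = 2)
  L <- setNames(panel$map$length_cM, panel$map$chrom)
  for (ind in pop$individuals[1:20]) {
    for (h in list(ind$h1, ind$h2)) {
      for (k in seq_along(h)) {
        expect_true(all(diff(h[[k]]$e) > 0))
        expect_equal(h[[k]]$e[length(h[[k]]$e)], unname(L[k]))
      }
    }
  }
  expect_equal(sum(ancestry_fractions(pop, panel)), 1)
})

test_that("elution phenotypes follow the additive model and 1-minute binning", {
  panel <- make_founder_panel(2, 8, seed = 5)
  ## noise-free limit, no QTLs: every fly elutes at its bin edge
  m0 <- phenotype_model(grand_mean = 6, residual_sd = 0, sex_effect = 0,
                        tolerance_shift = 2)
  e <- simulate_elution(panel, m0, n_flies = 5, exposure = "E1", seed = 1)
  expect_true(all(e$minute == 6))
  ## non-integer means are ceilinged to the next bin edge
  m5 <- phenotype_model(grand_mean = 5.2, residual_sd = 0, sex_effect = 0)
  expect_true(all(simulate_elution(panel, m5, n_flies = 3, seed = 1)$minute == 6))
  expect_error(simulate_elution(panel, m0, exposure = "E3"), "exposure")

  ## tolerance shift: mean(E2) - mean(E1) converges to the shift
  mt <- phenotype_model(grand_mean = 6.3, residual_sd = 2, sex_effect = 0,
                        tolerance_shift = 2)
  e1 <- simulate_elution(panel, mt, n_flies = 10000, exposure = "E1", seed = 2)
  e2 <- simulate_elution(panel, mt, n_flies = 10000, exposure = "E2", seed = 3)
  expect_lt(abs(mean(e2$minute) - mean(e1$minute) - 2), 0.08)

  ## single QTL of 1 min/allele: homozygote line classes differ by 2 min
  site <- which(panel$geno[, 1] != panel$geno[, 2])[1]
  mq <- phenotype_model(qtl_sites = site, qtl_effects = 1, grand_mean = 6.3,
                        residual_sd = 1.5, sex_effect = 0)
  eq <- simulate_elution(panel, mq, n_flies = 8000, seed = 4)
  cls <- tapply(eq$minute, panel$geno[site, eq$id], mean)
  expect_lt(abs(abs(cls["1"] - cls["0"]) - 2), 0.1)
})

test_that("simulate_dgrp_fly_data matches its generating moments", {
  ## zero-variance spec: observations are exactly mu +/- half the fixed
  ## factor effect
  s0 <- varcomp_spec(0, 0, 0, 0, n_lines = 3, n_reps = 2,
                     n_flies_per_rep = 2, grand_mean = 7, factor_effect = 1)
  d0 <- simulate_dgrp_fly_data(s0, seed = 1)
  expect_equal(sort(unique(round(d0$minute, 10))), c(6.5, 7.5))

  ## moment recovery on a large draw
  sp <- varcomp_spec(2, 0.5, 0.25, 3, n_lines = 400, n_reps = 2,
                     n_flies_per_rep = 30)
  d <- simulate_dgrp_fly_data(sp, seed = 2)
  expect_equal(nrow(d), 400 * 2 * 2 * 30)
  vc <- partition_variance(d, "sex")
  expect_lt(abs(vc$components[["sigma2_L"]] - 2), 0.6)
  expect_lt(abs(vc$components[["sigma2_LxF"]] - 0.5), 0.25)
  expect_lt(abs(vc$components[["sigma2_Rep"]] - 0.25), 0.12)
  expect_lt(abs(vc$components[["sigma2_eps"]] - 3), 0.1)
})

test_that("pool-seq counts follow pool frequency and depth sampling", {
  panel <- make_founder_panel(2, 30, seed = 6)
  pop <- diallel_base_population(panel, 40, seed = 1)
  ## force homozygosity for founder 1: pools fixed for founder-1 alleles
  for (i in seq_along(pop$individuals))
    pop$individuals[[i]]$h2 <- pop$individuals[[i]]$h1
  fixed_alt <- which(pop$individuals[[1]]$h1[[1]]$f == 1)
  sel <- list(sensitive = 1:20, resistant = 21:40)
  pc <- simulate_pool_seq(pop, sel, panel, mean_depth = 30, seed = 2)
  alt_in_1 <- panel$geno[segregating_sites(panel), 1] == 1
  expect_true(all(pc$alt_S[alt_in_1] == pc$d_S[alt_in_1]))
  expect_true(all(pc$alt_S[!alt_in_1] == 0))

  ## frequency 0.5 pools: mean estimate within Monte-Carlo error
  f1 <- diallel_base_population(panel, 300, seed = 3)   # all heterozygous
  sel2 <- list(sensitive = 1:150, resistant = 151:300)
  pc2 <- do.call(rbind, lapply(1:20, function(r)
    simulate_pool_seq(f1, sel2, panel, mean_depth = 50, seed = r)))
  est <- pc2$alt_S / pc2$d_S
  expect_lt(abs(mean(est) - 0.5), 4 * sd(est) / sqrt(length(est)))

  ## deep sequencing converges to the true pool frequency
  pc3 <- simulate_pool_seq(f1, sel2, panel, mean_depth = 20000, seed = 4)
  expect_lt(max(abs(pc3$alt_R / pc3$d_R - pc3$p_R_true)), 0.02)
})
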