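make_elu <- function(line, sex, date, minute, replicate = "R1") {
  data.frame(line = line, sex = sex, date = date, replicate = replicate,
             minute = minute, stringsAsFactors = FALSE)
}

test_that("control adjustment subtracts the per-date, per-sex control mean", {
  raw <- make_elu(line = c("ctrl", "ctrl", "A", "A"),
                  sex = "F", date = "D1", minute = c(6.0, 6.2, 8.0, 8.0))
  adj <- adjust_to_control(raw, "ctrl")
  expect_equal(adj$minute, c(1.9, 1.9))
  expect_false("ctrl" %in% adj$line)

  ## lines identical to the control adjust to zero
  same <- make_elu(line = c("ctrl", "A"), sex = "F", date = "D1",
                   minute = c(5, 5))
  expect_equal(adjust_to_control(same, "ctrl")$minute, 0)

  ## per-stratum subtraction: equal raw values on two dates with control
  ## means 6 and 7 end up 1.0 apart
  two <- make_elu(line = c("ctrl", "A", "ctrl", "A"),
                  sex = "F", date = c("D1", "D1", "D2", "D2"),
                  minute = c(6, 9, 7, 9))
  expect_equal(diff(adjust_to_control(two, "ctrl")$minute), -1.0)

  ## a stratum without control observations is an error naming it
  bad <- make_elu(line = c("ctrl", "A", "A"), sex = "F",
                  date = c("D1", "D1", "D2"), minute = c(6, 7, 8))
  expect_error(adjust_to_control(bad, "ctrl"), "D2")
})

test_that("variance partitioning matches an independent aov fit on a toy table", {
  ## 3 lines x 2 sexes x 2 reps x 2 flies, fixed values
  set.seed(42)
  toy <- expand.grid(fly = 1:2, replicate = c("R1", "R2"),
                     sex = c("F", "M"), line = c("l1", "l2", "l3"),
                     stringsAsFactors = FALSE)
  toy$minute <- c(5, 6, 7, 5, 8, 9, 6, 7, 4, 4, 5, 6, 7, 8, 8, 9,
                  6, 5, 7, 7, 9, 9, 10, 8)
  vc <- partition_variance(toy, "sex")

  ## independent oracle: aov error strata give the same mean squares
  fit <- suppressWarnings(summary(aov(minute ~ line * sex + Error(line:sex:replicate),
                     data = toy)))
  between <- as.data.frame(fit[[1]][[1]])
  within <- as.data.frame(fit[[2]][[1]])
  ms <- setNames(between[["Mean Sq"]], trimws(rownames(between)))
  ms_w <- within[["Mean Sq"]][1]
  expect_equal(vc$anova$MS, unname(c(ms["line"], ms["sex"], ms["line:sex"],
                                     ms["Residuals"], ms_w)))
  ## expected-mean-squares solution, written out by hand (f=2, r=2, s=2)
  expect_equal(vc$components[["sigma2_eps"]], ms_w)
  expect_equal(vc$components[["sigma2_Rep"]],
               max((ms[["Residuals"]] - ms_w) / 2, 0))
  expect_equal(vc$components[["sigma2_LxF"]],
               max((ms[["line:sex"]] - ms[["Residuals"]]) / 4, 0))
  expect_equal(vc$components[["sigma2_L"]],
               max((ms[["line"]] - ms[["line:sex"]]) / 8, 0))
})

test_that("H2 is near zero when lines do not differ, and components are truncated at zero", {
  sp <- varcomp_spec(0, 0, 0, 4, n_lines = 60, n_reps = 2,
                     n_flies_per_rep = 20)
  vc <- partition_variance(simulate_dgrp_fly_data(sp, seed = 3), "sex")
  expect_true(all(vc$components >= 0))
  expect_lt(vc$H2, 0.05)
  expect_gte(vc$H2, 0)
})

test_that("H2 is invariant to location shifts and rescaling", {
  sp <- varcomp_spec(2, 0.5, 0.3, 3, n_lines = 30, n_reps = 2,
                     n_flies_per_rep = 10)
  d <- simulate_dgrp_fly_data(sp, seed = 4)
  h <- partition_variance(d, "sex")$H2
  d_shift <- transform(d, minute = minute + 100)
  d_scale <- transform(d, minute = minute * 3.7)
  expect_equal(partition_variance(d_shift, "sex")$H2, h)
  expect_equal(partition_variance(d_scale, "sex")$H2, h)
})

test_that("crossed factor machinery is label-symmetric and sigma2_P optionally includes the replicate term", {
  sp <- varcomp_spec(2, 0.5, 0.3, 3, n_lines = 20, n_reps = 2,
                     n_flies_per_rep = 8)
  d_sex <- simulate_dgrp_fly_data(sp, seed = 5, factor_name = "sex")
  d_exp <- d_sex
  names(d_exp)[2] <- "exposure"
  v1 <- partition_variance(d_sex, "sex")
  v2 <- partition_variance(d_exp, "exposure")
  expect_equal(v1$components, v2$components)
  expect_equal(v1$H2, v2$H2)

  v3 <- partition_variance(d_sex, "sex", include_rep_in_P = TRUE)
  expect_equal(v3$sigma2_P, v1$sigma2_P + v1$components[["sigma2_Rep"]])
  expect_lte(v3$H2, v1$H2)
})

test_that("unbalanced tables are rejected and the subsampler restores balance", {
  sp <- varcomp_spec(1, 0.2, 0.1, 2, n_lines = 6, n_reps = 2,
                     n_flies_per_rep = 10)
  d <- simulate_dgrp_fly_data(sp, seed = 6)
  expect_error(partition_variance(d[-1, ], "sex"), "unbalanced")
  reb <- rebalance_elutions(d[-(1:3), ], "sex", seed = 1)
  expect_silent(partition_variance(reb, "sex"))
  ## rebalancing is a subset of the input
  expect_true(all(reb$minute %in% d$minute))
})

test_that("tolerance scores scale line differences by the mean difference", {
  e1 <- c(a = 5, b = 6, c = 7)
  e2 <- c(a = 9, b = 8, c = 7)
  tol <- tolerance_scores(e1, e2)
  ## hand value: denom = mean(E2) - mean(E1) = 2; line a: (9-5)/2 = 2
  expect_equal(tol$T[tol$line == "a"], 2)
  expect_equal(tol$T[tol$line == "c"], 0)     # E2 = E1
  expect_equal(mean(tol$T), 1)                # exact by construction
  ## a line whose difference equals the mean difference scores exactly 1
  expect_equal(tolerance_scores(c(x = 5, y = 7), c(x = 7, y = 9))$T,
               c(1, 1))
  expect_error(tolerance_scores(c(a = 5, b = 6), c(a = 6, b = 5)),
               "undefined")
})

test_that("cross-condition correlations are plain Pearson on line means", {
  lm5 <- data.frame(line = letters[1:5],
                    F_E1 = c(2, 4, 5, 7, 9),
                    M_E1 = c(1, 3, 6, 6, 10))
  r <- cross_correlations(lm5)
  ## textbook Pearson on the same numbers
  expect_equal(r["F_E1", "M_E1"], cor(lm5$F_E1, lm5$M_E1))
  expect_equal(unname(diag(r)), c(1, 1))

  ident <- data.frame(line = letters[1:4], a = 1:4, b = 1:4, c = -(1:4))
  r2 <- cross_correlations(ident)
  expect_equal(r2["a", "b"], 1)
  expect_equal(r2["a", "c"], -1)

  degen <- data.frame(line = letters[1:3], a = 1:3, b = rep(2, 3))
  expect_warning(r3 <- cross_correlations(degen), "zero variance")
  expect_true(is.na(r3["a", "b"]))
})

test_that("pooled SEM follows the root-sum-of-squares rule", {
  expect_equal(combined_sem(3, 4), 5)
  expect_equal(combined_sem(0, 2.3), 2.3)
  expect_equal(combined_sem(0.1, 0.1), sqrt(0.02))
  expect_error(combined_sem(-1, 2), "non-negative")
})

test_that("mutant ANOVA reproduces aov sums of squares and flags planted interactions", {
  grid <- expand.grid(fly = 1:4, replicate = c("R1", "R2"),
                      exposure = c("E1", "E2"), sex = c("F", "M"),
                      genotype = c("control", "mutant"),
                      stringsAsFactors = FALSE)
  set.seed(9)
  grid$minute <- 7 + 0.8 * (grid$genotype == "mutant") +
    0.5 * (grid$sex == "M") + rnorm(nrow(grid), 0, 0.5)
  res <- mutant_anova(grid)
  fit <- suppressWarnings(summary(aov(minute ~ genotype * sex * exposure +
                       Error(genotype:sex:exposure:replicate), data = grid)))
  between <- as.data.frame(fit[[1]][[1]])
  expect_equal(res$anova$SS[1:7], between[["Sum Sq"]][1:7])
  ## all factorial F ratios use the replicate mean square
  ms_rep <- between["Residuals", "Mean Sq"]
  expect_equal(res$anova$F[1:7], between[["Mean Sq"]][1:7] / ms_rep)
  ## effect summary: mutant - control with pooled SEM
  eff <- res$effects
  sub <- grid[grid$sex == "F" & grid$exposure == "E1", ]
  expect_equal(eff$difference[eff$sex == "F" & eff$exposure == "E1"],
               mean(sub$minute[sub$genotype == "mutant"]) -
                 mean(sub$minute[sub$genotype == "control"]))

  ## identical genotypes: no genetic term is significant in a noise-free table
  flat <- grid
  flat$minute <- 7 + 0.5 * (flat$sex == "M")
  res0 <- mutant_anova(flat)
  gp <- res0$anova$p[res0$anova$term %in% c("genotype", "genotype:sex",
                                            "genotype:exposure",
                                            "genotype:sex:exposure")]
  expect_true(all(is.na(gp) | gp > 0.99))

  expect_error(mutant_anova(grid[grid$genotype != "mutant", ]), "levels")
})

test_that("planted genotype-by-sex effects are detected at simulated power; null G:S stays at alpha", {
  run_once <- function(seed, gxs) {
    grid <- expand.grid(fly = 1:10, replicate = paste0("R", 1:3),
                        exposure = c("E1", "E2"), sex = c("F", "M"),
                        genotype = c("control", "mutant"),
                        stringsAsFactors = FALSE)
    set.seed(seed)
    grid$minute <- 7 + gxs * (grid$genotype == "mutant") * (grid$sex == "M") +
      rnorm(nrow(grid), 0, 1)
    p <- mutant_anova(grid)$anova
    p$p[p$term == "genotype:sex"]
  }
  p_alt <- vapply(1:40, run_once, numeric(1), gxs = 1.5)
  p_null <- vapply(41:80, run_once, numeric(1), gxs = 0)
  expect_gt(mean(p_alt < 0.05), 0.8)     # high power for a large effect
  expect_lt(mean(p_null < 0.05), 0.2)    # near-nominal false positive rate
})
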