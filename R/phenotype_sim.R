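#' Additive phenotype model for inebriometer elution times
#'
#' Per-fly elution time is modelled as
#' `grand_mean + sum(dosage * effect) + sex_effect (males) +
#' tolerance_shift (second exposure) + N(0, residual_sd)`,
#' then discretized to the upper edge of its collection bin: flies are
#' collected at fixed intervals (1 minute by default) as they fall
#' through the column, so an observed elution "time" is the bin edge.
#'
#' @param qtl_sites integer indices into the panel's site table.
#' @param qtl_effects additive effect per alternate allele, minutes.
#' @param grand_mean baseline mean elution time, minutes.
#' @param sex_effect minutes added for males (males typically elute
#'   later; sign is up to the caller).
#' @param tolerance_shift minutes added at the second exposure (E2).
#' @param residual_sd residual standard deviation, minutes (> 0).
#' @param bin_width collection interval, minutes (> 0).
#' @return an object of class `phenotype_model`.
#' @export
phenotype_model <- function(qtl_sites = integer(0), qtl_effects = numeric(0),
                            grand_mean = 7, sex_effect = 0.7,
                            tolerance_shift = 1.5, residual_sd = 2,
                            bin_width = 1) {
  stopifnot(length(qtl_sites) == length(qtl_effects),
            residual_sd > 0 || (residual_sd == 0),  # 0 allowed for limits
            bin_width > 0)
  structure(list(qtl_sites = as.integer(qtl_sites),
                 qtl_effects = as.numeric(qtl_effects),
                 grand_mean = grand_mean, sex_effect = sex_effect,
                 tolerance_shift = tolerance_shift,
                 residual_sd = residual_sd, bin_width = bin_width),
            class = "phenotype_model")
}

#' Simulate an inebriometer elution assay
#'
#' Phenotypes a cohort of AIP individuals (or inbred founder lines)
#' under the additive [phenotype_model()].  For a population, each
#' individual's QTL dosages are read off its founder mosaic; for a
#' founder panel, each line's dosage is twice its homozygous allele.
#'
#' @param x an `aip_population` or a `founder_panel`.
#' @param model a [phenotype_model()].
#' @param panel the founder panel (required when `x` is a population and
#'   the model has QTLs).
#' @param sex `"F"` or `"M"`.
#' @param exposure `"E1"` or `"E2"`.
#' @param n_flies for a population: cohort size (must not exceed the
#'   population size; individuals are phenotyped without replacement).
#'   For a panel: flies per line.
#' @param seed integer seed.
#' @param replicate replicate label stored in the output.
#' @param date assay date label stored in the output.
#' @return an elution table: `data.frame` with columns `id`, `sex`,
#'   `exposure`, `replicate`, `date`, `minute`, plus attribute
#'   `individual_idx` (population row indices) for population input.
#' @export
simulate_elution <- function(x, model, sex = "F", exposure = "E1",
                             n_flies = NULL, seed = 1L, panel = NULL,
                             replicate = "R1", date = "D1") {
  if (!exposure %in% c("E1", "E2"))
    stop("unknown exposure label: ", exposure, " (expected E1 or E2)")
  if (!sex %in% c("F", "M")) stop("unknown sex label: ", sex)
  set.seed(derive_seed(seed, "elution"))

  if (inherits(x, "aip_population")) {
    npop <- length(x$individuals)
    if (is.null(n_flies)) n_flies <- npop
    if (n_flies < 1 || n_flies > npop)
      stop("n_flies must be between 1 and the population size")
    idx <- if (n_flies == npop) seq_len(npop) else sample.int(npop, n_flies)
    g <- if (length(model$qtl_sites)) {
      if (is.null(panel)) stop("panel required to score QTL dosages")
      dosage_matrix(x, panel, model$qtl_sites)[idx, , drop = FALSE]
    } else matrix(0, length(idx), 0)
    ids <- paste0("fly", idx)
  } else if (inherits(x, "founder_panel")) {
    if (is.null(n_flies)) n_flies <- 1L
    nl <- length(x$line_ids)
    idx <- rep(seq_len(nl), each = n_flies)
    g <- if (length(model$qtl_sites)) {
      2L * t(x$geno[model$qtl_sites, idx, drop = FALSE])
    } else matrix(0, length(idx), 0)
    ids <- x$line_ids[idx]
    idx <- seq_along(idx)
  } else stop("x must be an aip_population or a founder_panel")

  mu <- model$grand_mean +
    (if (ncol(g)) as.numeric(g %*% model$qtl_effects) else 0) +
    (if (sex == "M") model$sex_effect else 0) +
    (if (exposure == "E2") model$tolerance_shift else 0)
  y <- mu + rnorm(length(ids), 0, model$residual_sd)
  minute <- pmax(model$bin_width,
                 ceiling(y / model$bin_width) * model$bin_width)
  out <- data.frame(id = ids, sex = sex, exposure = exposure,
                    replicate = replicate, date = date, minute = minute,
                    stringsAsFactors = FALSE)
  attr(out, "individual_idx") <- idx
  out
}

#' Variance-component specification for a line-panel assay
#'
#' Parameters of the balanced random-effects design
#' `Y = mu + L + F + L:F + Rep(L:F) + eps` used to simulate per-fly
#' phenotype tables from an inbred line panel (lines crossed with sex or
#' with exposure).  Broad-sense heritability implied by a spec is
#' `H2 = (s2_L + s2_LxF) / (s2_L + s2_LxF + s2_eps)`.
#'
#' @param sigma2_L among-line variance (minutes^2).
#' @param sigma2_LxF line-by-factor interaction variance.
#' @param sigma2_Rep replicate (nested in line x factor) variance.
#' @param sigma2_eps within-replicate residual variance.
#' @param n_lines,n_levels,n_reps,n_flies_per_rep design counts.
#' @param grand_mean overall mean, minutes.
#' @param factor_effect fixed difference between the two factor levels,
#'   minutes (level 2 minus level 1).
#' @return an object of class `varcomp_spec`.
#' @export
varcomp_spec <- function(sigma2_L, sigma2_LxF, sigma2_Rep, sigma2_eps,
                         n_lines = 205, n_levels = 2, n_reps = 2,
                         n_flies_per_rep = 70, grand_mean = 7,
                         factor_effect = 0.7) {
  stopifnot(sigma2_L >= 0, sigma2_LxF >= 0, sigma2_Rep >= 0, sigma2_eps >= 0,
            n_lines >= 1, n_levels >= 1, n_reps >= 1, n_flies_per_rep >= 1)
  structure(as.list(environment()), class = "varcomp_spec")
}

#' Implied broad-sense heritability of a `varcomp_spec`
#' @param spec a [varcomp_spec()].
#' @return `H2 = sigma2_G / sigma2_P` with `sigma2_G = sigma2_L +
#'   sigma2_LxF` and `sigma2_P = sigma2_G + sigma2_eps`.
#' @export
implied_H2 <- function(spec) {
  g <- spec$sigma2_L + spec$sigma2_LxF
  g / (g + spec$sigma2_eps)
}

#' Simulate a balanced line-panel fly table
#'
#' Draws a fully balanced per-fly table from the random-effects model of
#' [varcomp_spec()]: Gaussian line, line-by-factor and nested replicate
#' effects, a fixed two-level factor effect, and Gaussian residuals.
#' This is the generating model that the ANOVA estimator in
#' [partition_variance()] is meant to invert.
#'
#' @param spec a [varcomp_spec()].
#' @param seed integer seed.
#' @param factor_name name of the crossed-factor column (`"sex"` or
#'   `"exposure"`).
#' @param factor_levels labels of the factor levels.
#' @return elution-style `data.frame` with columns `line`, the factor
#'   column, `replicate`, `date`, `minute`.
#' @export
simulate_dgrp_fly_data <- function(spec, seed = 1L, factor_name = "sex",
                                   factor_levels = if (factor_name == "sex")
                                     c("F", "M") else c("E1", "E2")) {
  stopifnot(inherits(spec, "varcomp_spec"),
            length(factor_levels) == spec$n_levels)
  set.seed(derive_seed(seed, "dgrp_fly"))
  l <- spec$n_lines; s <- spec$n_levels; r <- spec$n_reps
  f <- spec$n_flies_per_rep
  line_eff <- rnorm(l, 0, sqrt(spec$sigma2_L))
  int_eff <- matrix(rnorm(l * s, 0, sqrt(spec$sigma2_LxF)), l, s)
  rep_eff <- array(rnorm(l * s * r, 0, sqrt(spec$sigma2_Rep)), c(l, s, r))
  fac_eff <- (seq_len(s) - (s + 1) / 2) / max(s - 1, 1) * spec$factor_effect

  li <- rep(seq_len(l), each = s * r * f)
  si <- rep(rep(seq_len(s), each = r * f), times = l)
  ri <- rep(rep(seq_len(r), each = f), times = l * s)
  y <- spec$grand_mean + line_eff[li] + fac_eff[si] + int_eff[cbind(li, si)] +
    rep_eff[cbind(li, si, ri)] + rnorm(l * s * r * f, 0, sqrt(spec$sigma2_eps))
  out <- data.frame(line = paste0("line", li), V = factor_levels[si],
                    replicate = paste0("R", ri), date = paste0("D", ri),
                    minute = y, stringsAsFactors = FALSE)
  names(out)[2] <- factor_name
  out
}
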