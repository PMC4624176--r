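#' Express phenotypes as deviations from a control line
#'
#' Subtracts, from every observation, the mean of the control line
#' measured on the same assay date and sex — the standard correction
#' for day-to-day environmental drift when a panel is phenotyped over
#' many days with a common control run alongside.  Control rows are
#' removed from the output.
#'
#' @param raw elution table with columns `line`, `sex`, `date`, `minute`.
#' @param control_line_id identifier of the control line.
#' @return the adjusted table (control rows dropped).
#' @export
adjust_to_control <- function(raw, control_line_id) {
  stopifnot(all(c("line", "sex", "date", "minute") %in% names(raw)))
  is_ctrl <- raw$line == control_line_id
  strata <- interaction(raw$date, raw$sex, drop = TRUE)
  have <- tapply(is_ctrl, strata, any)
  if (!all(have)) {
    stop("no control observations in strata (date.sex): ",
         paste(names(have)[!have], collapse = ", "))
  }
  ctrl_mean <- tapply(raw$minute[is_ctrl], strata[is_ctrl], mean)
  out <- raw[!is_ctrl, , drop = FALSE]
  out$minute <- out$minute - as.numeric(ctrl_mean[as.character(strata[!is_ctrl])])
  rownames(out) <- NULL
  out
}

#' Partition phenotypic variance in a balanced line-panel design
#'
#' Method-of-moments (expected-mean-squares) estimation for the balanced
#' mixed model `Y = mu + L + F + L:F + Rep(L:F) + eps`, with line `L`
#' random, the crossed factor `F` (sex or exposure) fixed, and replicate
#' nested within the line-by-factor cell:
#' \deqn{\hat\sigma^2_\epsilon = MS_{within}}
#' \deqn{\hat\sigma^2_{Rep} = (MS_{Rep} - MS_{within}) / f}
#' \deqn{\hat\sigma^2_{L\times F} = (MS_{L\times F} - MS_{Rep}) / (rf)}
#' \deqn{\hat\sigma^2_L = (MS_L - MS_{L\times F}) / (srf)}
#' with `f` flies per replicate, `r` replicates per cell and `s` factor
#' levels.  Genotypic variance is `s2_G = s2_L + s2_LxF`, phenotypic
#' variance `s2_P = s2_G + s2_eps` (the replicate component is excluded
#' from `s2_P` by default; set `include_rep_in_P = TRUE` to add it), and
#' broad-sense heritability `H2 = s2_G / s2_P`.  Negative component
#' estimates are truncated to zero only after all four are solved, so
#' truncation of one component never propagates into another.
#'
#' @param data per-fly table with columns `line`, the crossed factor,
#'   `replicate`, `minute`.  Must be balanced; unbalanced input is
#'   rejected (subsample with [rebalance_elutions()] first).
#' @param crossed_factor name of the crossed-factor column, `"sex"` or
#'   `"exposure"`.
#' @param include_rep_in_P include the replicate component in `s2_P`.
#' @return an object of class `varcomp`: list with `components` (named
#'   vector `sigma2_L`, `sigma2_LxF`, `sigma2_Rep`, `sigma2_eps`),
#'   `sigma2_G`, `sigma2_P`, `H2`, `anova` (data.frame with df, SS, MS,
#'   F, p per term) and the design counts.
#' @export
partition_variance <- function(data, crossed_factor = c("sex", "exposure"),
                               include_rep_in_P = FALSE) {
  crossed_factor <- match.arg(crossed_factor)
  stopifnot(all(c("line", crossed_factor, "replicate", "minute") %in%
                  names(data)))
  line <- factor(data$line)
  fct <- factor(data[[crossed_factor]])
  rep_ <- factor(data$replicate)
  y <- data$minute
  l <- nlevels(line); s <- nlevels(fct)
  if (l < 2 || s < 2) stop("need >= 2 lines and >= 2 factor levels")

  cell <- interaction(line, fct, drop = FALSE)
  repu <- interaction(line, fct, rep_, drop = TRUE)
  n_per_rep <- table(repu)
  reps_per_cell <- table(cell) / n_per_rep[1]
  if (length(unique(as.integer(n_per_rep))) != 1L ||
      length(unique(as.integer(reps_per_cell))) != 1L) {
    stop("design is unbalanced (unequal replicates per cell or flies per ",
         "replicate); rebalance first, e.g. with rebalance_elutions()")
  }
  f <- as.integer(n_per_rep[1])
  r <- as.integer(reps_per_cell[1])
  if (r < 2) stop("need >= 2 replicates per cell")

  gm <- mean(y)
  m_line <- tapply(y, line, mean)
  m_fct <- tapply(y, fct, mean)
  m_cell <- tapply(y, cell, mean)
  m_rep <- tapply(y, repu, mean)

  SS_L <- s * r * f * sum((m_line - gm)^2)
  SS_F <- l * r * f * sum((m_fct - gm)^2)
  cl <- m_line[rep(seq_len(l), times = s)]
  cf <- m_fct[rep(seq_len(s), each = l)]
  SS_LxF <- r * f * sum((m_cell - cl - cf + gm)^2)
  ## cell mean of each replicate unit, keyed through the data (robust to
  ## "." inside line labels)
  rep_key <- tapply(as.character(cell), repu, function(z) z[1])
  rep_cell <- m_cell[rep_key]
  SS_Rep <- f * sum((m_rep - rep_cell)^2)
  SS_W <- sum((y - m_rep[repu])^2)

  df <- c(L = l - 1, F = s - 1, LxF = (l - 1) * (s - 1),
          Rep = l * s * (r - 1), within = l * s * r * (f - 1))
  SS <- c(SS_L, SS_F, SS_LxF, SS_Rep, SS_W)
  MS <- SS / df

  ## F ratios follow the EMS ladder: random terms tested against the
  ## next stratum down; the fixed factor against the interaction.
  Fv <- c(MS[["L"]] / MS[["LxF"]], MS[["F"]] / MS[["LxF"]],
          MS[["LxF"]] / MS[["Rep"]], MS[["Rep"]] / MS[["within"]], NA)
  Fden <- c(df[["LxF"]], df[["LxF"]], df[["Rep"]], df[["within"]], NA)
  p <- stats::pf(Fv, df, Fden, lower.tail = FALSE)

  s2_eps <- MS[["within"]]
  s2_rep <- (MS[["Rep"]] - MS[["within"]]) / f
  s2_lxf <- (MS[["LxF"]] - MS[["Rep"]]) / (r * f)
  s2_l <- (MS[["L"]] - MS[["LxF"]]) / (s * r * f)
  comp <- pmax(c(sigma2_L = s2_l, sigma2_LxF = s2_lxf,
                 sigma2_Rep = s2_rep, sigma2_eps = s2_eps), 0)
  s2_G <- comp[["sigma2_L"]] + comp[["sigma2_LxF"]]
  s2_P <- s2_G + comp[["sigma2_eps"]] +
    if (include_rep_in_P) comp[["sigma2_Rep"]] else 0
  H2 <- if (s2_P > 0) s2_G / s2_P else 0

  anova_tab <- data.frame(
    term = c("line", crossed_factor, paste0("line:", crossed_factor),
             "replicate(line:factor)", "within"),
    df = as.integer(df), SS = SS, MS = MS, F = Fv, p = p,
    row.names = NULL)
  structure(list(components = comp, sigma2_G = s2_G, sigma2_P = s2_P,
                 H2 = H2, anova = anova_tab, crossed_factor = crossed_factor,
                 design = c(n_lines = l, n_levels = s, n_reps = r,
                            n_flies_per_rep = f)),
            class = "varcomp")
}

#' @exportS3Method base::print
print.varcomp <- function(x, ...) {
  cat("Balanced ANOVA variance components (line x ", x$crossed_factor,
      "):\n", sep = "")
  print(round(x$components, 4))
  cat(sprintf("sigma2_G = %.4f  sigma2_P = %.4f  H2 = %.3f\n",
              x$sigma2_G, x$sigma2_P, x$H2))
  invisible(x)
}

#' Rebalance an elution table by seeded subsampling
#'
#' Drops replicates/flies so that every line x factor cell has the same
#' number of replicates and every replicate the same number of flies,
#' enabling the balanced estimator of [partition_variance()].
#'
#' @param data per-fly table with columns `line`, `sex` and/or
#'   `exposure`, `replicate`, `minute`.
#' @param crossed_factor the crossed-factor column name.
#' @param seed integer seed for the subsampling draw.
#' @return a balanced subset of `data`.
#' @export
rebalance_elutions <- function(data, crossed_factor = "sex", seed = 1L) {
  set.seed(derive_seed(seed, "rebalance"))
  cell <- interaction(data$line, data[[crossed_factor]], drop = TRUE)
  repu <- interaction(cell, data$replicate, drop = TRUE)
  keep_reps <- tapply(as.character(repu), cell, unique)
  r_min <- min(lengths(keep_reps))
  chosen <- unlist(lapply(keep_reps, function(z)
    if (length(z) > r_min) sample(z, r_min) else z))
  data <- data[as.character(repu) %in% chosen, , drop = FALSE]
  repu <- interaction(data$line, data[[crossed_factor]], data$replicate,
                      drop = TRUE)
  f_min <- min(table(repu))
  idx <- unlist(lapply(split(seq_len(nrow(data)), repu), function(i)
    if (length(i) > f_min) sample(i, f_min) else i))
  out <- data[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-line tolerance scores
#'
#' Tolerance of line *i* is the increase of its mean elution time from
#' the first to the second exposure, scaled by the population mean
#' increase: `T_i = (E2_i - E1_i) / (mean(E2) - mean(E1))`, with the
#' population means taken as unweighted averages of line means — so the
#' mean of `T` across lines is exactly 1.
#'
#' @param line_means_E1,line_means_E2 named numeric vectors of line mean
#'   elution times under the first and second exposure (same line sets).
#' @return `data.frame` with columns `line`, `E1`, `E2`, `T`.
#' @export
tolerance_scores <- function(line_means_E1, line_means_E2) {
  if (is.null(names(line_means_E1)) || is.null(names(line_means_E2)))
    stop("line means must be named by line")
  if (!setequal(names(line_means_E1), names(line_means_E2)))
    stop("E1 and E2 must cover the same lines")
  e2 <- line_means_E2[names(line_means_E1)]
  denom <- mean(e2) - mean(line_means_E1)
  if (denom == 0)
    stop("tolerance undefined: population mean E2 equals mean E1")
  data.frame(line = names(line_means_E1),
             E1 = as.numeric(line_means_E1), E2 = as.numeric(e2),
             T = as.numeric((e2 - line_means_E1) / denom),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Correlations of line means across sex/exposure conditions
#'
#' Product-moment (Pearson) correlations of line means between every
#' pair of conditions — the line-mean analogue of the genetic
#' correlation for inbred panels.
#'
#' @param line_means `data.frame` with a `line` column and one numeric
#'   column per condition, or a named list of equally-named numeric
#'   vectors.
#' @return correlation matrix; conditions with zero variance give `NA`
#'   entries, with a warning naming them.
#' @export
cross_correlations <- function(line_means) {
  if (is.data.frame(line_means)) {
    m <- as.matrix(line_means[setdiff(names(line_means), "line")])
  } else {
    lines <- names(line_means[[1]])
    m <- vapply(line_means, function(v) as.numeric(v[lines]),
                numeric(length(lines)))
  }
  if (nrow(m) < 3) stop("need >= 3 lines")
  sds <- apply(m, 2, sd)
  if (any(sds == 0))
    warning("zero variance in condition(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "),
            "; correlations set to NA")
  suppressWarnings(cor(m))
}

#' Pooled standard error of a mutant-minus-control difference
#'
#' @param se_mutant,se_control standard errors of the two means (>= 0).
#' @return `sqrt(se_mutant^2 + se_control^2)`.
#' @export
combined_sem <- function(se_mutant, se_control) {
  if (any(se_mutant < 0) || any(se_control < 0))
    stop("standard errors must be non-negative")
  sqrt(se_mutant^2 + se_control^2)
}
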