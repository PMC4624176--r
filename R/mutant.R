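#' Factorial ANOVA for mutant-vs-control alcohol sensitivity assays
#'
#' Fits the fixed-effect factorial model
#' `Y = mu + G + S + E + G:S + G:E + S:E + G:S:E + Rep(G:S:E) + eps`
#' (genotype, sex, exposure) with replicate vials nested within the
#' genotype-by-sex-by-exposure cell.  All factorial terms are tested
#' against the among-replicate mean square (the whole-plot error: flies
#' within a vial are not independent evidence about vial-level factors);
#' the replicate term itself is tested against the within-replicate
#' residual.  Also reports, per sex and exposure, the mutant minus
#' control mean difference with its pooled standard error from
#' [combined_sem()].
#'
#' @param data per-fly table with columns `genotype` (two levels, e.g.
#'   mutant/control), `sex`, `exposure`, `replicate`, `minute`.
#' @return list with `anova` (data.frame: term, df, SS, MS, F, p) and
#'   `effects` (data.frame: sex, exposure, mutant_mean, control_mean,
#'   difference, sem).
#' @export
mutant_anova <- function(data) {
  need <- c("genotype", "sex", "exposure", "replicate", "minute")
  stopifnot(all(need %in% names(data)))
  for (v in c("genotype", "sex", "exposure")) {
    if (nlevels(factor(data[[v]])) < 2)
      stop("factor '", v, "' needs 2 levels")
  }
  cell <- interaction(data$genotype, data$sex, data$exposure, drop = FALSE)
  if (any(table(cell) == 0))
    stop("missing genotype x sex x exposure cell(s): ",
         paste(names(table(cell))[table(cell) == 0], collapse = ", "))

  d <- data.frame(y = data$minute, G = factor(data$genotype),
                  S = factor(data$sex), E = factor(data$exposure),
                  repu = interaction(data$genotype, data$sex, data$exposure,
                                     data$replicate, drop = TRUE))
  fit <- aov(y ~ G * S * E + Error(repu), data = d)
  st <- summary(fit)
  between <- as.data.frame(st[["Error: repu"]][[1]])
  within <- as.data.frame(st[["Error: Within"]][[1]])

  ms_rep <- between["Residuals", "Mean Sq"]
  df_rep <- between["Residuals", "Df"]
  ms_w <- within["Residuals", "Mean Sq"]
  df_w <- within["Residuals", "Df"]

  terms <- trimws(rownames(between))
  terms <- vapply(strsplit(terms, ":"), function(z)
    paste(c(G = "genotype", S = "sex", E = "exposure",
            Residuals = "Residuals")[z], collapse = ":"), "")
  keep <- terms != "Residuals"
  ## mean squares at rounding-noise level (e.g. a constant response)
  ## are treated as exact zeros: F = 0, p = 1 rather than 0/0 artefacts
  tol <- 1e-10 * mean(d$y^2)
  safe_F <- function(ms_num, ms_den) {
    out <- if (ms_den <= tol) rep(Inf, length(ms_num)) else ms_num / ms_den
    out[ms_num <= tol] <- 0
    out
  }
  tab <- data.frame(term = terms[keep],
                    df = between[keep, "Df"],
                    SS = between[keep, "Sum Sq"],
                    MS = between[keep, "Mean Sq"],
                    F = safe_F(between[keep, "Mean Sq"], ms_rep),
                    stringsAsFactors = FALSE)
  tab$p <- stats::pf(tab$F, tab$df, df_rep, lower.tail = FALSE)
  rep_row <- data.frame(term = "replicate(G:S:E)", df = df_rep,
                        SS = between["Residuals", "Sum Sq"], MS = ms_rep,
                        F = safe_F(ms_rep, ms_w),
                        p = stats::pf(safe_F(ms_rep, ms_w), df_rep, df_w,
                                      lower.tail = FALSE))
  res_row <- data.frame(term = "within", df = df_w,
                        SS = within["Residuals", "Sum Sq"], MS = ms_w,
                        F = NA_real_, p = NA_real_)
  anova_tab <- rbind(tab, rep_row, res_row)
  rownames(anova_tab) <- NULL

  glv <- levels(d$G)
  mutant_level <- if ("mutant" %in% glv) "mutant" else glv[1L]
  control_level <- setdiff(glv, mutant_level)[1L]
  eff <- do.call(rbind, lapply(levels(d$S), function(sx) {
    do.call(rbind, lapply(levels(d$E), function(ex) {
      ym <- d$y[d$G == mutant_level & d$S == sx & d$E == ex]
      yc <- d$y[d$G == control_level & d$S == sx & d$E == ex]
      sem <- combined_sem(sd(ym) / sqrt(length(ym)),
                          sd(yc) / sqrt(length(yc)))
      data.frame(sex = sx, exposure = ex, mutant_mean = mean(ym),
                 control_mean = mean(yc),
                 difference = mean(ym) - mean(yc), sem = sem,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(eff) <- NULL
  list(anova = anova_tab, effects = eff,
       mutant_level = mutant_level, control_level = control_level)
}
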