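#' Normalize qPCR cycle thresholds to the reference gene
#'
#' Technical replicates are averaged first (plate-level convention for
#' SYBR-green assays); then, within each (gene, sex, pool, biological
#' replicate) stratum, `deltaCt = mean Ct(gene) - mean Ct(reference)`.
#' Lower deltaCt means higher expression relative to the reference.
#' Any constant plate shift common to a stratum cancels exactly.
#'
#' @param table Ct table `data.frame` with columns `gene`, `sex`,
#'   `pool` (`"sensitive"`/`"resistant"`), `bio_rep`, `tech_rep`, `ct`.
#' @param reference reference gene name (default `"Gpdh"`, the classic
#'   invariant metabolic normalizer).
#' @return `data.frame` with `gene`, `sex`, `pool`, `bio_rep`,
#'   `delta_ct`.
#' @export
delta_ct <- function(table, reference = "Gpdh") {
  need <- c("gene", "sex", "pool", "bio_rep", "tech_rep", "ct")
  stopifnot(all(need %in% names(table)), all(table$ct > 0))
  agg <- aggregate(ct ~ gene + sex + pool + bio_rep, data = table, FUN = mean)
  ref <- agg[agg$gene == reference, ]
  if (nrow(ref) == 0L) stop("reference gene '", reference, "' absent")
  key <- function(d) paste(d$sex, d$pool, d$bio_rep, sep = "\r")
  ref_ct <- setNames(ref$ct, key(ref))
  tgt <- agg[agg$gene != reference, ]
  miss <- unique(key(tgt)[!key(tgt) %in% names(ref_ct)])
  if (length(miss))
    stop("reference gene missing in strata (sex/pool/bio_rep): ",
         paste(gsub("\r", "/", miss), collapse = ", "))
  tgt$delta_ct <- tgt$ct - as.numeric(ref_ct[key(tgt)])
  out <- tgt[c("gene", "sex", "pool", "bio_rep", "delta_ct")]
  rownames(out) <- NULL
  out
}

#' Sensitive-vs-resistant pool t-test on deltaCt values
#'
#' Equal-variance two-sample Student's t-test of a gene's deltaCt
#' between the sensitive and resistant pools, with biological
#' replicates as the experimental unit.  `direction` is the sign of the
#' expression difference in the resistant pool relative to the
#' sensitive pool (+1 = higher expression in resistant, i.e. lower
#' deltaCt there).
#'
#' @param delta_cts output of [delta_ct()].
#' @param gene,sex stratum to test.
#' @param var_equal use the pooled-variance Student's test (default);
#'   `FALSE` gives Welch.
#' @return list with `t`, `df`, `p`, `direction`,
#'   `mean_sensitive`, `mean_resistant` (deltaCt scale).
#' @export
pool_ttest <- function(delta_cts, gene, sex, var_equal = TRUE) {
  d <- delta_cts[delta_cts$gene == gene & delta_cts$sex == sex, ]
  xs <- d$delta_ct[d$pool == "sensitive"]
  xr <- d$delta_ct[d$pool == "resistant"]
  if (length(xs) < 2 || length(xr) < 2)
    stop("need >= 2 biological replicates per pool for ", gene, "/", sex)
  if (sd(xs) == 0 && sd(xr) == 0 && mean(xs) == mean(xr)) {
    tt <- list(statistic = c(t = 0),
               parameter = c(df = length(xs) + length(xr) - 2),
               p.value = 1)
  } else {
    tt <- t.test(xs, xr, var.equal = var_equal)
  }
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value,
       direction = sign(mean(xs) - mean(xr)),  # resistant lower dCt -> +1
       mean_sensitive = mean(xs), mean_resistant = mean(xr))
}

#' Test all genes of a deltaCt table
#'
#' Convenience wrapper running [pool_ttest()] over every gene x sex
#' stratum present.
#'
#' @inheritParams pool_ttest
#' @return `data.frame` with `gene`, `sex`, `t`, `df`, `p`, `direction`.
#' @export
pool_ttest_all <- function(delta_cts, var_equal = TRUE) {
  strata <- unique(delta_cts[c("gene", "sex")])
  out <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    r <- pool_ttest(delta_cts, strata$gene[i], strata$sex[i], var_equal)
    data.frame(gene = strata$gene[i], sex = strata$sex[i], t = r$t,
               df = r$df, p = r$p, direction = r$direction,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Are candidates enriched for altered expression?
#'
#' Classifies each tested transcript as "altered" when its pool t-test
#' p-value falls below `alpha`, tabulates altered/unaltered counts for
#' the candidate and the random control gene sets, and applies a
#' one-sided Fisher's exact test of the directional hypothesis that the
#' candidate proportion is greater.
#'
#' @param candidate_results,random_results data frames with a `p`
#'   column (e.g. from [pool_ttest_all()]), one row per transcript
#'   (gene x sex), or bare numeric p-value vectors.
#' @param alpha per-transcript significance level (default 0.05).
#' @return list with `table` (2x2 matrix, rows candidate/random,
#'   columns altered/not), `p` (one-sided Fisher), `odds_ratio`.
#' @export
altered_proportion_test <- function(candidate_results, random_results,
                                    alpha = 0.05) {
  getp <- function(x) if (is.data.frame(x)) x$p else as.numeric(x)
  pc <- getp(candidate_results)
  pr <- getp(random_results)
  if (length(pc) == 0 || length(pr) == 0) stop("both result sets must be non-empty")
  tab <- matrix(c(sum(pc < alpha), sum(pc >= alpha),
                  sum(pr < alpha), sum(pr >= alpha)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("candidate", "random"),
                                c("altered", "not_altered")))
  ft <- fisher.test(tab, alternative = "greater")
  list(table = tab, p = ft$p.value, odds_ratio = unname(ft$estimate))
}
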