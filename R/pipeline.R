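#' Run a reproducible simulate-to-scan pipeline
#'
#' Binds the simulator and the analysis stages into a single seeded,
#' manifest-logged run.  The configuration is a named list (or a path
#' to a YAML file with the same structure) with a `stages` vector and
#' one block per stage; unknown top-level keys are rejected so typos
#' fail loudly rather than silently using defaults.
#'
#' Supported stages:
#' \describe{
#'   \item{`simulate`}{builds a founder panel, a diallel base
#'     population, advances it by random mating, phenotypes an assay
#'     cohort, truncation-selects extremes and simulates pooled
#'     sequencing.  Writes `panel.vcf`, `elutions.tsv`,
#'     `pool_counts.tsv`.}
#'   \item{`xqtl`}{runs the pooled allele-frequency Z scan on the
#'     simulated (or externally supplied `counts`) table.  Writes
#'     `xqtl_results.tsv`.}
#'   \item{`quantgen`}{partitions variance of a balanced line-panel
#'     simulation from a `varcomp` block.  Writes
#'     `variance_components.json`.}
#' }
#'
#' @param config named list or YAML file path.
#' @param out_dir output directory (created if absent); defaults to
#'   `config$out`.
#' @return list of in-memory stage results, invisibly; files and a
#'   `manifest.json` (package version, seed, per-file md5 digests) are
#'   written to `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  known <- c("seed", "out", "stages", "simulate", "xqtl", "quantgen")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$stages) || !length(config$stages))
    stop("config$stages must list at least one stage")
  bad <- setdiff(config$stages, c("simulate", "xqtl", "quantgen"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  if (is.null(out_dir)) out_dir <- config$out
  if (is.null(out_dir)) stop("no output directory (config$out or out_dir)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  results <- list()
  files <- character(0)
  defaults <- function(block, defs) {
    if (is.null(block)) block <- list()
    for (k in names(defs)) if (is.null(block[[k]])) block[[k]] <- defs[[k]]
    block
  }

  if ("simulate" %in% config$stages) {
    sc <- defaults(config$simulate, list(
      n_lines = 6, n_sites_per_chrom = 40, private_fraction = 0.2,
      base_size = 300, generations = 25, cohort_size = 2000,
      n_qtl = 1, qtl_effect = 2, grand_mean = 7, residual_sd = 2,
      fraction = 0.1, mean_depth = 50, sex = "F", exposure = "E1"))
    panel <- make_founder_panel(sc$n_lines, sc$n_sites_per_chrom,
                                sc$private_fraction,
                                seed = derive_seed(seed, "pipe_panel"))
    pop <- diallel_base_population(panel, sc$base_size,
                                   seed = derive_seed(seed, "pipe_base"))
    pop <- advance_generations(pop, sc$generations, panel,
                               seed = derive_seed(seed, "pipe_adv"))
    cohort <- sample_offspring(pop, sc$cohort_size, panel,
                               seed = derive_seed(seed, "pipe_cohort"))
    seg <- which(segregating_sites(panel))
    qtl <- seg[round(seq(1, length(seg),
                         length.out = sc$n_qtl + 2))][-c(1, sc$n_qtl + 2)]
    model <- phenotype_model(qtl_sites = qtl,
                             qtl_effects = rep(sc$qtl_effect, length(qtl)),
                             grand_mean = sc$grand_mean,
                             residual_sd = sc$residual_sd)
    elu <- simulate_elution(cohort, model, sex = sc$sex,
                            exposure = sc$exposure, panel = panel,
                            seed = derive_seed(seed, "pipe_elu"))
    sel <- select_extremes(elu, sc$fraction,
                           seed = derive_seed(seed, "pipe_sel"))
    counts <- simulate_pool_seq(cohort, sel, panel, sc$mean_depth,
                                seed = derive_seed(seed, "pipe_pool"))
    files <- c(files,
               write_panel_vcf(panel, file.path(out_dir, "panel.vcf")),
               write_elutions(elu, file.path(out_dir, "elutions.tsv")),
               write_pool_counts(counts, file.path(out_dir, "pool_counts.tsv")))
    results$simulate <- list(panel = panel, cohort = cohort, model = model,
                             elutions = elu, selected = sel, counts = counts,
                             pool_size = length(sel$sensitive))
  }

  if ("xqtl" %in% config$stages) {
    xc <- defaults(config$xqtl, list(alpha = 0.05, nominal = 1e-5))
    if (!is.null(xc$counts)) {
      counts <- read_pool_counts(xc$counts)
      if (is.null(xc$n)) stop("xqtl stage with external counts needs 'n'")
      n <- xc$n
    } else if (!is.null(results$simulate)) {
      counts <- results$simulate$counts
      n <- 2 * results$simulate$pool_size
    } else {
      stop("xqtl stage needs either a 'counts' path or an upstream ",
           "simulate stage")
    }
    scan <- run_xqtl(counts, n = n, alpha = xc$alpha, nominal = xc$nominal)
    files <- c(files,
               write_tsv(scan, file.path(out_dir, "xqtl_results.tsv")))
    results$xqtl <- scan
  }

  if ("quantgen" %in% config$stages) {
    qc <- defaults(config$quantgen, list(
      sigma2_L = 3, sigma2_LxF = 0.5, sigma2_Rep = 0.5, sigma2_eps = 4.833,
      n_lines = 50, n_reps = 2, n_flies_per_rep = 20,
      crossed_factor = "sex"))
    spec <- varcomp_spec(qc$sigma2_L, qc$sigma2_LxF, qc$sigma2_Rep,
                         qc$sigma2_eps, n_lines = qc$n_lines,
                         n_reps = qc$n_reps,
                         n_flies_per_rep = qc$n_flies_per_rep)
    tab <- simulate_dgrp_fly_data(spec, seed = derive_seed(seed, "pipe_vc"),
                                  factor_name = qc$crossed_factor)
    vc <- partition_variance(tab, crossed_factor = qc$crossed_factor)
    f <- file.path(out_dir, "variance_components.json")
    jsonlite::write_json(list(components = as.list(vc$components),
                              sigma2_G = vc$sigma2_G, sigma2_P = vc$sigma2_P,
                              H2 = vc$H2),
                         f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
    results$quantgen <- vc
  }

  manifest <- list(
    package = "aipqtl",
    version = as.character(utils::packageVersion("aipqtl")),
    seed = seed,
    stages = config$stages,
    outputs = lapply(setNames(nm = basename(files)), function(b)
      unname(tools::md5sum(file.path(out_dir, b)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
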