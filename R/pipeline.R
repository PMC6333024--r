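#' Default pipeline configuration
#'
#' A complete run specification: simulation scale, QC thresholds, REML
#' settings, cross-validation scheme, density-experiment panel sizes,
#' cycle lengths, target accuracies, and the mandatory master seed from
#' which every stage's seed is derived deterministically.
#'
#' @param seed Master seed.
#' @param n_markers Simulated panel width.
#' @param traits Character vector naming which of the default traits to
#'   analyse (NULL = all 18).
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L, n_markers = 2000L, traits = NULL) {
  list(seed = as.integer(seed),
       simulate = list(n_markers = as.integer(n_markers),
                       missing_rate = 0.02, invariant_fraction = 0.02,
                       n_years = 3L, plants_per_plot = 1L, traits = traits),
       qc = list(cr_threshold = 0.90, maf_threshold = 0.05),
       reml = list(max_iter = 500L, tol = 1e-6),
       cv = list(n_folds = 13L, strategy = "random"),
       density = list(sizes = NULL),   # NULL = skip the density experiment
       report = list(L_f = 24, L_GS = c(12, 24),
                     targets = c(0.5, 0.6, 0.7, 0.8, 0.9)))
}

# deterministic per-stage seeds below 2^31
stage_seed <- function(master, stage)
  (as.integer(master) * 97L + match(stage, c("pedigree", "genotypes",
                                             "phenotypes", "folds",
                                             "density", "gibbs"))) %% 2147483647L

#' Run the full analysis pipeline
#'
#' simulate -> QC -> phenotypic REML/BLUP -> genomic heritability ->
#' cross-validated G-BLUP -> derived design statistics. All stage seeds
#' are deterministic functions of the master seed; outputs (tables, QC
#' report, manifest) are written under \code{out_dir} when given.
#'
#' @param config Configuration list as from \code{\link{default_config}},
#'   or the path of a YAML file holding one.
#' @param out_dir Output directory (created); NULL = return results only.
#' @return List with \code{panel}, \code{qc_report}, \code{pheno}
#'   (per-trait REML fits), \code{table} (the combined per-trait
#'   \code{derived_stats}), \code{density} (if run) and \code{truth}.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed)) stop("config$seed is mandatory", call. = FALSE)
  cfg <- utils::modifyList(default_config(config$seed), config)
  t0 <- Sys.time()
  log_stage <- function(...) message(sprintf("[%5.1fs] ",
    as.numeric(difftime(Sys.time(), t0, units = "secs"))), ...)

  log_stage("simulating population")
  ped <- simulate_pedigree(seed = stage_seed(cfg$seed, "pedigree"))
  panel <- simulate_genotypes(ped, n_markers = cfg$simulate$n_markers,
                              missing_rate = cfg$simulate$missing_rate,
                              invariant_fraction = cfg$simulate$invariant_fraction,
                              seed = stage_seed(cfg$seed, "genotypes"))
  specs <- default_trait_specs(cfg$simulate$n_years)
  if (!is.null(cfg$simulate$traits)) specs <- specs[cfg$simulate$traits]
  specs <- lapply(specs, function(s) {
    s$n_qtl <- min(s$n_qtl, cfg$simulate$n_markers); s })
  sim <- simulate_phenotypes(panel, ped, specs,
                             n_years = cfg$simulate$n_years,
                             plants_per_plot = cfg$simulate$plants_per_plot,
                             seed = stage_seed(cfg$seed, "phenotypes"))

  log_stage("SNP quality control")
  qc <- run_qc(panel, cfg$qc$cr_threshold, cfg$qc$maf_threshold)
  W <- impute_missing(qc$panel$genotypes)
  G <- grm(W)

  ind <- ped$individuals
  folds <- make_folds(ind$id, cfg$cv$n_folds, cfg$cv$strategy,
                      families = stats::setNames(ind$family, ind$id),
                      seed = stage_seed(cfg$seed, "folds"))

  pheno_fits <- list(); stats_list <- list(); density <- list()
  for (tr in names(specs)) {
    log_stage("trait ", tr)
    des <- build_design(sim$phenotypes, tr)
    vc <- reml_fit(des, max_iter = cfg$reml$max_iter, tol = cfg$reml$tol)
    fit <- blup_solve(des, vc)
    acc <- phenotypic_accuracy(des, vc)
    yc <- correct_phenotypes(des, fit)[rownames(W)]

    gh <- kernel_reml(yc, G)
    vy <- stats::var(yc)
    cv <- cv_run(W, yc, folds,
                 sigma_g2 = gh$h2 * vy, sigma_e2 = (1 - gh$h2) * vy)

    pheno_fits[[tr]] <- list(components = vc, accuracy = acc,
                             corrected = yc, genomic = gh, cv = cv)
    stats_list[[tr]] <- list(trait = tr, h2_phen = acc$h2_phen,
                             r_yy = acc$r_yy, ha2 = gh$h2,
                             r_gy = cv$r_gy, sd_r = cv$sd_r,
                             b = cv$b, sd_b = cv$sd_b)
    if (!is.null(cfg$density$sizes))
      density[[tr]] <- density_experiment(qc$panel, yc, cfg$density$sizes,
                                          h2 = gh$h2, n_folds = cfg$cv$n_folds,
                                          seed = stage_seed(cfg$seed, "density"))
  }

  table <- build_tables(stats_list, n = nrow(ind),
                        targets = cfg$report$targets,
                        L_f = cfg$report$L_f, L_GS = cfg$report$L_GS)

  res <- list(panel = qc$panel, qc_report = qc$report, pheno = pheno_fits,
              table = table, density = if (length(density)) density else NULL,
              truth = sim$truth, config = cfg)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(table, file.path(out_dir, "derived_stats.csv"),
                     row.names = FALSE)
    utils::write.csv(format_derived_stats(table),
                     file.path(out_dir, "derived_stats_formatted.csv"),
                     row.names = FALSE)
    write_qc_report(qc$report, file.path(out_dir, "qc_report.json"))
    for (tr in names(density))
      utils::write.csv(density[[tr]],
                       file.path(out_dir, paste0("density_", tr, ".csv")),
                       row.names = FALSE)
    manifest <- list(seed = cfg$seed,
                     n_individuals = nrow(ind),
                     n_markers_input = cfg$simulate$n_markers,
                     n_markers_retained = qc$report$n_retained,
                     traits = names(specs),
                     timestamp = format(Sys.time(), tz = "UTC"),
                     r_version = as.character(getRversion()))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
    log_stage("outputs written to ", out_dir)
  }
  invisible(res)
}
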