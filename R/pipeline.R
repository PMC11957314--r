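.defaultPipelineConfig <- function() {
  list(seed = 42L,
       synthetic = list(write_cells = TRUE),
       profiling = list(method = "robust_mad", sd_max = 2000,
                        corr_max = 0.9),
       clustering = list(linkage = "average", metric = "pearson",
                         min_induction = 20, clip = 8, heatmap = TRUE),
       models = list(targets = c("viability_pct", "cell_count"),
                     n_trees = 200L, seed = 42L, split_fraction = 0.8,
                     low_variance_floor = 200, per_compound = TRUE),
       smogn = list(enabled = TRUE, rel_coef = 5, rel_thres = 0.8,
                    k_neighbors = 5L, noise_sd_frac = 0.02),
       dose = list(alpha = 0.05, decoupling_floor = 0.2, fdr = FALSE))
}

.mergeConfig <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]))
      defaults[[nm]] <- .mergeConfig(defaults[[nm]], user[[nm]])
    else defaults[[nm]] <- user[[nm]]
  }
  defaults
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes simulate -> profile -> cluster -> model -> augment -> dose on
#' a synthetic experiment described by the configuration, writing every
#' artifact as CSV (plus optional heatmap PNGs) under \code{outdir},
#' together with a run log recording the seed, package version and
#' effective parameters. The whole run is a pure function of
#' (config, seed): rerunning with the same configuration reproduces the
#' output tree byte for byte.
#'
#' Configuration blocks (YAML file or nested list; all optional):
#' \code{seed}; \code{synthetic} (arguments of [syntheticConfig()], plus
#' \code{write_cells}); \code{profiling} (\code{method}, \code{sd_max},
#' \code{corr_max}); \code{clustering} (\code{linkage}, \code{metric},
#' \code{min_induction}, \code{clip}, \code{heatmap}); \code{models}
#' (\code{targets}, \code{n_trees}, \code{seed}, \code{split_fraction},
#' \code{low_variance_floor}, \code{per_compound}); \code{smogn}
#' (\code{enabled} + [smognConfig()] arguments); \code{dose}
#' (\code{alpha}, \code{decoupling_floor}, \code{fdr}).
#'
#' @param config path to a YAML file, or a nested list; unknown keys are
#'   an error.
#' @param outdir output directory.
#' @return invisibly, a list with the main in-memory artifacts
#'   (profiles, treatment profiles, reports, summaries, potencies).
#' @export
runPipeline <- function(config = list(), outdir) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- .defaultPipelineConfig()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("invalid config key(s): ", paste(unknown, collapse = ", "))
  cfg <- .mergeConfig(defaults, config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  syn_args <- cfg$synthetic
  write_cells <- isTRUE(syn_args$write_cells)
  syn_args$write_cells <- NULL
  syn_args$seed <- if (is.null(syn_args$seed)) cfg$seed else syn_args$seed
  scfg <- do.call(syntheticConfig, syn_args)

  .msg("simulate: ", scfg$n_compounds, " compounds x ",
       length(scfg$concentrations), " concentrations on ", scfg$n_plates,
       " plates")
  exp <- generateExperiment(scfg)
  if (write_cells) writeExperiment(exp, outdir)
  else {
    fwrite(exp$metadata, file.path(outdir, "metadata.csv"))
    fwrite(exp$truth$compounds, file.path(outdir, "ground_truth.csv"))
  }

  .msg("profile: aggregating, normalizing (", cfg$profiling$method,
       ") and filtering")
  wells <- aggregateWells(exp$cells)
  wells <- normalizeProfiles(wells, method = cfg$profiling$method)
  filtered <- filterFeatures(wells, sd_max = cfg$profiling$sd_max,
                             corr_max = cfg$profiling$corr_max)
  viab <- normalizeViability(exp$viability)
  filtered <- attachViability(filtered, viab)
  writeProfiles(filtered, file.path(outdir, "profiles.csv"))
  fwrite(as.data.table(dropLedger(filtered)),
         file.path(outdir, "drop_ledger.csv"))

  trt <- aggregateTreatments(wells)
  writeProfiles(trt, file.path(outdir, "treatment_profiles.csv"))

  .msg("cluster: induction filter + ", cfg$clustering$linkage,
       " linkage on ", cfg$clustering$metric)
  flt <- filterByInduction(trt[, !isVehicle(trt)],
                           min_induction = cfg$clustering$min_induction)
  fwrite(data.table(profile_id = names(flt$induction),
                    induction_pct = flt$induction,
                    kept = flt$induction > cfg$clustering$min_induction),
         file.path(outdir, "induction.csv"))
  clus <- NULL
  if (ncol(flt$kept) >= 2L) {
    clus <- clusterProfiles(flt$kept, linkage = cfg$clustering$linkage,
                            metric = cfg$clustering$metric)
    exportClustergram(clus, t(profileMatrix(flt$kept)),
                      file.path(outdir, "clustergram"),
                      clip = cfg$clustering$clip,
                      png = isTRUE(cfg$clustering$heatmap))
  }

  .msg("model: random forests (", cfg$models$n_trees, " trees)")
  spec <- rfModelSpec(n_trees = cfg$models$n_trees, seed = cfg$models$seed,
                      split_fraction = cfg$models$split_fraction,
                      low_variance_floor = cfg$models$low_variance_floor)
  reports <- list()
  if (isTRUE(cfg$models$per_compound))
    reports <- perCompoundModels(filtered, targets = cfg$models$targets,
                                 spec = spec)
  for (tg in cfg$models$targets)
    reports[[paste0("GLOBAL.", tg)]] <- globalModel(filtered, tg, spec)

  smogn_report <- NULL
  if (isTRUE(cfg$smogn$enabled)) {
    .msg("augment: SMOGN on the training partition")
    smg <- smognConfig(rel_coef = cfg$smogn$rel_coef,
                       rel_thres = cfg$smogn$rel_thres,
                       k_neighbors = cfg$smogn$k_neighbors,
                       noise_sd_frac = cfg$smogn$noise_sd_frac,
                       seed = cfg$seed)
    smogn_report <- tryCatch(
      globalModel(filtered, "viability_pct", spec, smogn = smg),
      error = function(e) {
        .msg("SMOGN augmentation skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(smogn_report))
      reports[["GLOBAL_SMOGN.viability_pct"]] <- smogn_report
    # augmented training table, synthetic rows flagged
    sub <- filtered[, !isVehicle(filtered)]
    mf <- .modelFrame(sub, "viability_pct")
    sp <- splitTrainTest(nrow(mf$x), spec)
    aug <- tryCatch(smognAugment(mf$x[sp$train, , drop = FALSE],
                                 mf$y[sp$train], smg),
                    error = function(e) NULL)
    if (!is.null(aug))
      fwrite(cbind(data.table(viability_pct = aug$y,
                              synthetic = aug$synthetic, mode = aug$mode),
                   as.data.table(aug$X)),
             file.path(outdir, "augmented_profiles.csv"))
  }
  fwrite(as.data.table(reportTable(reports)),
         file.path(outdir, "model_reports.csv"))
  cand <- reports[vapply(reports, function(r)
    r@scope != "GLOBAL" && !r@augmented && r@target == "viability_pct",
    logical(1))]
  imp <- if (length(cand) >= 2L) importanceMatrix(cand)
  if (!is.null(imp)) {
    fwrite(cbind(data.table(model = rownames(imp$matrix)),
                 as.data.table(imp$matrix)),
           file.path(outdir, "importances.csv"))
    if (!is.null(imp$row_cluster) && isTRUE(cfg$clustering$heatmap))
      exportClustergram(imp$row_cluster, imp$matrix,
                        file.path(outdir, "importance_heatmap"),
                        clip = NULL, png = TRUE)
  }

  .msg("dose: screens and potency fits")
  summaries <- conditionTests(filtered, viability = viab,
                              fdr = isTRUE(cfg$dose$fdr))
  fwrite(as.data.table(summaries),
         file.path(outdir, "condition_summaries.csv"))
  potency <- rbind(fitPotency(summaries, "viability"),
                   fitPotency(summaries, "count"))
  fwrite(as.data.table(potency), file.path(outdir, "potency.csv"))
  dec <- decouplingReport(summaries, alpha = cfg$dose$alpha,
                          count_drop_floor = cfg$dose$decoupling_floor)
  fwrite(as.data.table(dec), file.path(outdir, "decoupling.csv"))

  log <- list(package = "phenotox",
              version = as.character(utils::packageVersion("phenotox")),
              seed = cfg$seed, config = cfg)
  yaml::write_yaml(log, file.path(outdir, "run_log.yaml"))
  invisible(list(profiles = filtered, treatments = trt, cluster = clus,
                 reports = reports, summaries = summaries,
                 potency = potency, decoupling = dec,
                 truth = exp$truth))
}
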