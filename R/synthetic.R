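#' Configuration for the synthetic screen generator
#'
#' Describes one synthetic Cell Painting experiment: a compound panel
#' profiled at a log-spaced concentration series with technical replicate
#' wells on replicate plates, plus vehicle-control wells on every plate.
#' The defaults mirror the screening design the analysis assumes: 30
#' compounds in 5 mechanism groups, 8 concentrations from 10 nM to 30 uM,
#' 4 wells per condition on each of 3 plates (96 treated wells per
#' compound) and 35 vehicle wells per plate.
#'
#' Noise structure (documented in the methods vignette): cell-level
#' feature noise is multivariate normal with block-diagonal correlation
#' (blocks emulate channel/compartment feature families); per-well counts
#' are Poisson around the expected count times a per-well lognormal
#' biological factor; each plate adds a small additive feature offset so
#' per-plate vehicle normalization is load-bearing; luminescence carries
#' independent lognormal and multiplicative noise.
#'
#' @param n_compounds,n_mechanisms panel size and number of shared
#'   mechanism-of-action groups.
#' @param concentrations molar concentration series (default 8 points,
#'   log-spaced 1e-8 to 3e-5).
#' @param wells_per_condition_per_plate,n_plates technical replicates per
#'   plate and plate replicates.
#' @param vehicle_wells_per_plate vehicle-control wells per plate
#'   (default 35, within the 30-40 screening convention).
#' @param n_features,baseline_cells_per_well feature count and expected
#'   cells per healthy well.
#' @param seed integer seed; all outputs are pure functions of
#'   (config, seed).
#' @param effect_scale feature shift at full effect, in units of the
#'   cell-level noise SD.
#' @param hill Hill coefficient shared by the dose-effect curves.
#' @param n_general_features,n_specific_per_mechanism sizes of the
#'   general-toxicity and mechanism-specific feature supports.
#' @param direction_jitter SD of per-compound jitter around the mechanism
#'   effect direction.
#' @param block_size,block_rho feature noise correlation blocks.
#' @param plate_offset_sd,well_offset_sd additive plate and well feature
#'   offsets (units of cell-level noise SD).
#' @param count_lognorm_sd,lum_lognorm_sd,lum_cv lognormal SD of the
#'   per-well count factor, of the luminescence well factor, and the
#'   multiplicative CV of the luminescence read.
#' @param lum_scale luminescence units per expected healthy cell.
#' @return A \code{SyntheticConfig} (validated list).
#' @export
syntheticConfig <- function(n_compounds = 30L, n_mechanisms = 5L,
    concentrations = 10^seq(log10(1e-8), log10(3e-5), length.out = 8L),
    wells_per_condition_per_plate = 4L, n_plates = 3L,
    vehicle_wells_per_plate = 35L, n_features = 300L,
    baseline_cells_per_well = 250L, seed = 42L,
    effect_scale = 8, hill = 1.5,
    n_general_features = 120L, n_specific_per_mechanism = 24L,
    direction_jitter = 0.15, block_size = 30L, block_rho = 0.6,
    plate_offset_sd = 0.05, well_offset_sd = 0.05,
    count_lognorm_sd = 0.1, lum_lognorm_sd = 0.1, lum_cv = 0.05,
    lum_scale = 1000) {
  cfg <- list(n_compounds = as.integer(n_compounds),
              n_mechanisms = as.integer(n_mechanisms),
              concentrations = as.numeric(concentrations),
              wells_per_condition_per_plate =
                as.integer(wells_per_condition_per_plate),
              n_plates = as.integer(n_plates),
              vehicle_wells_per_plate = as.integer(vehicle_wells_per_plate),
              n_features = as.integer(n_features),
              baseline_cells_per_well = as.integer(baseline_cells_per_well),
              seed = as.integer(seed), effect_scale = effect_scale,
              hill = hill,
              n_general_features = as.integer(n_general_features),
              n_specific_per_mechanism = as.integer(n_specific_per_mechanism),
              direction_jitter = direction_jitter,
              block_size = as.integer(block_size), block_rho = block_rho,
              plate_offset_sd = plate_offset_sd,
              well_offset_sd = well_offset_sd,
              count_lognorm_sd = count_lognorm_sd,
              lum_lognorm_sd = lum_lognorm_sd, lum_cv = lum_cv,
              lum_scale = lum_scale)
  counts <- cfg[c("n_compounds", "n_mechanisms",
                  "wells_per_condition_per_plate", "n_plates",
                  "vehicle_wells_per_plate", "n_features",
                  "baseline_cells_per_well")]
  if (any(vapply(counts, function(v) v < 1L, logical(1))))
    stop("all design counts must be positive")
  if (cfg$n_features < 2L) stop("at least two features are required")
  if (any(cfg$concentrations <= 0)) stop("concentrations must be positive")
  if (cfg$vehicle_wells_per_plate < 2L)
    stop("need at least 2 vehicle wells per plate")
  if (cfg$n_general_features +
      cfg$n_mechanisms * cfg$n_specific_per_mechanism > cfg$n_features)
    stop("informative feature supports exceed n_features; reduce ",
         "n_general_features or n_specific_per_mechanism")
  if (cfg$block_rho < 0 || cfg$block_rho >= 1)
    stop("block_rho must be in [0, 1)")
  class(cfg) <- "SyntheticConfig"
  cfg
}

#' Sigmoidal (Hill) dose-effect curve
#'
#' \code{effect = emax * c^hill / (c^hill + ec50^hill)}; the fractional
#' effect at concentration \code{c}, ranging from 0 (no effect) to
#' \code{emax} (plateau). Used by the generator for cell-count decline,
#' ATP decline and morphological shift magnitude.
#'
#' @param c concentration(s), molar, >= 0.
#' @param ec50 midpoint concentration, molar, > 0.
#' @param hill Hill coefficient, > 0.
#' @param emax maximal fractional effect in [0, 1].
#' @return effect value(s) in [0, emax].
#' @examples
#' hillEffect(1e-6, ec50 = 1e-6, hill = 2, emax = 0.8)  # emax / 2
#' @export
hillEffect <- function(c, ec50, hill, emax) {
  stopifnot(all(c >= 0), all(ec50 > 0), all(hill > 0),
            all(emax >= 0), all(emax <= 1))
  ch <- c^hill
  emax * ch / (ch + ec50^hill)
}

# Deterministic compound truth table (no RNG): mechanism assignment,
# potency/efficacy ladders, plus one colchicine-like decoupled compound
# and one no-effect compound.
.compoundTruth <- function(cfg) {
  n <- cfg$n_compounds
  code <- sprintf("CP%02d", seq_len(n))
  mech <- ((seq_len(n) - 1L) %% cfg$n_mechanisms) + 1L
  pos <- ((seq_len(n) - 1L) %/% cfg$n_mechanisms) + 1L   # rank in mechanism
  per <- max(pos)
  emax_ladder <- seq(1, 0.2, length.out = max(per, 2L))[pos]
  ec50_ladder <- 10^seq(log10(3e-7), log10(5e-6),
                        length.out = max(per, 2L))[pos]
  mech_shift <- c(0.6, 0.9, 1.3, 1.9, 2.8)[((mech - 1L) %% 5L) + 1L]
  ec50 <- ec50_ladder * mech_shift
  truth <- data.frame(compound = code, mechanism_id = mech,
                      ec50_count = ec50, ec50_atp = ec50,
                      hill = cfg$hill,
                      emax_count = emax_ladder, emax_atp = emax_ladder,
                      decoupled = FALSE, stringsAsFactors = FALSE)
  if (n >= 7L) {   # decoupled: detectable count collapses, ATP intact
    truth$ec50_count[7L] <- 3e-8
    truth$ec50_atp[7L] <- 3e-8
    truth$emax_count[7L] <- 0.7
    truth$emax_atp[7L] <- 0
    truth$decoupled[7L] <- TRUE
  }
  if (n >= 2L) {   # last compound: no visible effect on either endpoint
    truth$emax_count[n] <- 0
    truth$emax_atp[n] <- 0
  }
  truth$emax_morph <- pmax(truth$emax_count, truth$emax_atp)
  truth$toxic <- truth$emax_count > 0 | truth$emax_atp > 0
  truth
}

# Effect directions: unit vectors combining a shared general-toxicity
# component with a mechanism-specific component (disjoint supports),
# jittered per compound. Consumes RNG; call under the experiment seed.
.effectDirections <- function(cfg, truth) {
  p <- cfg$n_features
  ng <- cfg$n_general_features
  ns <- cfg$n_specific_per_mechanism
  g <- stats::rnorm(ng)
  g <- g / sqrt(sum(g^2))
  mech_dirs <- lapply(seq_len(cfg$n_mechanisms), function(m) {
    s <- stats::rnorm(ns)
    s / sqrt(sum(s^2))
  })
  alpha <- 0.6; beta <- 0.8
  dirs <- matrix(0, nrow = nrow(truth), ncol = p,
                 dimnames = list(truth$compound, NULL))
  for (k in seq_len(nrow(truth))) {
    m <- truth$mechanism_id[k]
    s <- mech_dirs[[m]] + cfg$direction_jitter * stats::rnorm(ns)
    s <- s / sqrt(sum(s^2))
    v <- numeric(p)
    v[seq_len(ng)] <- alpha * g
    v[ng + (m - 1L) * ns + seq_len(ns)] <- beta * s
    dirs[k, ] <- v / sqrt(sum(v^2))
  }
  informative <- seq_len(ng + cfg$n_mechanisms * ns)
  list(directions = dirs, informative = informative)
}

.featureNames <- function(p) {
  compartment <- c("Nucleus", "Cytoplasm", "Cell")
  channel <- c("DNA", "ER", "Mito", "Actin", "RNA")
  class <- c("Intensity", "Texture", "Profile", "Radial")
  i <- seq_len(p) - 1L
  paste(compartment[i %% 3L + 1L], channel[(i %/% 3L) %% 5L + 1L],
        class[(i %/% 15L) %% 4L + 1L], sprintf("F%03d", i + 1L), sep = "_")
}

# Cholesky factor of the block-diagonal equicorrelation noise covariance.
.noiseChol <- function(p, block_size, rho) {
  L <- matrix(0, p, p)
  starts <- seq(1L, p, by = block_size)
  for (s in starts) {
    e <- min(s + block_size - 1L, p)
    b <- e - s + 1L
    S <- matrix(rho, b, b); diag(S) <- 1
    L[s:e, s:e] <- chol(S)
  }
  L
}

#' Generate a full synthetic Cell Painting experiment
#'
#' Simulates single-cell morphology, per-well luminescence and the ground
#' truth behind both, with the statistical structure the downstream
#' analysis assumes. For each treated well the expected detectable cell
#' count is \code{baseline * (1 - hillEffect(c; count params))}, realized
#' as a Poisson draw around a per-well lognormal biological factor. Each
#' cell's feature vector is the feature baseline plus
#' \code{hillEffect(c; morphology magnitude) * effect_direction *
#' effect_scale}, plus block-correlated cell-level noise, a per-well
#' offset and a small per-plate offset. Luminescence is proportional to
#' the true viable biomass, \code{baseline * (1 - hillEffect(c; atp
#' params))}, with lognormal and multiplicative noise — so a compound can
#' lose detectable cells while its ATP signal stays flat
#' (colchicine-like decoupling). Vehicle wells receive noise only.
#'
#' Identical \code{(config, seed)} give identical outputs.
#'
#' @param config a [syntheticConfig()].
#' @param null if \code{TRUE}, force every compound inert (all
#'   \code{emax} = 0) while keeping the identical layout and noise;
#'   used for type-I-error calibration of the significance screen.
#' @return list with elements \code{cells} (a \code{CellFeatureTable}:
#'   single-cell rows joined with well metadata, feature columns in
#'   \code{attr(, "feature_cols")}), \code{metadata} (one row per well),
#'   \code{viability} (a \code{ViabilityTable} of raw luminescence),
#'   and \code{truth} (per-compound Hill parameters, per-well expected
#'   count and true viability fraction, the informative-feature index
#'   set and the effect directions).
#' @name generateExperiment
NULL

.experimentSetup <- function(cfg, null) {
  set.seed(cfg$seed)
  truth <- .compoundTruth(cfg)
  if (null) {
    truth$emax_count <- 0; truth$emax_atp <- 0; truth$emax_morph <- 0
    truth$toxic <- FALSE; truth$decoupled <- FALSE
  }
  dir <- .effectDirections(cfg, truth)
  p <- cfg$n_features
  n_cond <- cfg$n_compounds * length(cfg$concentrations)
  wpp <- n_cond * cfg$wells_per_condition_per_plate +
    cfg$vehicle_wells_per_plate

  # per-plate well design (same layout on every plate)
  design <- data.table(
    compound = c(rep(rep(truth$compound, each = length(cfg$concentrations)),
                     each = cfg$wells_per_condition_per_plate),
                 rep("VEHICLE", cfg$vehicle_wells_per_plate)),
    concentration_m = c(rep(rep(cfg$concentrations, cfg$n_compounds),
                            each = cfg$wells_per_condition_per_plate),
                        rep(0, cfg$vehicle_wells_per_plate)))
  design[, vehicle := compound == "VEHICLE"]
  design[, well := .wellLabels(wpp)]
  ki <- match(design$compound, truth$compound)           # NA for vehicle

  tr <- !design$vehicle
  effFor <- function(ec50, emax) {
    out <- numeric(nrow(design))
    out[tr] <- hillEffect(design$concentration_m[tr], ec50[ki[tr]],
                          truth$hill[ki[tr]], emax[ki[tr]])
    out
  }
  list(truth = truth, dir = dir, design = design, ki = ki,
       fnames = .featureNames(p),
       baseline_means = stats::rnorm(p, 0, 2),
       L = .noiseChol(p, cfg$block_size, cfg$block_rho),
       eff_count = effFor(truth$ec50_count, truth$emax_count),
       eff_atp = effFor(truth$ec50_atp, truth$emax_atp),
       eff_morph = effFor(truth$ec50_count, truth$emax_morph))
}

# Simulates one plate; consumes RNG in a fixed order so that callers
# iterating over plates draw an identical stream regardless of what they
# do with the cells.
.simulatePlate <- function(cfg, st, pl) {
  p <- cfg$n_features
  design <- st$design
  plate_id <- sprintf("P%d", pl)
  nw <- nrow(design)
  plate_offset <- stats::rnorm(p, 0, cfg$plate_offset_sd)
  well_factor <- exp(stats::rnorm(nw, 0, cfg$count_lognorm_sd))
  exp_count <- cfg$baseline_cells_per_well * well_factor * (1 - st$eff_count)
  n_cells <- stats::rpois(nw, exp_count)
  well_offset <- matrix(stats::rnorm(nw * p, 0, cfg$well_offset_sd), nw, p)

  M <- well_offset +
    matrix(st$baseline_means + plate_offset, nw, p, byrow = TRUE) +
    (st$eff_morph * cfg$effect_scale) *
      st$dir$directions[ifelse(is.na(st$ki), 1L, st$ki), , drop = FALSE] *
      as.numeric(!is.na(st$ki))
  rm(well_offset)

  idx <- rep(seq_len(nw), n_cells)
  X <- matrix(stats::rnorm(length(idx) * p), length(idx), p) %*% st$L
  X <- X + M[idx, , drop = FALSE]
  colnames(X) <- st$fnames

  lum <- cfg$lum_scale * cfg$baseline_cells_per_well *
    exp(stats::rnorm(nw, 0, cfg$lum_lognorm_sd)) * (1 - st$eff_atp) *
    exp(stats::rnorm(nw, 0, cfg$lum_cv))

  meta <- data.table(plate_id = plate_id, well = design$well,
                     compound = design$compound,
                     concentration_m = design$concentration_m,
                     vehicle = design$vehicle)
  list(cells = cbind(data.table(plate_id = plate_id,
                                well = design$well[idx]),
                     as.data.table(X)),
       meta = meta,
       viab = data.table(plate_id = plate_id, well = design$well,
                         luminescence = lum),
       truth_wells = data.table(plate_id = plate_id, well = design$well,
                                compound = design$compound,
                                concentration_m = design$concentration_m,
                                true_expected_count = exp_count,
                                true_viability_frac = 1 - st$eff_atp))
}

.truthOut <- function(st, null) {
  list(compounds = st$truth,
       wells = setDF(rbindlist(st$truth_wells_acc)),
       informative_features = st$fnames[st$dir$informative],
       directions = `colnames<-`(st$dir$directions, st$fnames),
       null = null)
}

#' @rdname generateExperiment
#' @param config a [syntheticConfig()].
#' @param null force every compound inert (see above).
#' @export
generateExperiment <- function(config, null = FALSE) {
  cfg <- config
  if (!inherits(cfg, "SyntheticConfig"))
    stop("'config' must be a SyntheticConfig")
  st <- .experimentSetup(cfg, null)
  cells_list <- meta_list <- viab_list <- tw_list <-
    vector("list", cfg$n_plates)
  for (pl in seq_len(cfg$n_plates)) {
    sim <- .simulatePlate(cfg, st, pl)
    cells_list[[pl]] <- sim$cells
    meta_list[[pl]] <- sim$meta
    viab_list[[pl]] <- sim$viab
    tw_list[[pl]] <- sim$truth_wells
  }
  metadata <- rbindlist(meta_list)
  cells <- makeCellFeatureTable(rbindlist(cells_list), metadata)
  viability <- .makeViabilityTable(rbindlist(viab_list), metadata)
  st$truth_wells_acc <- tw_list
  list(cells = cells, metadata = setDF(metadata), viability = viability,
       truth = .truthOut(st, null))
}

#' Generate and aggregate an experiment plate by plate
#'
#' Equivalent to [generateExperiment()] followed by [aggregateWells()] —
#' identical RNG stream, identical profiles — but each plate's
#' single-cell table is aggregated to well medians and discarded before
#' the next plate is simulated, keeping peak memory at one plate's worth
#' of cells. Intended for full-scale experiments where the single-cell
#' table itself is not needed.
#'
#' @param config a [syntheticConfig()].
#' @param null as in [generateExperiment()].
#' @return list with \code{profiles} (unnormalized well-level
#'   \linkS4class{ProfileSet}), \code{metadata}, \code{viability} and
#'   \code{truth} as in [generateExperiment()].
#' @export
generateProfiledExperiment <- function(config, null = FALSE) {
  cfg <- config
  if (!inherits(cfg, "SyntheticConfig"))
    stop("'config' must be a SyntheticConfig")
  st <- .experimentSetup(cfg, null)
  parts <- meta_list <- viab_list <- tw_list <-
    vector("list", cfg$n_plates)
  for (pl in seq_len(cfg$n_plates)) {
    sim <- .simulatePlate(cfg, st, pl)
    parts[[pl]] <- .aggregateCells(makeCellFeatureTable(sim$cells,
                                                        sim$meta))
    meta_list[[pl]] <- sim$meta
    viab_list[[pl]] <- sim$viab
    tw_list[[pl]] <- sim$truth_wells
    rm(sim)
  }
  metadata <- rbindlist(meta_list)
  assay <- do.call(cbind, lapply(parts, `[[`, "assay"))
  cd <- do.call(rbind, lapply(parts, `[[`, "colData"))
  empty <- do.call(rbind, lapply(parts, `[[`, "empty"))
  profiles <- ProfileSet(assay, cd, level = "well",
                         metadata = list(normalized = FALSE,
                                         empty_wells = empty,
                                         cells_dropped_na = 0L))
  viability <- .makeViabilityTable(rbindlist(viab_list), metadata)
  st$truth_wells_acc <- tw_list
  list(profiles = profiles, metadata = setDF(metadata),
       viability = viability, truth = .truthOut(st, null))
}

#' Generate a null experiment (every compound inert)
#'
#' Same layout and noise as [generateExperiment()] with all maximal
#' effects forced to zero, so any significant call by the downstream
#' screen is a false positive. Used to check type-I-error calibration.
#'
#' @param config a [syntheticConfig()].
#' @return as [generateExperiment()].
#' @export
makeNullExperiment <- function(config) generateExperiment(config, null = TRUE)
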