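# Shared fixtures. Expensive objects (notably the full-scale synthetic
# experiment) are built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cachedFixture <- function(name, fn) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, fn(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# Small screen: 8 compounds in 4 mechanisms, so the decoupled (CP07) and
# no-effect (CP08) compounds are both present; cheap enough for unit tests.
tinyConfig <- function(seed = 5, ...) {
  syntheticConfig(n_compounds = 8, n_mechanisms = 4,
                  baseline_cells_per_well = 20, n_features = 30,
                  n_general_features = 12, n_specific_per_mechanism = 4,
                  block_size = 10, vehicle_wells_per_plate = 6,
                  seed = seed, ...)
}

tinyRun <- function() cachedFixture("tiny_run", function() {
  ex <- suppressMessages(generateExperiment(tinyConfig()))
  wells <- suppressMessages(aggregateWells(ex$cells))
  nz <- normalizeProfiles(wells)
  flt <- suppressMessages(filterFeatures(nz))
  v <- normalizeViability(ex$viability)
  flt <- attachViability(flt, v)
  list(ex = ex, wells = wells, nz = nz, flt = flt, v = v,
       trt = aggregateTreatments(nz), truth = ex$truth)
})

# Full-scale synthetic screen under the default design; used by the
# acceptance suite.
defaultRun <- function() cachedFixture("default_run", function() {
  cfg <- syntheticConfig()
  ex <- suppressMessages(generateProfiledExperiment(cfg))
  nz <- normalizeProfiles(ex$profiles)
  flt <- suppressMessages(filterFeatures(nz))
  v <- normalizeViability(ex$viability)
  flt <- attachViability(flt, v)
  list(cfg = cfg, flt = flt, trt = aggregateTreatments(nz), v = v,
       truth = ex$truth)
})

# Hand-built well-level ProfileSet (profiles: wells x features matrix).
psFromMatrix <- function(m, plate = "P1", vehicle = NULL,
                         compound = NULL, conc = NULL,
                         cell_count = NULL, normalized = FALSE) {
  n <- nrow(m)
  if (is.null(vehicle)) vehicle <- rep(FALSE, n)
  if (is.null(compound)) compound <- ifelse(vehicle, "VEHICLE", "DRUG")
  if (is.null(conc)) conc <- ifelse(vehicle, 0, 1e-6)
  if (is.null(cell_count)) cell_count <- rep(10L, n)
  if (length(plate) == 1L) plate <- rep(plate, n)
  well <- sprintf("%s%02d", LETTERS[(seq_len(n) - 1L) %/% 24L + 1L],
                  (seq_len(n) - 1L) %% 24L + 1L)
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste(plate, well, sep = ":")
  cd <- data.frame(plate_id = plate, well = well, compound = compound,
                   concentration_m = conc, vehicle = vehicle,
                   cell_count = cell_count, row.names = ids)
  rownames(m) <- ids
  if (is.null(colnames(m))) colnames(m) <- sprintf("F%02d", seq_len(ncol(m)))
  ProfileSet(t(m), cd, level = "well",
             metadata = list(normalized = normalized,
                             norm_method = if (normalized) "robust_mad"))
}

# Minimal single-cell fixture: 2 wells x 3 cells x 3 features.
toyCellCsv <- function(dir = withr::local_tempdir(.local_envir =
                                                    parent.frame())) {
  cells <- data.frame(plate_id = "P1",
                      well = rep(c("A01", "A02"), each = 3L),
                      FeatA = c(1, 2, 9, 4, 5, 6),
                      FeatB = c(0, 0, 3, 1, 1, 1),
                      FeatC = c(10, 20, 30, 40, 50, 60))
  md <- data.frame(plate_id = "P1", well = c("A01", "A02"),
                   compound = c("VEHICLE", "CP01"),
                   concentration_m = c(0, 1e-6),
                   vehicle = c(TRUE, FALSE))
  cp <- file.path(dir, "cells.csv"); mp <- file.path(dir, "metadata.csv")
  write.csv(cells, cp, row.names = FALSE)
  write.csv(md, mp, row.names = FALSE)
  list(cells = cp, metadata = mp, dir = dir, cells_df = cells, md_df = md)
}
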