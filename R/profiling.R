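#' Aggregate single cells to per-well median profiles
#'
#' One profile per well: each feature is the median over that well's cell
#' population; the well's cell count (number of contributing cells) is
#' attached to \code{colData}. Cells with any missing feature value are
#' dropped first with a logged count. Wells present in the metadata but
#' contributing no cells are excluded from the profile columns and listed
#' in \code{metadata()$empty_wells} with cell_count 0.
#'
#' @param cells a \code{CellFeatureTable} (see [readCellFeatures()] /
#'   [makeCellFeatureTable()]).
#' @return a well-level \linkS4class{ProfileSet} (unnormalized).
#' @name aggregateWells
NULL

.aggregateCells <- function(cells) {
  feat <- attr(cells, "feature_cols")
  dt <- as.data.table(cells)

  complete <- stats::complete.cases(dt[, feat, with = FALSE])
  n_dropped <- sum(!complete)
  if (n_dropped) {
    .msg("dropping ", n_dropped, " cell(s) with missing feature values")
    dt <- dt[complete]
  }
  if (!nrow(dt)) stop("no complete cells left to aggregate")

  med <- dt[, c(list(cell_count = .N),
                lapply(.SD, stats::median)),
            by = c("plate_id", "well", "compound", "concentration_m",
                   "vehicle"),
            .SDcols = feat]

  md_wells <- attr(cells, "metadata")
  have <- .wellKey(med$plate_id, med$well)
  empty <- md_wells[!.wellKey(md_wells$plate_id, md_wells$well) %in% have,
                    , drop = FALSE]
  empty$cell_count <- rep(0L, nrow(empty))

  assay <- t(as.matrix(med[, feat, with = FALSE]))
  rownames(assay) <- feat
  colnames(assay) <- have
  cd <- setDF(med[, .(plate_id, well, compound, concentration_m, vehicle,
                      cell_count)])
  rownames(cd) <- have
  list(assay = assay, colData = cd, empty = empty, n_dropped = n_dropped)
}

#' @rdname aggregateWells
#' @export
aggregateWells <- function(cells) {
  if (!inherits(cells, "CellFeatureTable"))
    stop("'cells' must be a CellFeatureTable")
  if (!nrow(cells)) stop("empty cell table")
  parts <- .aggregateCells(cells)
  if (nrow(parts$empty))
    .msg(nrow(parts$empty), " well(s) with zero contributing cells ",
         "excluded from profiles (kept in metadata()$empty_wells): ",
         paste(head(.wellKey(parts$empty$plate_id, parts$empty$well), 8L),
               collapse = ", "), if (nrow(parts$empty) > 8L) ", ...")
  ProfileSet(parts$assay, parts$colData, level = "well",
             metadata = list(normalized = FALSE,
                             empty_wells = parts$empty,
                             cells_dropped_na = parts$n_dropped))
}

#' Per-well cell counts including zero-cell wells
#'
#' Wells whose entire population was lost (no detectable cells) carry no
#' profile column but are real observations for count-based analyses;
#' this accessor returns the profiled wells' metadata with the zero-cell
#' wells appended (cell_count 0).
#'
#' @param ps a well-level \linkS4class{ProfileSet}.
#' @return data.frame with one row per well in the original metadata.
#' @export
wellCountTable <- function(ps) {
  stopifnot(is(ps, "ProfileSet"), profileLevel(ps) == "well")
  cd <- as.data.frame(SummarizedExperiment::colData(ps))
  empty <- S4Vectors::metadata(ps)$empty_wells
  cols <- c("plate_id", "well", "compound", "concentration_m", "vehicle",
            "cell_count")
  out <- cd[, intersect(cols, colnames(cd)), drop = FALSE]
  if ("viability_pct" %in% colnames(cd))
    out$viability_pct <- cd$viability_pct
  if (!is.null(empty) && nrow(empty)) {
    empty <- empty[, cols, drop = FALSE]
    if ("viability_pct" %in% colnames(out))
      empty$viability_pct <- NA_real_
    out <- rbind(out, empty)
  }
  rownames(out) <- NULL
  out
}

.normStats <- function(x, method) {
  # x: control values of one feature on one plate; returns center/scale
  switch(method,
    robust_mad = {
      ctr <- stats::median(x)
      list(center = ctr,
           scale = 1.4826 * stats::median(abs(x - ctr)))
    },
    zscore = list(center = mean(x), scale = stats::sd(x)),
    minmax = list(center = min(x), scale = max(x) - min(x)))
}

#' Normalize well profiles against same-plate vehicle controls
#'
#' Per feature and per plate, profiles are centered and scaled using
#' statistics of that plate's vehicle-control wells only:
#' \describe{
#'   \item{robust_mad}{\code{(x - median_ctrl) / (1.4826 * MAD_ctrl)},
#'     with \code{MAD_ctrl = median(|x_ctrl - median_ctrl|)}; the 1.4826
#'     consistency constant calibrates the MAD to the SD of a normal
#'     distribution, so vehicle profiles have robust Z-scores with
#'     median 0 and unit 1.4826*MAD on every plate.}
#'   \item{zscore}{\code{(x - mean_ctrl) / sd_ctrl}.}
#'   \item{minmax}{\code{(x - min_ctrl) / (max_ctrl - min_ctrl)}.}
#' }
#' Features whose control scale is zero on any plate carry no calibrated
#' deviation scale and are dropped with a warning (recorded in the drop
#' ledger).
#'
#' @param ps a well-level \linkS4class{ProfileSet}.
#' @param method normalization method.
#' @return the normalized \linkS4class{ProfileSet}; \code{metadata()}
#'   records the method and the control wells used per plate.
#' @export
normalizeProfiles <- function(ps, method = c("robust_mad", "zscore",
                                             "minmax")) {
  method <- match.arg(method)
  stopifnot(is(ps, "ProfileSet"))
  if (profileLevel(ps) != "well")
    stop("normalization operates on well-level profiles")
  m <- profileMatrix(ps)
  plates <- plateIds(ps)
  veh <- isVehicle(ps)
  out <- m
  zero_scale <- character()
  control_wells <- list()
  for (pl in unique(plates)) {
    cols <- which(plates == pl)
    ctrl <- cols[veh[cols]]
    if (length(ctrl) < 2L)
      stop("plate ", pl, " has fewer than 2 vehicle wells")
    control_wells[[pl]] <- colnames(m)[ctrl]
    for (f in seq_len(nrow(m))) {
      st <- .normStats(m[f, ctrl], method)
      if (!is.finite(st$scale) || st$scale == 0) {
        zero_scale <- c(zero_scale, rownames(m)[f])
      } else {
        out[f, cols] <- (m[f, cols] - st$center) / st$scale
      }
    }
  }
  zero_scale <- unique(zero_scale)
  keep <- setdiff(rownames(m), zero_scale)
  if (length(zero_scale)) {
    warning(length(zero_scale),
            " feature(s) dropped: zero control scale on some plate",
            call. = FALSE)
  }
  led <- rbind(dropLedger(ps),
               if (length(zero_scale))
                 data.frame(feature = zero_scale, reason = "zero_scale",
                            detail = method))
  res <- ps[keep, ]
  SummarizedExperiment::assay(res, "profile") <- out[keep, , drop = FALSE]
  md <- S4Vectors::metadata(res)
  md$normalized <- TRUE
  md$norm_method <- method
  md$control_wells <- control_wells
  md$drop_ledger <- led
  S4Vectors::metadata(res) <- md
  res
}

#' Prune features by dispersion and pairwise correlation
#'
#' First drops features whose SD (across all profiles) exceeds
#' \code{sd_max} — guarding against extreme values produced by the
#' normalization itself — then walks the remaining features in stored
#' column order, dropping any feature whose absolute Pearson correlation
#' with an already-kept feature exceeds \code{corr_max} (the earlier
#' feature wins; deterministic). Idempotent.
#'
#' @param ps a normalized \linkS4class{ProfileSet}.
#' @param sd_max SD cutoff (default 2000).
#' @param corr_max absolute correlation cutoff (default 0.9).
#' @return the filtered \linkS4class{ProfileSet}; dropped features and
#'   reasons are appended to \code{dropLedger()}.
#' @export
filterFeatures <- function(ps, sd_max = 2000, corr_max = 0.9) {
  stopifnot(is(ps, "ProfileSet"))
  if (!isNormalized(ps)) stop("filterFeatures expects normalized profiles")
  m <- profileMatrix(ps)
  sds <- apply(m, 1L, stats::sd)
  drop_sd <- rownames(m)[sds > sd_max]
  keep1 <- setdiff(rownames(m), drop_sd)
  led_new <- if (length(drop_sd))
    data.frame(feature = drop_sd, reason = "sd",
               detail = sprintf("sd=%.4g", sds[drop_sd]))

  sub <- m[keep1, , drop = FALSE]
  kept <- integer()
  dropped_cor <- character(); partner <- character()
  if (nrow(sub) >= 1L) {
    cm <- suppressWarnings(stats::cor(t(sub)))
    cm[is.na(cm)] <- 0
    for (j in seq_len(nrow(sub))) {
      if (length(kept) &&
          any(abs(cm[j, kept]) > corr_max)) {
        hit <- kept[which(abs(cm[j, kept]) > corr_max)[1L]]
        dropped_cor <- c(dropped_cor, rownames(sub)[j])
        partner <- c(partner, rownames(sub)[hit])
      } else {
        kept <- c(kept, j)
      }
    }
  }
  if (length(dropped_cor))
    led_new <- rbind(led_new,
                     data.frame(feature = dropped_cor,
                                reason = "correlation",
                                detail = paste0("r>", corr_max, " with ",
                                                partner)))
  keep_final <- rownames(sub)[kept]
  if (!length(keep_final)) stop("all features dropped by filters")

  res <- ps[keep_final, ]
  md <- S4Vectors::metadata(res)
  md$drop_ledger <- rbind(dropLedger(ps), led_new)
  md$filtered <- TRUE
  md$filter_params <- c(sd_max = sd_max, corr_max = corr_max)
  S4Vectors::metadata(res) <- md
  res
}

#' Aggregate well profiles to treatment-level profiles
#'
#' One profile per compound-by-concentration condition (vehicle wells
#' collapse to a single VEHICLE profile): each feature value is the
#' median across the condition's wells over all plates, and
#' \code{cell_count} is the median well cell count.
#'
#' @param ps a normalized well-level \linkS4class{ProfileSet}.
#' @return a treatment-level \linkS4class{ProfileSet}.
#' @export
aggregateTreatments <- function(ps) {
  stopifnot(is(ps, "ProfileSet"))
  if (!isNormalized(ps))
    stop("treatment aggregation expects normalized profiles")
  if (profileLevel(ps) != "well") stop("input must be well-level")
  cd <- as.data.frame(SummarizedExperiment::colData(ps))
  grp <- paste(cd$compound, signif(cd$concentration_m, 8L), sep = "@")
  ug <- unique(grp)
  m <- profileMatrix(ps)
  agg <- vapply(ug, function(g) {
    cols <- which(grp == g)
    apply(m[, cols, drop = FALSE], 1L, stats::median)
  }, numeric(nrow(m)))
  first <- match(ug, grp)
  cc <- vapply(ug, function(g) stats::median(cd$cell_count[grp == g]),
               numeric(1))
  nw <- vapply(ug, function(g) sum(grp == g), numeric(1))
  cd_out <- data.frame(compound = cd$compound[first],
                       concentration_m = cd$concentration_m[first],
                       vehicle = cd$vehicle[first],
                       cell_count = cc, n_wells = as.integer(nw),
                       row.names = ug)
  md <- S4Vectors::metadata(ps)
  ProfileSet(agg, cd_out, level = "treatment",
             metadata = list(normalized = TRUE,
                             norm_method = md$norm_method,
                             control_wells = md$control_wells,
                             drop_ledger = md$drop_ledger))
}

#' Attach vehicle-relative viability to well profiles
#'
#' Matches wells by \code{plate_id} + \code{well} and stores
#' \code{viability_pct} in \code{colData}; run [normalizeViability()]
#' first.
#'
#' @param ps a well-level \linkS4class{ProfileSet}.
#' @param viability a normalized \code{ViabilityTable}.
#' @return \code{ps} with \code{viabilityPct()} populated.
#' @export
attachViability <- function(ps, viability) {
  stopifnot(is(ps, "ProfileSet"))
  if (all(is.na(viability$viability_pct)))
    stop("viability table is unnormalized; run normalizeViability() first")
  key_ps <- .wellKey(plateIds(ps), wellIds(ps))
  key_v <- .wellKey(viability$plate_id, viability$well)
  mi <- match(key_ps, key_v)
  if (anyNA(mi))
    stop("profiles without a viability read: ",
         paste(key_ps[is.na(mi)][1:5], collapse = ", "))
  viabilityPct(ps) <- viability$viability_pct[mi]
  ps
}
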