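#' Build a CellFeatureTable by joining single-cell rows to well metadata
#'
#' @param cells data.frame with \code{plate_id}, \code{well} and numeric
#'   feature columns (one row per segmented cell).
#' @param metadata plate metadata with one row per well: \code{plate_id},
#'   \code{well}, \code{compound}, \code{concentration_m}, \code{vehicle}.
#' @return a \code{CellFeatureTable}: the joined data.table with feature
#'   column names recorded in \code{attr(, "feature_cols")}.
#' @export
makeCellFeatureTable <- function(cells, metadata) {
  cells <- as.data.table(cells)
  metadata <- setDF(as.data.table(metadata))
  .checkMetadata(metadata)
  if (!all(c("plate_id", "well") %in% names(cells)))
    stop("cell table must carry 'plate_id' and 'well' columns")

  cand <- setdiff(names(cells), .metadataSchema)
  numeric_ok <- vapply(cells[, cand, with = FALSE], is.numeric, logical(1))
  if (any(!numeric_ok)) {
    .msg("excluding non-numeric candidate feature column(s): ",
         paste(cand[!numeric_ok], collapse = ", "))
    warning("non-numeric feature column(s) excluded: ",
            paste(cand[!numeric_ok], collapse = ", "), call. = FALSE)
  }
  feat <- cand[numeric_ok]
  if (!length(feat)) stop("zero feature columns detected")

  key_cells <- .wellKey(cells$plate_id, cells$well)
  key_md <- .wellKey(metadata$plate_id, metadata$well)
  orphan <- setdiff(unique(key_cells), key_md)
  if (length(orphan))
    stop("cell rows reference well(s) absent from plate metadata: ",
         paste(orphan, collapse = ", "))

  mi <- match(key_cells, key_md)
  out <- cbind(cells[, c("plate_id", "well"), with = FALSE],
               data.table(compound = metadata$compound[mi],
                          concentration_m = metadata$concentration_m[mi],
                          vehicle = metadata$vehicle[mi]),
               cells[, feat, with = FALSE])
  data.table::setattr(out, "feature_cols", feat)
  data.table::setattr(out, "metadata", metadata)
  data.table::setattr(out, "class",
                      c("CellFeatureTable", class(data.table())))
  out
}

.makeViabilityTable <- function(v, metadata) {
  v <- as.data.table(v)
  metadata <- setDF(as.data.table(metadata))
  .checkMetadata(metadata)
  if (!all(c("plate_id", "well", "luminescence") %in% names(v)))
    stop("viability table must carry 'plate_id', 'well', 'luminescence'")
  if (any(!is.finite(v$luminescence)) || any(v$luminescence < 0))
    stop("luminescence reads must be finite and non-negative")
  key <- .wellKey(v$plate_id, v$well)
  if (anyDuplicated(key))
    stop("duplicated well(s) in viability table: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  key_md <- .wellKey(metadata$plate_id, metadata$well)
  orphan <- setdiff(key, key_md)
  if (length(orphan))
    stop("viability well(s) absent from plate metadata: ",
         paste(orphan, collapse = ", "))
  mi <- match(key, key_md)
  out <- data.table(plate_id = v$plate_id, well = v$well,
                    compound = metadata$compound[mi],
                    concentration_m = metadata$concentration_m[mi],
                    vehicle = metadata$vehicle[mi],
                    luminescence = v$luminescence,
                    viability_pct = NA_real_)
  data.table::setattr(out, "class",
                      c("ViabilityTable", class(data.table())))
  out
}

#' Read a single-cell feature CSV joined to plate metadata
#'
#' The feature columns are auto-detected as the numeric columns that are
#' not part of the metadata schema (\code{plate_id}, \code{well},
#' \code{compound}, \code{concentration_m}, \code{vehicle}); non-numeric
#' candidates are excluded with a warning. Cell rows that reference a
#' well absent from the metadata are an error.
#'
#' @param path CSV of single-cell rows (header; \code{plate_id},
#'   \code{well}, feature columns).
#' @param metadata_path CSV of plate metadata, one row per well.
#' @return a \code{CellFeatureTable}; see [makeCellFeatureTable()].
#' @export
readCellFeatures <- function(path, metadata_path) {
  for (f in c(path, metadata_path))
    if (!file.exists(f)) stop("file not found: ", f)
  cells <- fread(path)
  metadata <- fread(metadata_path)
  makeCellFeatureTable(cells, metadata)
}

#' Read a per-well luminescence CSV joined to plate metadata
#'
#' @param path CSV with \code{plate_id}, \code{well},
#'   \code{luminescence} (raw reads; zero is allowed for a dead well).
#' @param metadata_path CSV of plate metadata, one row per well.
#' @return a \code{ViabilityTable} with \code{viability_pct} unset
#'   (populated later by [normalizeViability()]).
#' @export
readViability <- function(path, metadata_path) {
  for (f in c(path, metadata_path))
    if (!file.exists(f)) stop("file not found: ", f)
  v <- fread(path)
  metadata <- fread(metadata_path)
  .makeViabilityTable(v[, intersect(c("plate_id", "well", "luminescence"),
                                    names(v)), with = FALSE], metadata)
}

#' Write the standard CSVs of a (synthetic) experiment
#'
#' Writes \code{cell_features.csv} (plate_id, well + features),
#' \code{metadata.csv}, \code{viability.csv} (raw reads) and
#' \code{ground_truth.csv} (per-compound truth, when present).
#'
#' @param experiment a list as returned by [generateExperiment()].
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
writeExperiment <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  feat <- attr(experiment$cells, "feature_cols")
  paths <- c(cells = file.path(dir, "cell_features.csv"),
             metadata = file.path(dir, "metadata.csv"),
             viability = file.path(dir, "viability.csv"))
  fwrite(experiment$cells[, c("plate_id", "well", feat), with = FALSE],
         paths["cells"])
  fwrite(experiment$metadata, paths["metadata"])
  fwrite(as.data.table(experiment$viability)[,
           c("plate_id", "well", "luminescence"), with = FALSE],
         paths["viability"])
  if (!is.null(experiment$truth$compounds)) {
    paths <- c(paths, truth = file.path(dir, "ground_truth.csv"))
    fwrite(experiment$truth$compounds, paths["truth"])
  }
  invisible(paths)
}

#' Export a ProfileSet as CSV (metadata columns + features)
#'
#' @param ps a \linkS4class{ProfileSet}.
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeProfiles <- function(ps, path) {
  cd <- as.data.frame(SummarizedExperiment::colData(ps))
  m <- t(profileMatrix(ps))
  fwrite(cbind(data.table(profile_id = colnames(ps)), as.data.table(cd),
               as.data.table(m)), path)
  invisible(path)
}
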