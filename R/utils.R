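# Internal helpers shared across modules.

#' @importFrom data.table data.table as.data.table := .N .SD setnames
#'   rbindlist fwrite fread setDF setDT
#' @import methods
NULL

# Deterministic sub-seed derivation; stays below 2^31 so it is always a
# valid R integer seed.
.subSeed <- function(seed, offset) {
  s <- (abs(as.numeric(seed)) + 104729 * abs(as.numeric(offset))) %% 2147483629
  as.integer(s)
}

.msg <- function(...) message("phenotox: ", ...)

.assertScalarNum <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    stop(sprintf("'%s' must be a finite scalar in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

# Well key used to align profiles, viability reads and metadata.
.wellKey <- function(plate_id, well) paste(plate_id, well, sep = ":")

# Row-letter + zero-padded-column labels (A01, ..., Z36, AA01, ...) for an
# arbitrary number of wells laid out in rows of `ncol` wells.
.wellLabels <- function(n, ncol = 36L) {
  rows <- ceiling(n / ncol)
  lab1 <- LETTERS
  lab2 <- as.vector(outer(LETTERS, LETTERS, function(a, b) paste0(a, b)))
  rowlab <- c(lab1, lab2)[seq_len(rows)]
  idx <- seq_len(n) - 1L
  paste0(rowlab[idx %/% ncol + 1L], sprintf("%02d", idx %% ncol + 1L))
}

.metadataSchema <- c("plate_id", "well", "compound", "concentration_m",
                     "vehicle")

.checkMetadata <- function(md) {
  miss <- setdiff(.metadataSchema, names(md))
  if (length(miss)) {
    stop("plate metadata is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  key <- .wellKey(md$plate_id, md$well)
  if (anyDuplicated(key)) {
    stop("duplicate well(s) in plate metadata: ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  if (!all(grepl("^[A-Z]+[0-9]{2,}$", md$well))) {
    stop("well labels must match row-letter + zero-padded column (e.g. 'B03')",
         call. = FALSE)
  }
  bad <- md$vehicle & (md$concentration_m != 0 | md$compound != "VEHICLE")
  bad <- bad | (!md$vehicle & md$compound == "VEHICLE")
  if (any(bad)) {
    stop("vehicle flag inconsistent with compound/concentration for well(s): ",
         paste(head(key[bad], 5L), collapse = ", "), call. = FALSE)
  }
  invisible(md)
}
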