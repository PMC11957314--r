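#' Vehicle-relative viability normalization
#'
#' Scales each well's luminescence against the median luminescence of
#' its plate's vehicle-control wells (100\% = healthy vehicle level):
#' \code{viability_pct = 100 * luminescence / median(vehicle
#' luminescence on the same plate)}. The per-plate vehicle median is
#' exactly 100 after normalization.
#'
#' @param v a \code{ViabilityTable} (see [readViability()]).
#' @return the table with \code{viability_pct} populated.
#' @export
normalizeViability <- function(v) {
  v <- as.data.table(v)
  for (pl in unique(v$plate_id)) {
    rows <- v$plate_id == pl
    ctrl <- v$luminescence[rows & v$vehicle]
    if (!length(ctrl)) stop("plate ", pl, " has no vehicle wells")
    med <- stats::median(ctrl)
    if (med <= 0) stop("plate ", pl,
                       " rejected: vehicle median luminescence is 0")
    v[rows, viability_pct := 100 * luminescence / med]
  }
  data.table::setattr(v, "class", c("ViabilityTable", class(data.table())))
  v
}

.welchP <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) return(NA_real_)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
  }
  tryCatch(stats::t.test(x, y)$p.value, error = function(e) NA_real_)
}

.tier <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))))
}

#' Per-condition significance screen of count and viability
#'
#' For every compound-by-concentration condition, the condition's
#' well-level cell counts and viability percentages are compared with
#' the vehicle-control wells of the plates the condition occupies, by a
#' two-sided Welch (unequal-variance) two-sample t-test. Significance
#' tiers: \code{*} p < 0.05, \code{**} p < 0.01, \code{***} p < 0.001,
#' \code{ns} otherwise. No multiple-testing correction is applied by
#' default; set \code{fdr = TRUE} for Benjamini-Hochberg adjusted
#' p-values per endpoint.
#'
#' Wells whose whole population was lost (zero detectable cells) carry
#' no profile but count as observations of 0 for the cell-count test;
#' they are recovered from \code{metadata()$empty_wells}.
#'
#' @param ps a well-level \linkS4class{ProfileSet} carrying cell counts
#'   (and \code{viability_pct}, if viability is to be screened; see
#'   [attachViability()]).
#' @param viability optional normalized \code{ViabilityTable}; when
#'   given, viability percentages are (re)matched by plate and well for
#'   every well, including zero-cell wells.
#' @param fdr apply Benjamini-Hochberg adjustment per endpoint.
#' @return data.frame of \code{ConditionSummary} rows: compound,
#'   concentration, median count and viability, relative count drop
#'   versus vehicle, p-values and tiers per endpoint.
#' @export
conditionTests <- function(ps, viability = NULL, fdr = FALSE) {
  cd <- wellCountTable(ps)
  if (!nrow(cd)) stop("empty profile set")
  if (!is.null(viability)) {
    if (all(is.na(viability$viability_pct)))
      stop("viability table is unnormalized; run normalizeViability() first")
    mi <- match(.wellKey(cd$plate_id, cd$well),
                .wellKey(viability$plate_id, viability$well))
    cd$viability_pct <- viability$viability_pct[mi]
  }
  have_v <- "viability_pct" %in% colnames(cd) && !all(is.na(cd$viability_pct))
  trt <- cd[!cd$vehicle, , drop = FALSE]
  if (!nrow(trt)) stop("no treated wells")
  key <- paste(trt$compound, signif(trt$concentration_m, 8L), sep = "@")
  out <- lapply(unique(key), function(kk) {
    rows <- trt[key == kk, , drop = FALSE]
    scope <- cd$vehicle & cd$plate_id %in% unique(rows$plate_id)
    veh <- cd[scope, , drop = FALSE]
    if (nrow(rows) < 2L || nrow(veh) < 2L)
      stop("condition ", kk, ": insufficient replication for the screen")
    p_count <- .welchP(rows$cell_count, veh$cell_count)
    p_viab <- if (have_v) .welchP(rows$viability_pct, veh$viability_pct)
              else NA_real_
    data.frame(compound = rows$compound[1],
               concentration_m = rows$concentration_m[1],
               n_wells = nrow(rows), n_vehicle = nrow(veh),
               median_count = stats::median(rows$cell_count),
               vehicle_median_count = stats::median(veh$cell_count),
               median_count_pct =
                 100 * stats::median(rows$cell_count) /
                 stats::median(veh$cell_count),
               median_viability_pct =
                 if (have_v) stats::median(rows$viability_pct) else NA_real_,
               p_count = p_count, p_viability = p_viab,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (fdr) {
    out$p_count <- stats::p.adjust(out$p_count, method = "BH")
    out$p_viability <- stats::p.adjust(out$p_viability, method = "BH")
  }
  out$count_drop_frac <- 1 - out$median_count / out$vehicle_median_count
  out$tier_count <- .tier(out$p_count)
  out$tier_viability <- .tier(out$p_viability)
  out
}

.fit4pl <- function(dose, resp) {
  # y = floor + (ceiling - floor) / (1 + (x / e)^b)
  start <- list(fl = min(resp), ce = max(resp),
                le = mean(log(range(dose))), b = 1)
  lo <- c(fl = -Inf, ce = -Inf, le = log(min(dose) / 100), b = 0.1)
  hi <- c(fl = Inf, ce = Inf, le = log(max(dose) * 100), b = 10)
  f <- function(p, x) p[1] + (p[2] - p[1]) / (1 + exp(p[4] *
                                                      (log(x) - p[3])))
  fit <- tryCatch(
    minpack.lm::nlsLM(resp ~ fl + (ce - fl) / (1 + exp(b * (log(dose) - le))),
                      start = start, lower = lo, upper = hi,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    p <- stats::coef(fit)
    return(list(midpoint = exp(p[["le"]]), rss = sum(stats::resid(fit)^2),
                converged = TRUE))
  }
  # fallback: direct least squares on the same parameterization
  obj <- function(p) sum((resp - f(p, dose))^2)
  op <- tryCatch(stats::optim(unlist(start), obj), error = function(e) NULL)
  if (is.null(op)) return(NULL)
  le <- min(max(op$par[["le"]], lo[["le"]]), hi[["le"]])
  list(midpoint = exp(le), rss = op$value, converged = op$convergence == 0)
}

#' Four-parameter log-logistic potency summaries (IC50 / LC50)
#'
#' Fits, per compound, a 4PL curve (floor, ceiling, slope, midpoint) by
#' least squares to the median response across concentrations —
#' \code{viability_pct} for IC50 or the vehicle-relative median cell
#' count for LC50 — and reports the fitted midpoint. The potency is
#' not-determined when fewer than 4 concentrations respond, the fit
#' fails, or the response is flat (span below 20\% of the top response).
#' Midpoints outside the tested range are flagged extrapolated.
#'
#' @param summaries a [conditionTests()] data.frame.
#' @param endpoint \code{"viability"} (IC50) or \code{"count"} (LC50).
#' @return data.frame of \code{PotencySummary} rows: compound, potency
#'   (molar or NA), \code{determined}, \code{extrapolated},
#'   \code{converged}, \code{rss}.
#' @export
fitPotency <- function(summaries, endpoint = c("viability", "count")) {
  endpoint <- match.arg(endpoint)
  resp_col <- if (endpoint == "viability") "median_viability_pct"
              else "median_count_pct"
  out <- lapply(sort(unique(summaries$compound)), function(cp) {
    rows <- summaries[summaries$compound == cp, , drop = FALSE]
    rows <- rows[order(rows$concentration_m), , drop = FALSE]
    dose <- rows$concentration_m
    resp <- rows[[resp_col]]
    nd <- function(why) data.frame(compound = cp, endpoint = endpoint,
                                   potency_m = NA_real_, determined = FALSE,
                                   reason = why, extrapolated = NA,
                                   converged = NA, rss = NA_real_,
                                   stringsAsFactors = FALSE)
    if (length(dose) < 4L) stop("compound ", cp,
                                ": fewer than 4 concentrations")
    if (any(is.na(resp))) return(nd("missing response"))
    if ((max(resp) - min(resp)) < 0.2 * max(resp)) return(nd("flat"))
    fit <- .fit4pl(dose, resp)
    if (is.null(fit) || !fit$converged || !is.finite(fit$midpoint))
      return(nd("fit failed"))
    data.frame(compound = cp, endpoint = endpoint,
               potency_m = fit$midpoint, determined = TRUE, reason = "",
               extrapolated = fit$midpoint < min(dose) |
                 fit$midpoint > max(dose),
               converged = fit$converged, rss = fit$rss,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Conditions where cell count drops but ATP viability does not
#'
#' Flags conditions with a significant count decrease (\code{p_count <
#' alpha}), non-significant viability (\code{p_viability >= alpha}) and
#' a median count drop of at least \code{count_drop_floor} — the
#' colchicine-like decoupling signature in which cells stop being
#' detectable while the population's ATP content is maintained.
#'
#' @param summaries a [conditionTests()] data.frame with both endpoints.
#' @param alpha significance level (default 0.05).
#' @param count_drop_floor minimal fractional count decrease
#'   (default 0.2).
#' @return the flagged subset of \code{summaries} (possibly empty).
#' @export
decouplingReport <- function(summaries, alpha = 0.05,
                             count_drop_floor = 0.2) {
  need <- c("p_count", "p_viability", "count_drop_frac")
  if (!all(need %in% colnames(summaries)))
    stop("run conditionTests() on profiles with viability attached first")
  flag <- !is.na(summaries$p_count) & summaries$p_count < alpha &
    !is.na(summaries$p_viability) & summaries$p_viability >= alpha &
    summaries$count_drop_frac >= count_drop_floor
  summaries[flag, , drop = FALSE]
}
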