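# Stage 4: what would broad-scale restoration cost? Linear per-hectare
# extrapolation under per-technique lower/median/upper cost bounds, plus
# the taxonomic-coverage statistic.

#' Per-technique restoration cost scheme
#'
#' @param technique Technique name.
#' @param low,median,high US$ per hectare bounds (0 < low <= median <=
#'   high).
#' @return One-row data frame of class `cost_scheme`.
#' @export
cost_scheme <- function(technique, low, median, high) {
  if (!(low > 0 && low <= median && median <= high))
    stop("cost bounds must satisfy 0 < low <= median <= high", call. = FALSE)
  structure(data.frame(technique = technique, low_usd_per_ha = low,
                       median_usd_per_ha = median, high_usd_per_ha = high),
            class = c("cost_scheme", "data.frame"))
}

#' Bundled per-technique cost table
#'
#' Reads the per-hectare cost table shipped with the package. The table is
#' a synthetic stand-in assembled from the published headline figures: the
#' global per-hectare range (US$6,000 lower bound; US$143 million upper for
#' artificial-reef construction, with US$261 million recorded for the most
#' intensive substrate-addition approaches) and a coral-gardening median
#' consistent with a ~US$3.3 billion bill for restoring 117,000 ha.
#' Technique-level interior values are plausible placeholders; replace the
#' CSV with a digitized published table for real analyses.
#'
#' @return Data frame, one row per technique, of class `cost_scheme`.
#' @export
default_cost_table <- function() {
  f <- system.file("extdata", "cost_schemes_synthetic.csv",
                   package = "reefrestore", mustWork = TRUE)
  tab <- read.csv(f)
  for (i in seq_len(nrow(tab)))
    cost_scheme(tab$technique[i], tab$low_usd_per_ha[i],
                tab$median_usd_per_ha[i], tab$high_usd_per_ha[i])  # validate
  structure(tab, class = c("cost_scheme", "data.frame"))
}

#' Restoration cost as a function of rehabilitated area
#'
#' Total cost is linear through the origin: per-hectare bound times area,
#' for the lower, median and upper bound of each scheme row.
#'
#' @param scheme A `cost_scheme` (one or more rows).
#' @param areas_ha Non-negative areas in hectares.
#' @return Data frame with technique, area_ha and low/median/high totals in
#'   US$.
#' @export
cost_curve <- function(scheme, areas_ha) {
  if (any(areas_ha < 0)) stop("areas must be >= 0", call. = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(scheme)), function(i)
    data.frame(technique = scheme$technique[i], area_ha = areas_ha,
               low_usd = scheme$low_usd_per_ha[i] * areas_ha,
               median_usd = scheme$median_usd_per_ha[i] * areas_ha,
               high_usd = scheme$high_usd_per_ha[i] * areas_ha)))
  rownames(out) <- NULL
  out
}

#' Hectares corresponding to a fraction of a reef area
#'
#' @param total_area_km2 Total degraded area in square kilometres.
#' @param fraction Fraction in \[0, 1\].
#' @return Area in hectares (1 km^2 = 100 ha).
#' @export
area_for_fraction <- function(total_area_km2, fraction) {
  assert_number(fraction, "fraction", 0, 1)
  if (total_area_km2 < 0) stop("area must be >= 0", call. = FALSE)
  total_area_km2 * fraction * 100
}

#' Average taxonomic coverage of restoration actions
#'
#' Mean, over records, of the ratio between the number of coral taxa used
#' in a restoration action and the local coral richness of its locality,
#' reported as a percent. Records at zero-richness localities are excluded
#' with a report.
#'
#' @param records `restoration_records` (with `n_genera`).
#' @param grid The `reef_grid` the records belong to.
#' @return Percent coverage (scalar); attribute `n_excluded`.
#' @export
taxonomic_coverage <- function(records, grid) {
  loc <- grid$localities
  j <- match(records$locality_id, loc$id)
  if (anyNA(j)) stop("record(s) reference unknown localities", call. = FALSE)
  richness <- loc$coral_richness[j]
  ok <- richness > 0
  if (any(!ok)) message(sum(!ok), " record(s) excluded: zero local richness")
  out <- mean(records$n_genera[ok] / richness[ok]) * 100
  attr(out, "n_excluded") <- sum(!ok)
  out
}
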