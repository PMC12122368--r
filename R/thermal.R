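# Stage 3: bleaching-alert exposure of restored versus control sites and
# projected DHW >= 20 C-weeks exceedance, the mass-mortality proxy.

#' Count bleaching-alert exposure in a window of years
#'
#' Number of event-years (years with at least one recorded alert) for a
#' locality at the given severity or worse, within a window of calendar
#' years. Severity `"I"` counts level-I-or-worse events (levels I and II),
#' `"II"` counts level-II only. Set `count = "events"` to sum the events
#' themselves (a year with several alerts then retains its multiplicity).
#'
#' @param grid A `reef_grid`.
#' @param locality_id Locality id in `grid$localities$id`.
#' @param years Window of calendar years; must lie within alert coverage.
#' @param level `"I"` (or worse) or `"II"`.
#' @param count `"years"` (event-years, default) or `"events"`.
#' @return Integer count.
#' @export
count_alert_events <- function(grid, locality_id, years,
                               level = c("I", "II"),
                               count = c("years", "events")) {
  level <- match.arg(level); count <- match.arg(count)
  if (length(years) > 0 && !all(years %in% grid$alert_years))
    stop(sprintf("window [%s, %s] outside alert coverage (%d-%d)",
                 min(years), max(years), min(grid$alert_years),
                 max(grid$alert_years)), call. = FALSE)
  i <- match(locality_id, grid$localities$id)
  if (is.na(i)) stop("unknown locality id: ", locality_id, call. = FALSE)
  if (length(years) == 0L) return(0L)
  m <- if (level == "I") severe_alerts(grid) else grid$alerts_l2
  v <- m[i, as.character(years)]
  if (count == "years") sum(v >= 1) else as.integer(sum(v))
}

# Localities restored in the five years strictly preceding a target year.
restored_membership <- function(records, target_year, window = 5L) {
  unique(records$locality_id[records$year >= target_year - window &
                             records$year <= target_year - 1L])
}

#' Yearly alert exposure of recently restored versus control sites
#'
#' For each target year, the "restored" group contains localities restored
#' in the preceding five years (membership is rolling: a locality restored
#' in year y counts for target years y+1 to y+5 only) and all remaining
#' localities act as controls. The fraction of each group exposed to at
#' least one alert of each severity that year is computed, then aggregated
#' in bins labelled by their upper boundary (e.g. 1990 = 1986-1990) as mean
#' and s.d. over the member years. Years in which the restored group is
#' empty yield no restored fraction and are excluded from that bin's mean.
#'
#' @param grid A `reef_grid`.
#' @param records `restoration_records`.
#' @param years Target years (default: full alert coverage).
#' @param bin_width Aggregation interval (5 years).
#' @return List with `yearly` (per target year, group and severity) and
#'   `bins` (per bin, group and severity: mean, s.d., n_years).
#' @export
restored_vs_control_fractions <- function(grid, records,
                                          years = grid$alert_years,
                                          bin_width = 5L) {
  if (!all(years %in% grid$alert_years))
    stop("requested years outside alert coverage", call. = FALSE)
  sev1 <- severe_alerts(grid); sev2 <- grid$alerts_l2
  ids <- grid$localities$id
  yearly <- list()
  for (y in years) {
    rest <- intersect(restored_membership(records, y), ids)
    ctrl <- setdiff(ids, rest)
    for (level in c("I", "II")) {
      m <- if (level == "I") sev1 else sev2
      exposed <- m[, as.character(y)] >= 1
      names(exposed) <- ids
      for (group in c("restored", "control")) {
        members <- if (group == "restored") rest else ctrl
        frac <- if (length(members) == 0L) NA_real_
                else mean(exposed[as.character(members)])
        yearly[[length(yearly) + 1L]] <- data.frame(
          year = y, group = group, level = level,
          n_group = length(members), fraction = frac)
      }
    }
  }
  yearly <- do.call(rbind, yearly)
  yearly$bin <- ceiling(yearly$year / bin_width) * bin_width
  dropped <- sum(is.na(yearly$fraction))
  if (dropped > 0)
    message(dropped, " year-group cell(s) undefined (empty group), excluded from bins")
  parts <- split(yearly, list(yearly$bin, yearly$group, yearly$level),
                 drop = TRUE)
  bins <- do.call(rbind, lapply(parts, function(d) {
    v <- d$fraction[!is.na(d$fraction)]
    data.frame(bin = d$bin[1], group = d$group[1], level = d$level[1],
               mean_fraction = if (length(v)) mean(v) else NA_real_,
               sd_fraction = if (length(v) > 1) sd(v) else NA_real_,
               n_years = length(v))
  }))
  rownames(bins) <- NULL
  list(yearly = yearly, bins = bins[order(bins$level, bins$group, bins$bin), ])
}

#' Projected DHW exceedance summaries
#'
#' For each locality, counts the years in `years` whose annual maximum DHW
#' is at or above `threshold_cweeks` (>= 20 C-weeks is the near-complete-
#' mortality proxy) and records the first such year. Group summaries
#' compare restored and non-restored localities.
#'
#' @param grid A `reef_grid` with a DHW matrix.
#' @param threshold_cweeks Exceedance threshold, inclusive (default 20).
#' @param years Projection years (default 2015-2100).
#' @return List with `per_locality` (id, restored, n_exceedance_years,
#'   first_exceedance_year) and `groups` (per group: fraction with >= 1
#'   exceedance, mean/s.d. of counts and of first year).
#' @export
dhw_exceedance <- function(grid, threshold_cweeks = 20,
                           years = grid$dhw_years) {
  if (is.null(grid$dhw)) stop("grid has no DHW series", call. = FALSE)
  if (!all(years %in% grid$dhw_years))
    stop("requested years outside DHW coverage", call. = FALSE)
  m <- grid$dhw[, as.character(years), drop = FALSE]
  exceed <- m >= threshold_cweeks
  n_exc <- rowSums(exceed)
  first <- apply(exceed, 1, function(v) if (any(v)) years[which(v)[1]] else NA_integer_)
  per <- data.frame(id = grid$localities$id,
                    restored = grid$localities$restored,
                    n_exceedance_years = as.integer(n_exc),
                    first_exceedance_year = as.integer(first))
  groups <- do.call(rbind, lapply(c(TRUE, FALSE), function(r) {
    d <- per[per$restored == r, ]
    data.frame(group = if (r) "restored" else "control",
               n = nrow(d),
               fraction_exceeding = mean(d$n_exceedance_years >= 1),
               events_mean = mean(d$n_exceedance_years),
               events_sd = sd(d$n_exceedance_years),
               first_year_mean = mean(d$first_exceedance_year, na.rm = TRUE),
               first_year_sd = sd(d$first_exceedance_year, na.rm = TRUE))
  }))
  list(per_locality = per, groups = groups)
}
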