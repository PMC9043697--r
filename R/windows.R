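#' Enumerate candidate climate windows
#'
#' Candidate windows are contiguous runs of calendar months inside a span
#' that runs from September of the year preceding a focal flight season
#' (index 1) to September of the focal year (index 13).  With the default
#' span and window lengths of one to three months there are exactly 36
#' candidates.
#'
#' @param span_months Number of month slots in the span (default 13,
#'   September of the previous year through September of the focal year).
#' @param max_length Maximum window length in months (default 3).
#' @return A data frame with one row per window: `start_month_index`,
#'   `length_months` and a human-readable `label` such as `"Jan-Feb"`.
#' @export
enumerate_windows <- function(span_months = 13L, max_length = 3L) {
  stopifnot(span_months >= 1L, max_length >= 1L)
  out <- do.call(rbind, lapply(seq_len(max_length), function(len) {
    if (span_months - len + 1L < 1L) return(NULL)
    data.frame(start_month_index = seq_len(span_months - len + 1L),
               length_months = len)
  }))
  out <- out[order(out$start_month_index, out$length_months), , drop = FALSE]
  rownames(out) <- NULL
  out$label <- vapply(seq_len(nrow(out)), function(i) {
    window_label(out$start_month_index[i], out$length_months[i])
  }, character(1))
  out
}

#' Map a window-span index to calendar month and year
#'
#' Index 1 is September of the year before the focal flight season;
#' indices 1--4 (Sep--Dec) therefore belong to `focal_year - 1`, indices
#' 5--13 (Jan--Sep) to `focal_year`.
#'
#' @param start_month_index First slot of the window (1--13).
#' @param length_months Window length in months.
#' @param focal_year Calendar year of the flight season.
#' @return Data frame with columns `year` and `month` (1--12), one row per
#'   month of the window.
#' @export
window_months <- function(start_month_index, length_months, focal_year) {
  idx <- seq(start_month_index, start_month_index + length_months - 1L)
  stopifnot(all(idx >= 1L))
  data.frame(
    year  = ifelse(idx <= 4L, focal_year - 1L, focal_year),
    month = ((idx + 7L) %% 12L) + 1L
  )
}

window_label <- function(start_month_index, length_months) {
  idx <- seq(start_month_index, start_month_index + length_months - 1L)
  mon <- month.abb[((idx + 7L) %% 12L) + 1L]
  if (length(mon) == 1L) mon else paste(mon[1L], mon[length(mon)], sep = "-")
}

#' Calendar months covered by a window (ignoring year)
#' @noRd
window_calendar_months <- function(start_month_index, length_months) {
  idx <- seq(start_month_index, start_month_index + length_months - 1L)
  ((idx + 7L) %% 12L) + 1L
}

#' Vectorized window means for many (site, focal year) pairs
#' @noRd
window_mean_many <- function(temperature, site_ids, focal_years,
                             start_month_index, length_months,
                             element = "tmean") {
  tkey <- paste(temperature$site_id, temperature$year, temperature$month,
                sep = "\r")
  vals <- temperature[[element]]
  idx <- seq(start_month_index, start_month_index + length_months - 1L)
  acc <- matrix(NA_real_, length(site_ids), length(idx))
  for (j in seq_along(idx)) {
    yr <- if (idx[j] <= 4L) focal_years - 1L else focal_years
    mo <- ((idx[j] + 7L) %% 12L) + 1L
    hit <- match(paste(site_ids, yr, mo, sep = "\r"), tkey)
    if (anyNA(hit)) {
      bad <- which(is.na(hit))[1L]
      stop(sprintf("missing temperature for site %s, year %d, month %d",
                   as.character(site_ids[bad]), yr[bad], mo))
    }
    acc[, j] <- vals[hit]
  }
  rowMeans(acc)
}

#' Mean temperature of a climate window
#'
#' Unweighted mean of the monthly values of one temperature element over
#' the window's months, with the September-to-September calendar mapping
#' of [window_months()].
#'
#' @param temperature Data frame with columns `site_id`, `year`, `month`
#'   and the temperature elements (`tmean`, `tmin`, `tmax`).
#' @param site_id Site identifier.
#' @param start_month_index,length_months Window definition.
#' @param focal_year Calendar year of the flight season.
#' @param element Temperature element column to average (default
#'   `"tmean"`).
#' @return Mean temperature in degrees Celsius (length-1 numeric).
#' @export
window_mean_temperature <- function(temperature, site_id, start_month_index,
                                    length_months, focal_year,
                                    element = "tmean") {
  stopifnot(element %in% names(temperature))
  mons <- window_months(start_month_index, length_months, focal_year)
  vals <- numeric(nrow(mons))
  for (i in seq_len(nrow(mons))) {
    hit <- temperature$site_id == site_id &
      temperature$year == mons$year[i] & temperature$month == mons$month[i]
    if (!any(hit)) {
      stop(sprintf("missing temperature for site %s, year %d, month %d",
                   as.character(site_id), mons$year[i], mons$month[i]))
    }
    vals[i] <- temperature[[element]][hit][1L]
  }
  mean(vals)
}
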