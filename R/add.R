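#' Accumulated degree days (ADD)
#'
#' ADD weights elapsed postmortem time by temperature: every 24-hour period
#' contributes its mean Celsius temperature, so two days at 27.5 C
#' contribute 55 degree days. The calculator follows four accrual rules:
#'
#' 1. **Half days.** Placements and swabs both happen around midday, so
#'    every calendar day is treated as two half-days, each worth half the
#'    day's rate. The postmortem clock runs from death-day midday to
#'    sampling-day midday; the first and last days therefore contribute one
#'    half-day each.
#' 2. **Cold storage.** Days between death and placement accrue at a
#'    constant storage temperature (default 3 C) regardless of weather;
#'    the storage period ends at placement-day midday.
#' 3. **Frozen intervals.** Days inside a frozen interval contribute zero,
#'    overriding storage.
#' 4. **Temperature proxy.** Post-placement days use the recorded daily
#'    mean air temperature; negative means are clamped to zero by default
#'    (base-0 thermal accumulation), configurable off.
#'
#' @name add_calculator
NULL

#' Construct a cadaver timeline
#'
#' @param death_date,placement_date `Date`s (or strings coercible to
#'   `Date`), death no later than placement.
#' @param frozen_intervals list of length-2 `Date` vectors, closed day
#'   ranges within `[death_date, placement_date]`.
#' @param storage_temp_c constant storage temperature, Celsius (default 3).
#' @return an object of class `cadaver_timeline`.
#' @export
cadaver_timeline <- function(death_date, placement_date,
                             frozen_intervals = list(),
                             storage_temp_c = 3) {
  death_date <- as.Date(death_date)
  placement_date <- as.Date(placement_date)
  if (death_date > placement_date) {
    stop("death_date must not be after placement_date", call. = FALSE)
  }
  frozen_intervals <- lapply(frozen_intervals, function(iv) {
    iv <- as.Date(iv)
    if (length(iv) != 2L || iv[1] > iv[2]) {
      stop("each frozen interval must be a start/end Date pair", call. = FALSE)
    }
    if (iv[1] < death_date || iv[2] > placement_date) {
      stop("frozen intervals must lie within [death_date, placement_date]",
           call. = FALSE)
    }
    iv
  })
  structure(list(death_date = death_date, placement_date = placement_date,
                 frozen_intervals = frozen_intervals,
                 storage_temp_c = storage_temp_c),
            class = "cadaver_timeline")
}

is_frozen_day <- function(day, timeline) {
  for (iv in timeline$frozen_intervals) {
    if (day >= iv[1] && day <= iv[2]) return(TRUE)
  }
  FALSE
}

# Rate (degree days per full day) in force for one half-day slot.
# `half` is "am" or "pm"; storage ends at placement-day midday.
slot_rate <- function(day, half, timeline, temps, clamp_negative = TRUE) {
  if (is_frozen_day(day, timeline)) return(0)
  in_storage <- day < timeline$placement_date ||
    (day == timeline$placement_date && half == "am")
  if (in_storage) return(timeline$storage_temp_c)
  i <- match(day, temps$date)
  if (is.na(i)) {
    stop("no temperature record for ", format(day),
         " (needed for a post-placement day)", call. = FALSE)
  }
  rate <- temps$mean_c[i]
  if (clamp_negative) rate <- max(rate, 0)
  rate
}

#' Degree-day contribution of one calendar day
#'
#' Sums the half-day slots of `day` that fall inside the postmortem clock
#' (death-day midday to sampling-day midday). A frozen day contributes 0;
#' a full storage day contributes the storage temperature; a full
#' post-placement day contributes its (clamped) daily mean; boundary days
#' contribute one half-day.
#'
#' @param day a `Date` within `[death_date, sample_date]`.
#' @param timeline a [cadaver_timeline()].
#' @param temps daily temperature table, see [read_daily_temperature()].
#' @param sample_date the swab `Date`.
#' @param clamp_negative clamp negative daily means to zero (default TRUE).
#' @return degree days contributed by `day`.
#' @export
daily_contribution <- function(day, timeline, temps, sample_date,
                               clamp_negative = TRUE) {
  day <- as.Date(day); sample_date <- as.Date(sample_date)
  if (day < timeline$death_date || day > sample_date) {
    stop("day outside [death_date, sample_date]", call. = FALSE)
  }
  total <- 0
  if (day > timeline$death_date) {   # morning half included
    total <- total + slot_rate(day, "am", timeline, temps, clamp_negative) / 2
  }
  if (day < sample_date) {           # afternoon half included
    total <- total + slot_rate(day, "pm", timeline, temps, clamp_negative) / 2
  }
  total
}

#' Accumulated degree days at a sampling date
#'
#' Sum of [daily_contribution()] over every day from death to the swab.
#' Nonnegative and nondecreasing in `sample_date`.
#'
#' @inheritParams daily_contribution
#' @return ADD in degree days (Celsius x day).
#' @export
accumulated_degree_days <- function(timeline, temps, sample_date,
                                    clamp_negative = TRUE) {
  sample_date <- as.Date(sample_date)
  if (sample_date < timeline$placement_date) {
    stop("sample_date must be on or after placement_date", call. = FALSE)
  }
  days <- seq(timeline$death_date, sample_date, by = "day")
  sum(vapply(days, daily_contribution, numeric(1), timeline = timeline,
             temps = temps, sample_date = sample_date,
             clamp_negative = clamp_negative))
}

#' Read a daily temperature series
#'
#' CSV with columns `date` (ISO) and `mean_c` (daily mean, Celsius), one
#' record per day.
#'
#' @param path CSV path.
#' @return data frame with `date` (`Date`) and `mean_c` columns.
#' @export
read_daily_temperature <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "mean_c") %in% names(df))) {
    stop("temperature CSV needs columns date, mean_c", call. = FALSE)
  }
  df$date <- as.Date(df$date)
  if (anyDuplicated(df$date)) stop("duplicate temperature dates", call. = FALSE)
  if (any(!is.finite(df$mean_c))) stop("non-finite daily mean", call. = FALSE)
  df[order(df$date), c("date", "mean_c")]
}

#' Read and write cadaver timelines as JSON
#'
#' Fields: `death_date`, `placement_date`, `frozen_intervals` (list of
#' `[start, end]` pairs), `storage_temp_c`.
#'
#' @param path JSON path.
#' @return `read_cadaver_timeline`: a [cadaver_timeline()].
#' @export
read_cadaver_timeline <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fr <- x$frozen_intervals
  if (is.null(fr) || length(fr) == 0) {
    fr <- list()
  } else if (is.matrix(fr)) {
    fr <- lapply(seq_len(nrow(fr)), function(i) fr[i, ])
  }
  cadaver_timeline(x$death_date, x$placement_date, fr,
                   storage_temp_c = if (is.null(x$storage_temp_c)) 3
                                    else x$storage_temp_c)
}

#' @rdname read_cadaver_timeline
#' @param timeline a [cadaver_timeline()].
#' @export
write_cadaver_timeline <- function(timeline, path) {
  x <- list(death_date = format(timeline$death_date),
            placement_date = format(timeline$placement_date),
            frozen_intervals = lapply(timeline$frozen_intervals, format),
            storage_temp_c = timeline$storage_temp_c)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.cadaver_timeline <- function(x, ...) {
  cat("<cadaver_timeline> death ", format(x$death_date), ", placement ",
      format(x$placement_date), ", ", length(x$frozen_intervals),
      " frozen interval(s), storage ", x$storage_temp_c, " C\n", sep = "")
  invisible(x)
}
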