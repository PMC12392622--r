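# Derived environmental parameters from daily weather.

#' Names of the 14 derived environmental parameters
#'
#' DL (day length), GDD (growing degree days), dGDD (day-to-day change in
#' GDD), DTR (diurnal temperature range), PTT (photothermal time, GDD x DL),
#' dPTT (day-to-day change in PTT), PTR (photothermal ratio, GDD / DL),
#' PTD1 (DL x DTR), PTD2 (DL / DTR), TSR (temperature square ratio, MMR^2),
#' MMR (Kelvin minimum-to-maximum temperature ratio), PR (precipitation),
#' RH (relative humidity), PRDTR (precipitation / DTR).
#'
#' @export
env_param_names <- function() {
  c("DL", "GDD", "dGDD", "DTR", "PTT", "dPTT", "PTR",
    "PTD1", "PTD2", "TSR", "MMR", "PR", "RH", "PRDTR")
}

#' Astronomical day length
#'
#' Day length in hours from the solar-declination formula
#' `delta = 23.45 deg * sin(2*pi*(284 + doy)/365)`,
#' `DL = (24/pi) * acos(-tan(lat) * tan(delta))`, with the acos argument
#' clamped to `[-1, 1]` so polar day/night yield 24 h / 0 h instead of NaN.
#'
#' @param latitude Latitude in degrees, in `[-90, 90]`. Recycled against
#'   `day_of_year`.
#' @param day_of_year Day of year, 1--366.
#' @return Day length in hours, in `[0, 24]`.
#' @examples
#' compute_day_length(34.27, 172) # midsummer at ~34 N, > 14 h
#' @export
compute_day_length <- function(latitude, day_of_year) {
  if (any(!is.finite(latitude)) || any(latitude < -90) || any(latitude > 90)) {
    stop("`latitude` must be finite and within [-90, 90]", call. = FALSE)
  }
  if (any(!is.finite(day_of_year)) || any(day_of_year < 1) ||
      any(day_of_year > 366)) {
    stop("`day_of_year` must be within 1..366", call. = FALSE)
  }
  decl <- (23.45 * pi / 180) * sin(2 * pi * (284 + day_of_year) / 365)
  arg <- -tan(latitude * pi / 180) * tan(decl)
  arg <- pmin(1, pmax(-1, arg))
  (24 / pi) * acos(arg)
}

#' Validate a weather table
#'
#' A weather table is a data frame with one row per environment x day:
#' columns `environment`, `latitude` (degrees), `planting_doy` (day of year
#' the crop was sown), `day` (1-based day after planting, contiguous per
#' environment), `tmax`, `tmin` (deg C), `prec` (mm/day), `rh` (%) and
#' optionally `day_length` (hours; computed from latitude and date when
#' absent).
#'
#' @param weather Data frame as described above.
#' @return `weather`, invisibly, after checks.
#' @export
validate_weather <- function(weather) {
  needed <- c("environment", "latitude", "planting_doy", "day",
              "tmax", "tmin", "prec", "rh")
  missing_cols <- setdiff(needed, names(weather))
  if (length(missing_cols)) {
    stop("weather table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (env in unique(weather$environment)) {
    d <- sort(weather$day[weather$environment == env])
    if (d[1] != 1L || any(diff(d) != 1L)) {
      stop("days must be contiguous from 1 in environment ", env,
           call. = FALSE)
    }
  }
  if (any(weather$tmax < weather$tmin)) {
    stop("tmax < tmin found in weather table", call. = FALSE)
  }
  if (any(weather$rh < 0 | weather$rh > 100)) {
    stop("rh must lie in [0, 100]", call. = FALSE)
  }
  if (any(weather$prec < 0)) {
    stop("precipitation must be non-negative", call. = FALSE)
  }
  invisible(weather)
}

#' Default daily formula registry for the 14 environmental parameters
#'
#' Each entry is a function of a single-environment daily weather data frame
#' (columns `tmax`, `tmin`, `prec`, `rh`, `day_length`, ordered by day)
#' returning one value per day. Divisions are guarded so no entry can
#' produce NaN or Inf: photothermal ratios return 0 when day length is 0,
#' and DTR denominators are floored at `eps`. Temperature ratios use Kelvin
#' so they stay positive. Entries can be replaced wholesale to swap in
#' alternative definitions without touching the pipeline.
#'
#' @param tbase Base temperature for growing degree days (deg C).
#' @param tcap Cap on daily maximum temperature for GDD (deg C).
#' @param eps Floor for DTR denominators (deg C).
#' @return Named list of 14 daily formulas, with a `requires` attribute per
#'   entry naming the weather columns it consumes.
#' @export
default_formula_registry <- function(tbase = 0, tcap = 30, eps = 0.1) {
  gdd <- function(w) {
    pmax(0, (pmin(w$tmax, tcap) + pmax(w$tmin, tbase)) / 2 - tbase)
  }
  need <- function(f, cols) {
    attr(f, "requires") <- cols
    f
  }
  tt <- c("tmax", "tmin")
  list(
    DL    = need(function(w) w$day_length, "day_length"),
    GDD   = need(gdd, tt),
    dGDD  = need(function(w) c(0, diff(gdd(w))), tt),
    DTR   = need(function(w) w$tmax - w$tmin, tt),
    PTT   = need(function(w) gdd(w) * w$day_length, c(tt, "day_length")),
    dPTT  = need(function(w) c(0, diff(gdd(w) * w$day_length)),
                 c(tt, "day_length")),
    PTR   = need(function(w) ifelse(w$day_length > 0,
                                    gdd(w) / w$day_length, 0),
                 c(tt, "day_length")),
    PTD1  = need(function(w) w$day_length * (w$tmax - w$tmin),
                 c(tt, "day_length")),
    PTD2  = need(function(w) w$day_length / pmax(w$tmax - w$tmin, eps),
                 c(tt, "day_length")),
    TSR   = need(function(w) ((w$tmin + 273.15) / (w$tmax + 273.15))^2, tt),
    MMR   = need(function(w) (w$tmin + 273.15) / (w$tmax + 273.15), tt),
    PR    = need(function(w) w$prec, "prec"),
    RH    = need(function(w) w$rh, "rh"),
    PRDTR = need(function(w) w$prec / pmax(w$tmax - w$tmin, eps),
                 c("prec", tt))
  )
}

#' Derive the environmental-parameter cube from daily weather
#'
#' Applies every registered daily formula to each environment's weather
#' series, yielding an environment x parameter x day array. If `day_length`
#' is absent it is computed from latitude, planting day-of-year and day
#' after planting; a supplied `day_length` column takes precedence.
#'
#' @param weather Weather table (see [validate_weather()]).
#' @param registry Named list of daily formulas; defaults to
#'   [default_formula_registry()].
#' @return An `env_param_cube`: numeric array with dims (environment,
#'   parameter, day) and dimnames.
#' @export
derive_parameters <- function(weather, registry = default_formula_registry()) {
  validate_weather(weather)
  envs <- unique(as.character(weather$environment))
  n_day <- max(weather$day)
  params <- names(registry)
  cube <- array(
    NA_real_, dim = c(length(envs), length(params), n_day),
    dimnames = list(environment = envs, parameter = params, day = NULL)
  )
  for (env in envs) {
    w <- weather[weather$environment == env, , drop = FALSE]
    w <- w[order(w$day), , drop = FALSE]
    if (is.null(w$day_length) || all(is.na(w$day_length))) {
      doy <- (w$planting_doy[1] + w$day - 2) %% 365 + 1
      w$day_length <- compute_day_length(w$latitude[1], doy)
    }
    for (p in params) {
      f <- registry[[p]]
      req <- attr(f, "requires")
      if (!is.null(req)) {
        absent <- setdiff(req, names(w))
        if (length(absent)) {
          stop("parameter ", p, " requires missing weather variable(s): ",
               paste(absent, collapse = ", "), call. = FALSE)
        }
      }
      v <- f(w)
      if (length(v) != nrow(w) || any(!is.finite(v))) {
        stop("formula for parameter ", p,
             " returned non-finite or wrong-length values", call. = FALSE)
      }
      cube[env, p, seq_len(nrow(w))] <- v
    }
  }
  class(cube) <- c("env_param_cube", class(cube))
  cube
}

#' Mean of one environmental parameter over a growth window
#'
#' Arithmetic mean of the daily values over the closed day interval
#' `[start, end]` (both ends included, so the window 147--154 spans 8 days),
#' per environment.
#'
#' @param cube An `env_param_cube` from [derive_parameters()].
#' @param parameter One of [env_param_names()] (or any registered name).
#' @param start,end First and last day after planting of the window,
#'   1-based, inclusive.
#' @return Named numeric vector of window means, ordered as the cube's
#'   environments.
#' @export
window_mean <- function(cube, parameter, start, end) {
  if (!parameter %in% dimnames(cube)$parameter) {
    stop("unknown parameter: ", parameter, call. = FALSE)
  }
  n_day <- dim(cube)[3]
  if (start < 1 || end > n_day || start > end) {
    stop("window [", start, ", ", end, "] outside available days 1..",
         n_day, call. = FALSE)
  }
  slab <- cube[, parameter, start:end, drop = FALSE]
  out <- apply(slab, 1, mean)
  names(out) <- dimnames(cube)$environment
  out
}

#' Write / read an environmental-parameter cube as long-format CSV
#'
#' Columns: environment, parameter, day, value.
#'
#' @param cube An `env_param_cube`.
#' @param path File path.
#' @return `write_cube_csv()` returns `path` invisibly; `read_cube_csv()`
#'   returns an `env_param_cube`.
#' @export
write_cube_csv <- function(cube, path) {
  dn <- dimnames(cube)
  long <- expand.grid(
    environment = dn$environment, parameter = dn$parameter,
    day = seq_len(dim(cube)[3]),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  long$value <- as.vector(cube)
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cube_csv
#' @export
read_cube_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  envs <- unique(long$environment)
  params <- unique(long$parameter)
  days <- sort(unique(long$day))
  cube <- array(
    NA_real_, dim = c(length(envs), length(params), length(days)),
    dimnames = list(environment = envs, parameter = params, day = NULL)
  )
  idx <- cbind(match(long$environment, envs), match(long$parameter, params),
               match(long$day, days))
  cube[idx] <- long$value
  class(cube) <- c("env_param_cube", class(cube))
  cube
}
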