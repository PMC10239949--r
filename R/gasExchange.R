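#' Gas-exchange configuration
#'
#' @param patm mean atmospheric pressure, mmHg (default 760).
#' @param respiratoryQuotient assumed respiratory quotient (default 0.8).
#' @param svpOverride optional fixed saturated water vapour pressure in
#'   mmHg. By default the vapour pressure is computed from each record's
#'   own body temperature; supply e.g. 52 to use a single fixed value
#'   throughout.
#' @return list of class \code{"gasExchangeConfig"}.
#' @export
gasExchangeConfig <- function(patm = 760, respiratoryQuotient = 0.8,
                              svpOverride = NULL) {
  stopIfNot(patm > 0, "patm must be > 0")
  stopIfNot(respiratoryQuotient > 0, "respiratory quotient must be > 0")
  structure(list(patm = patm, rq = respiratoryQuotient,
                 svpOverride = svpOverride),
            class = "gasExchangeConfig")
}

#' Saturated water vapour pressure at body temperature
#'
#' Buck (1981) formulation for vapour pressure over liquid water,
#' converted from hPa to mmHg. Monotone increasing in temperature; rounds
#' to 52 mmHg at a lamb body temperature of 39 degrees C.
#'
#' @param temperature body temperature in degrees C, within [30, 45].
#' @return vapour pressure in mmHg (vectorised).
#' @export
svpMmHg <- function(temperature) {
  stopIfNot(all(is.finite(temperature)) &&
              all(temperature >= 30 & temperature <= 45),
            "temperature must lie in [30, 45] degrees C")
  hpa <- 6.1121 * exp(17.502 * temperature / (240.97 + temperature))
  hpa / 1.3332239
}

validateBloodGas <- function(bg) {
  err <- function(m) stop("invalid blood-gas record: ", m, call. = FALSE)
  need <- c("fio2", "pao2", "paco2", "temp_c")
  if (!all(need %in% names(bg))) err(paste("missing columns:",
      paste(setdiff(need, names(bg)), collapse = ", ")))
  if (any(!is.finite(bg$pao2)) || any(bg$pao2 <= 0) ||
      any(!is.finite(bg$paco2)) || any(bg$paco2 <= 0))
    err("partial pressures must be positive")
  if (any(bg$fio2 < 0.21 - 1e-9) || any(bg$fio2 > 1 + 1e-9))
    err("fio2 must lie in [0.21, 1]")
  if (any(bg$temp_c < 30) || any(bg$temp_c > 45))
    err("temperature must lie in [30, 45]")
  invisible(bg)
}

#' Alveolar-arterial oxygen difference
#'
#' \code{AaDO2 = FiO2 * (Patm - P_H2O) - PaCO2 / RQ - PaO2}, with all
#' pressures in mmHg. \code{P_H2O} is the saturated water vapour pressure
#' at the record's body temperature (or a fixed override from the
#' configuration). Negative values, which measurement noise can produce,
#' are returned as computed with a warning rather than clipped.
#'
#' @param bg a blood-gas record: data.frame (or coercible list) with
#'   columns \code{fio2}, \code{pao2}, \code{paco2}, \code{temp_c}.
#' @param cfg a \code{\link{gasExchangeConfig}}.
#' @return AaDO2 in mmHg (vectorised over rows).
#' @export
aado2 <- function(bg, cfg = gasExchangeConfig()) {
  bg <- as.data.frame(bg)
  validateBloodGas(bg)
  svp <- cfg$svpOverride %||% svpMmHg(bg$temp_c)
  val <- bg$fio2 * (cfg$patm - svp) - bg$paco2 / cfg$rq - bg$pao2
  if (any(val < 0))
    warning("negative AaDO2 value(s) returned as computed", call. = FALSE)
  val
}

#' AaDO2 over a time-sorted series of blood-gas records
#'
#' @param records data.frame of blood-gas rows with a \code{time_min}
#'   column, sorted by time.
#' @param cfg a \code{\link{gasExchangeConfig}}.
#' @return data.frame \code{time_min, aado2, negative} (negative values
#'   flagged, not clipped). Empty input returns an empty frame.
#' @export
aado2Series <- function(records, cfg = gasExchangeConfig()) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L)
    return(data.frame(time_min = numeric(), aado2 = numeric(),
                      negative = logical()))
  stopIfNot("time_min" %in% names(records), "records need a time_min column")
  if (is.unsorted(records$time_min, strictly = FALSE))
    stop("records must be sorted by time", call. = FALSE)
  val <- suppressWarnings(aado2(records, cfg))
  if (any(val < 0))
    warning("negative AaDO2 value(s) flagged in series", call. = FALSE)
  data.frame(time_min = records$time_min, aado2 = val, negative = val < 0)
}
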