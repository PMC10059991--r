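#' Read an Ohio-style CGM XML file
#'
#' Parses the XML dialect of the OhioT1DM continuous-glucose-monitoring
#' releases: a `<patient>` root holding `<glucose_level>`, `<bolus>`,
#' `<basal>` and `<meal>` blocks of `<event>` elements.  Glucose values are
#' converted to the package's canonical unit, mmol/L (division by exactly
#' 18 when the source is mg/dL); bolus doses to mU; basal rates to mU/min.
#' Timestamps become integer minutes from the first glucose reading,
#' snapped to the sampling grid, and insulin/meal events are aligned to the
#' closest available glucose reading time ([align_events()]).
#'
#' The source schema does not declare units, so they are explicit
#' arguments rather than silent guesses.  The original units are recorded
#' in the returned object's `units` attribute.  OhioT1DM distributes
#' training and testing portions as separate files; the whole file is
#' tagged with the given `split`, and [assign_split()] is deliberately not
#' applied.
#'
#' @param path XML file path.
#' @param split Split tag for every timestamp (`"train"` or `"test"`).
#' @param delta_t Sampling interval, minutes (default 5).
#' @param units_glucose `"mg/dL"` (default) or `"mmol/L"`.
#' @param units_bolus `"U"` (default; converted to mU) or `"mU"`.
#' @param units_basal `"U/hr"` (default; converted to mU/min) or `"mU/min"`.
#' @return A [patient_series()].
#' @export
read_ohio_xml <- function(path, split = "train", delta_t = 5,
                          units_glucose = c("mg/dL", "mmol/L"),
                          units_bolus = c("U", "mU"),
                          units_basal = c("U/hr", "mU/min")) {
  units_glucose <- match.arg(units_glucose)
  units_bolus <- match.arg(units_bolus)
  units_basal <- match.arg(units_basal)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed XML in ", path, ": ", conditionMessage(e), call. = FALSE))
  glu <- xml2::xml_find_all(doc, ".//glucose_level/event")
  if (length(glu) == 0L)
    stop("no <glucose_level> events in ", path, call. = FALSE)
  ts_raw <- xml2::xml_attr(glu, "ts")
  val <- suppressWarnings(as.numeric(xml2::xml_attr(glu, "value")))
  if (anyNA(val))
    stop("non-numeric glucose value in <glucose_level> event", call. = FALSE)
  t0 <- .ohio_time(ts_raw[1])
  tmin <- vapply(ts_raw, function(s) .ohio_time(s) - t0, numeric(1L),
                 USE.NAMES = FALSE)
  tg <- round(tmin / delta_t) * delta_t
  keep <- !duplicated(tg)
  tg <- tg[keep]; val <- val[keep]
  if (units_glucose == "mg/dL") val <- mgdl_to_mmoll(val)

  get_events <- function(xpath, value_attrs, kind, ts_attrs = c("ts", "ts_begin")) {
    nodes <- xml2::xml_find_all(doc, xpath)
    if (length(nodes) == 0L)
      return(data.frame(timestamp = numeric(), kind = character(),
                        value = numeric(), stringsAsFactors = FALSE))
    ts <- rep(NA_character_, length(nodes))
    for (a in ts_attrs) {
      miss <- is.na(ts)
      ts[miss] <- xml2::xml_attr(nodes[miss], a)
    }
    v <- rep(NA_real_, length(nodes))
    for (a in value_attrs) {
      miss <- is.na(v)
      v[miss] <- suppressWarnings(as.numeric(xml2::xml_attr(nodes[miss], a)))
    }
    if (anyNA(ts) || anyNA(v))
      stop("missing ts/value attribute in <", kind, "> event", call. = FALSE)
    tm <- vapply(ts, function(s) .ohio_time(s) - t0, numeric(1L),
                 USE.NAMES = FALSE)
    data.frame(timestamp = tm, kind = kind, value = v,
               stringsAsFactors = FALSE)
  }
  bol <- get_events(".//bolus/event", c("dose", "value"), "bolus")
  bas <- get_events(".//basal/event", c("value", "dose"), "basal")
  meal <- get_events(".//meal/event", c("carbs", "value"), "meal")
  if (units_bolus == "U") bol$value <- bol$value * 1000
  if (units_basal == "U/hr") bas$value <- bas$value * 1000 / 60

  ev <- rbind(bol, bas, meal)
  ev <- align_events(ev, tg)

  grid_t <- seq(min(tg), max(tg), by = delta_t)
  glucose <- rep(NA_real_, length(grid_t))
  glucose[match(tg, grid_t)] <- val
  bolus <- meal_g <- numeric(length(grid_t))
  basal <- numeric(length(grid_t))
  for (i in seq_len(nrow(ev))) {
    j <- match(ev$timestamp[i], grid_t)
    switch(ev$kind[i],
           bolus = bolus[j] <- bolus[j] + ev$value[i],
           meal = meal_g[j] <- meal_g[j] + ev$value[i],
           basal = basal[j:length(basal)] <- ev$value[i])
  }
  s <- patient_series(
    patient_id = xml2::xml_attr(xml2::xml_root(doc), "id"),
    grid = data.frame(t = grid_t, glucose = glucose, bolus = bolus,
                      basal = basal, meal = meal_g, split = split,
                      stringsAsFactors = FALSE),
    delta_t = delta_t)
  attr(s, "units") <- c(glucose = units_glucose, bolus = units_bolus,
                        basal = units_basal)
  s
}

# Accepts either plain minutes or the "dd-mm-yyyy hh:mm:ss" stamps of the
# Ohio releases; returns minutes as a numeric.
.ohio_time <- function(s) {
  x <- suppressWarnings(as.numeric(s))
  if (!is.na(x)) return(x)
  p <- as.POSIXct(s, format = "%d-%m-%Y %H:%M:%S", tz = "UTC")
  if (is.na(p))
    stop("unparseable timestamp '", s, "' (want minutes or dd-mm-yyyy hh:mm:ss)",
         call. = FALSE)
  as.numeric(p) / 60
}
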