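#' Construct a patient series
#'
#' The canonical per-patient container: a regular 5-minute grid holding the
#' CGM glucose trace (mmol/L, `NA` = missing reading) together with insulin
#' boluses (mU, impulse at their grid time), the basal infusion rate
#' (mU/min, piecewise constant, recorded per grid row) and meal
#' carbohydrates (g).  Timestamps are integer minutes from the series
#' start; no calendar dates are kept.
#'
#' @param patient_id Identifier string.
#' @param grid Data frame with columns `t`, `glucose`, `bolus`, `basal`,
#'   `meal`, `split` (`"train"`/`"test"`).
#' @param delta_t Sampling interval in minutes (default 5).
#' @return Object of class `"patient_series"`.
#' @export
patient_series <- function(patient_id, grid, delta_t = 5) {
  need <- c("t", "glucose", "bolus", "basal", "meal", "split")
  if (!all(need %in% names(grid)))
    stop("grid must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  grid <- grid[order(grid$t), need]
  rownames(grid) <- NULL
  if (any(diff(grid$t) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (any(grid$t %% delta_t != 0))
    stop("timestamps must be multiples of delta_t", call. = FALSE)
  if (!all(grid$split %in% c("train", "test")))
    stop("split tags must be 'train' or 'test'", call. = FALSE)
  if (any(which(grid$split == "test") < max(0L, which(grid$split == "train"))))
    stop("all train timestamps must precede test timestamps", call. = FALSE)
  structure(list(patient_id = as.character(patient_id),
                 delta_t = delta_t, grid = grid),
            class = "patient_series")
}

#' @export
print.patient_series <- function(x, ...) {
  g <- x$grid
  cat(sprintf(
    "patient_series '%s': %d points @ %g min (%.1f days), %d missing\n",
    x$patient_id, nrow(g), x$delta_t, nrow(g) * x$delta_t / 1440,
    sum(is.na(g$glucose))))
  cat(sprintf("  boluses %d, meals %d, train %d / test %d\n",
              sum(g$bolus > 0), sum(g$meal > 0),
              sum(g$split == "train"), sum(g$split == "test")))
  invisible(x)
}

#' Extract event records from a patient series
#'
#' @param series A [patient_series()].
#' @param kinds Which kinds to extract (`"bolus"`, `"basal"`, `"meal"`).
#' @return Data frame with columns `timestamp`, `kind`, `value`; basal
#'   events mark rate changes (run-length encoded).
#' @export
series_events <- function(series, kinds = c("bolus", "basal", "meal")) {
  g <- series$grid
  out <- list()
  if ("bolus" %in% kinds && any(g$bolus > 0)) {
    i <- which(g$bolus > 0)
    out$bolus <- data.frame(timestamp = g$t[i], kind = "bolus",
                            value = g$bolus[i], stringsAsFactors = FALSE)
  }
  if ("basal" %in% kinds) {
    r <- rle(g$basal)
    start <- cumsum(c(1L, head(r$lengths, -1L)))
    keep <- r$values > 0 | seq_along(r$values) > 1L  # record changes incl. to 0
    if (any(keep))
      out$basal <- data.frame(timestamp = g$t[start[keep]], kind = "basal",
                              value = r$values[keep], stringsAsFactors = FALSE)
  }
  if ("meal" %in% kinds && any(g$meal > 0)) {
    i <- which(g$meal > 0)
    out$meal <- data.frame(timestamp = g$t[i], kind = "meal",
                           value = g$meal[i], stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(timestamp = numeric(), kind = character(),
                      value = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$timestamp), ]
}

#' Synthetic cohort configuration
#'
#' Defines the study conditions the generator emulates: a 5-minute CGM grid,
#' glucose confined to \[2, 25\] mmol/L, Poisson meal schedules with boluses
#' dosed by a per-patient carbohydrate ratio, a constant basal rate, missing
#' readings, and the strong class imbalance of real CGM cohorts (the two
#' hypoglycemic bands jointly rare).  Per-patient dynamics coefficients are
#' drawn from the configured ranges so that patients are distinct but
#' related learning tasks.
#'
#' Glucose evolves on the grid as
#' `G(t+dt) = G(t) + alpha*C(t) - beta*I(t) + gamma*(G_b - G(t)) + noise`,
#' clipped to \[2, 25\], where `I` and `C` are the absorption signals.
#'
#' @param n_patients Number of patients.
#' @param days Duration per patient in days.
#' @param seed Integer; fixes the whole cohort deterministically.
#' @param basal_glucose Glycemic set point `G_b` in mmol/L; a length-2
#'   vector draws one set point per patient (subjects differ in their
#'   resting glycemia, which is what spreads band occupancy across the
#'   cohort).
#' @param meal_rate Expected meals per day (Poisson).
#' @param carb_range Meal size range in grams.
#' @param carb_ratio_range Per-patient grams of carbohydrate covered by one
#'   mU of bolus signal input (dose = carbs / ratio).
#' @param dose_noise_range Per-meal multiplicative dosing error (patients
#'   estimate meal carbohydrates imperfectly); under- and overdosing is
#'   what produces the occasional hyper- and hypoglycemic excursions.
#' @param basal_rate_range Per-patient basal infusion rate, mU/min.
#' @param alpha_range,beta_range,gamma_range Ranges of the carbohydrate
#'   gain (mmol/L per g of absorbed carb per step), insulin gain (mmol/L
#'   per mU/L per step) and mean-reversion rate (per step).
#' @param noise_sd Per-step glucose noise, mmol/L.
#' @param missing_rate Fraction of glucose readings dropped at random.
#' @param test_fraction Chronological test fraction (see [assign_split()]).
#' @param params [absorption_params()] used for the signals.
#' @return List of class `"cohort_config"`.
#' @export
cohort_config <- function(n_patients = 6, days = 2, seed = 20230101,
                          basal_glucose = c(6, 10.5), meal_rate = 3,
                          carb_range = c(20, 100),
                          carb_ratio_range = c(5.5, 8),
                          dose_noise_range = c(0.55, 1.35),
                          basal_rate_range = c(0.005, 0.02),
                          alpha_range = c(0.45, 0.7),
                          beta_range = c(0.03, 0.05),
                          gamma_range = c(0.015, 0.035),
                          noise_sd = 0.2, missing_rate = 0.03,
                          test_fraction = 0.25,
                          params = absorption_params()) {
  cfg <- list(n_patients = n_patients, days = days, seed = as.integer(seed),
              basal_glucose = basal_glucose, meal_rate = meal_rate,
              carb_range = carb_range, carb_ratio_range = carb_ratio_range,
              dose_noise_range = dose_noise_range,
              basal_rate_range = basal_rate_range, alpha_range = alpha_range,
              beta_range = beta_range, gamma_range = gamma_range,
              noise_sd = noise_sd, missing_rate = missing_rate,
              test_fraction = test_fraction, params = params)
  num <- unlist(cfg[setdiff(names(cfg), "params")])
  if (any(!is.finite(num)))
    stop("cohort configuration contains non-finite values", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1 || meal_rate < 0 ||
      noise_sd < 0 || days <= 0 || n_patients < 1)
    stop("cohort configuration out of range", call. = FALSE)
  structure(cfg, class = "cohort_config")
}

# run `expr` under a private RNG stream; restores the caller's stream
with_private_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate one synthetic patient
#'
#' Deterministic given `(config$seed, patient_index)`.  See
#' [cohort_config()] for the dynamics.
#'
#' @param config A [cohort_config()].
#' @param patient_index Integer in `1:config$n_patients`.
#' @return A [patient_series()] with id `sim<index>`.
#' @export
simulate_patient <- function(config, patient_index) {
  stopifnot(inherits(config, "cohort_config"))
  seed_i <- (config$seed + 7919L * as.integer(patient_index)) %%
    .Machine$integer.max
  with_private_seed(seed_i, .simulate_patient_impl(config, patient_index))
}

.draw <- function(range) if (length(range) == 1L) range else
  runif(1, range[1], range[2])

.simulate_patient_impl <- function(config, patient_index) {
  n <- as.integer(round(config$days * 288))
  dt <- 5
  grid_t <- (seq_len(n) - 1L) * dt
  # per-patient physiology
  alpha <- .draw(config$alpha_range)
  beta <- .draw(config$beta_range)
  gamma <- .draw(config$gamma_range)
  ratio <- .draw(config$carb_ratio_range)
  basal_rate <- .draw(config$basal_rate_range)
  g_b <- .draw(config$basal_glucose)
  # meal schedule: Poisson count per day, uniform times snapped to the
  # grid, thinned to at least 90 min apart (meals are discrete sittings)
  meal <- numeric(n); bolus <- numeric(n)
  last_meal <- -Inf
  for (day in seq_len(ceiling(config$days))) {
    k <- rpois(1, config$meal_rate)
    if (k == 0) next
    tt <- sort(runif(k, (day - 1) * 1440, min(day * 1440, n * dt - dt)))
    keep <- logical(length(tt))
    for (j in seq_along(tt)) {
      if (tt[j] - last_meal >= 90) { keep[j] <- TRUE; last_meal <- tt[j] }
    }
    tt <- tt[keep]; k <- length(tt)
    if (k == 0) next
    idx <- pmin(n, round(tt / dt) + 1L)
    carbs <- runif(k, config$carb_range[1], config$carb_range[2])
    derr <- runif(k, config$dose_noise_range[1], config$dose_noise_range[2])
    for (j in seq_len(k)) {
      meal[idx[j]] <- meal[idx[j]] + carbs[j]
      # pump-style cap on a single bolus keeps plasma insulin in the
      # physiological [0, 10] mU/L range even for overlapping meals
      bolus[idx[j]] <- min(18, bolus[idx[j]] + derr[j] * carbs[j] / ratio)
    }
  }
  ev_ins <- data.frame(
    timestamp = c(grid_t[bolus > 0], 0),
    kind = c(rep("bolus", sum(bolus > 0)), "basal"),
    value = c(bolus[bolus > 0], basal_rate), stringsAsFactors = FALSE)
  ev_meal <- data.frame(timestamp = grid_t[meal > 0],
                        kind = rep("meal", sum(meal > 0)),
                        value = meal[meal > 0], stringsAsFactors = FALSE)
  I <- insulin_signal(ev_ins, config$params, grid_t)
  C <- carb_signal(ev_meal, config$params, grid_t)
  noise <- if (config$noise_sd > 0) rnorm(n, 0, config$noise_sd) else numeric(n)
  G <- numeric(n)
  G[1] <- g_b
  for (i in seq_len(n - 1L)) {
    G[i + 1L] <- G[i] + alpha * C[i] - beta * I[i] +
      gamma * (g_b - G[i]) + noise[i]
    G[i + 1L] <- min(25, max(2, G[i + 1L]))
  }
  if (config$missing_rate > 0) {
    drop <- runif(n) < config$missing_rate
    G[drop] <- NA_real_
  }
  grid <- data.frame(t = grid_t, glucose = G, bolus = bolus,
                     basal = basal_rate, meal = meal,
                     split = "train", stringsAsFactors = FALSE)
  s <- patient_series(paste0("sim", patient_index), grid, delta_t = dt)
  assign_split(s, config$test_fraction)
}

#' Simulate a cohort of synthetic patients
#'
#' @param config A [cohort_config()].
#' @return List of [patient_series()], length `config$n_patients`.
#' @export
simulate_cohort <- function(config) {
  lapply(seq_len(config$n_patients), function(i) simulate_patient(config, i))
}

#' Chronological train/test split
#'
#' The final `test_fraction` of the time span is tagged `test`, the rest
#' `train`; no shuffling.  With an odd count at fraction 0.5 the test side
#' is larger by one (the train size is floored).
#'
#' @param series A [patient_series()].
#' @param test_fraction Fraction in (0, 1).
#' @return The series with updated split tags.
#' @export
assign_split <- function(series, test_fraction) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stop("`test_fraction` must be in (0, 1)", call. = FALSE)
  n <- nrow(series$grid)
  n_train <- floor(n * (1 - test_fraction))
  series$grid$split <- rep(c("train", "test"), c(n_train, n - n_train))
  series
}

#' Write / read the internal per-patient CSV format
#'
#' One row per grid timestamp with columns `t, glucose, bolus, basal, meal,
#' split`; missing glucose is an empty field.  A single comment line keeps
#' the patient id and sampling interval so that
#' `read_patient_csv(write_patient_csv(s, f))` is the identity.
#'
#' @param series A [patient_series()].
#' @param path File path.
#' @return `write_patient_csv` returns `path` invisibly; `read_patient_csv`
#'   returns a [patient_series()].
#' @export
write_patient_csv <- function(series, path) {
  stopifnot(inherits(series, "patient_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# patient_series id=%s delta_t=%g",
                     series$patient_id, series$delta_t), con)
  write.csv(series$grid, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_patient_csv
#' @export
read_patient_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("^# patient_series id=(\\S+) delta_t=(\\S+)$",
                               hdr))[[1]]
  if (length(m) != 3L)
    stop("not an internal patient CSV (bad header): ", path, call. = FALSE)
  g <- read.csv(path, skip = 1L, stringsAsFactors = FALSE,
                colClasses = c(t = "numeric", glucose = "numeric",
                               bolus = "numeric", basal = "numeric",
                               meal = "numeric", split = "character"))
  patient_series(m[2], g, delta_t = as.numeric(m[3]))
}
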