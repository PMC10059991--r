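#' Hovorka-type absorption parameters
#'
#' Constants of the insulin two-compartment absorption chain and the gut
#' carbohydrate absorption kernel.
#'
#' @param t_max_I Time-to-maximum insulin absorption, minutes (default 55).
#' @param k_e Fractional elimination rate of plasma insulin, 1/min
#'   (default 0.138).
#' @param V_I Insulin distribution volume, L/kg (default 0.12).
#' @param t_max Time-of-maximum glucose appearance rate after a meal,
#'   minutes (default 40).
#' @param A_g Carbohydrate bioavailability, dimensionless in (0, 1\]
#'   (default 0.8).
#' @param weight Body weight in kg used to scale `V_I`; the default 1
#'   treats doses and concentrations as per-kg quantities, which only fixes
#'   the covariate scale seen by the evolved models.
#' @return A list of class `"absorption_params"`.
#' @export
absorption_params <- function(t_max_I = 55, k_e = 0.138, V_I = 0.12,
                              t_max = 40, A_g = 0.8, weight = 1) {
  p <- list(t_max_I = t_max_I, k_e = k_e, V_I = V_I, t_max = t_max,
            A_g = A_g, weight = weight)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1L &&
                    is.finite(x) && x > 0, logical(1L))))
    stop("all absorption parameters must be finite positive scalars",
         call. = FALSE)
  if (A_g > 1) stop("`A_g` must not exceed 1", call. = FALSE)
  structure(p, class = "absorption_params")
}

# Exact one-step transition of the linear insulin system
#   dS1/dt = U - S1/t_max_I
#   dS2/dt = (S1 - S2)/t_max_I
#   dI/dt  = S2/(V_I t_max_I) - k_e I
# over a step of `dt` minutes with piecewise-constant infusion U:
#   x(t+dt) = Phi x(t) + Gamma U,  Phi = expm(A dt), Gamma = A^-1(Phi - I)B.
.insulin_stepper <- function(params, dt) {
  a <- 1 / params$t_max_I
  b <- 1 / (params$V_I * params$weight * params$t_max_I)
  A <- matrix(c(-a, 0, 0,
                a, -a, 0,
                0, b, -params$k_e), nrow = 3, byrow = TRUE)
  Phi <- as.matrix(Matrix::expm(A * dt))
  Gamma <- solve(A, (Phi - diag(3)) %*% c(1, 0, 0))
  list(Phi = Phi, Gamma = as.numeric(Gamma))
}

#' Plasma insulin concentration from dosing events
#'
#' Integrates the two-compartment subcutaneous absorption chain plus plasma
#' elimination on the CGM grid.  Boluses enter as instantaneous additions
#' to the first compartment; basal rates as a piecewise-constant infusion.
#' The system is linear, so the per-step update is computed exactly from
#' the matrix exponential (no integration step-size error) and
#' superposition over events holds to floating precision.
#'
#' @param insulin_events Data frame with columns `timestamp` (minutes, on
#'   the grid), `kind` (`"bolus"` or `"basal"`) and `value` (bolus: dose in
#'   mU; basal: rate in mU/min that holds from its timestamp until the next
#'   basal event).  May have zero rows.
#' @param params An [absorption_params()] object.
#' @param grid Increasing vector of equally spaced timestamps (minutes).
#' @return Numeric vector `I(t)` (mU/L) on `grid`.
#' @export
insulin_signal <- function(insulin_events, params = absorption_params(),
                           grid) {
  ev <- .check_events(insulin_events, c("bolus", "basal"))
  n <- length(grid)
  if (n < 1L) stop("empty grid", call. = FALSE)
  dt <- if (n > 1L) grid[2] - grid[1] else 5
  st <- .insulin_stepper(params, dt)
  # basal rate per grid point (last basal event at or before t; 0 before any)
  U <- numeric(n)
  bas <- ev[ev$kind == "basal", , drop = FALSE]
  if (nrow(bas) > 0L) {
    bas <- bas[order(bas$timestamp), , drop = FALSE]
    idx <- findInterval(grid, bas$timestamp)
    U[idx > 0L] <- bas$value[idx[idx > 0L]]
  }
  bol <- numeric(n)
  bb <- ev[ev$kind == "bolus", , drop = FALSE]
  if (nrow(bb) > 0L) {
    pos <- match(bb$timestamp, grid)
    if (anyNA(pos))
      stop("bolus timestamps must lie on the grid (align events first)",
           call. = FALSE)
    for (i in seq_len(nrow(bb))) bol[pos[i]] <- bol[pos[i]] + bb$value[i]
  }
  x <- c(0, 0, 0)
  I <- numeric(n)
  for (i in seq_len(n)) {
    x[1] <- x[1] + bol[i]          # impulse into S1 at its grid time
    I[i] <- x[3]
    if (i < n) x <- st$Phi %*% x + st$Gamma * U[i]
  }
  pmax(I, 0)
}

#' Gut carbohydrate absorption signal from meal events
#'
#' Each meal of `Dg` grams at time `t0` contributes
#' `Dg * A_g * (t - t0) * exp(-(t - t0)/t_max) / t_max^2` for `t >= t0`
#' and zero before; overlapping meals superpose.  The kernel peaks at lag
#' `t_max` with value `Dg * A_g / (t_max * e)` and integrates to
#' `Dg * A_g` over an infinite horizon.
#'
#' @param meal_events Data frame with columns `timestamp` (minutes), `kind`
#'   (`"meal"`) and `value` (carbohydrates, g).  May have zero rows.
#' @inheritParams insulin_signal
#' @return Numeric vector `C(t)` (g) on `grid`.
#' @export
carb_signal <- function(meal_events, params = absorption_params(), grid) {
  ev <- .check_events(meal_events, "meal")
  C <- numeric(length(grid))
  tm <- params$t_max
  for (i in seq_len(nrow(ev))) {
    lag <- grid - ev$timestamp[i]
    on <- lag >= 0
    C[on] <- C[on] + ev$value[i] * params$A_g * lag[on] *
      exp(-lag[on] / tm) / tm^2
  }
  C
}

.check_events <- function(events, kinds) {
  if (is.null(events) || nrow(events) == 0L)
    return(data.frame(timestamp = numeric(), kind = character(),
                      value = numeric(), stringsAsFactors = FALSE))
  stopifnot(all(c("timestamp", "kind", "value") %in% names(events)))
  if (!all(events$kind %in% kinds))
    stop("unexpected event kind; wanted ", paste(kinds, collapse = "/"),
         call. = FALSE)
  if (any(events$value < 0))
    stop("event values (doses/carbohydrates) must be non-negative",
         call. = FALSE)
  events
}

#' Align event timestamps to the nearest glucose reading time
#'
#' Insulin and carbohydrate records are snapped to the closest CGM reading
#' timestamp; an exact midpoint goes to the earlier reading.
#'
#' @param events Event data frame with a `timestamp` column (may be empty).
#' @param glucose_timestamps Non-empty vector of reading times (minutes).
#' @return The events with `timestamp` replaced by grid times.
#' @export
align_events <- function(events, glucose_timestamps) {
  if (length(glucose_timestamps) == 0L)
    stop("no glucose timestamps to align to", call. = FALSE)
  if (is.null(events) || nrow(events) == 0L) return(events)
  g <- sort(glucose_timestamps)
  idx <- findInterval(events$timestamp, g)
  snapped <- vapply(seq_along(idx), function(i) {
    t <- events$timestamp[i]
    if (idx[i] == 0L) return(g[1])
    if (idx[i] >= length(g)) return(g[length(g)])
    lo <- g[idx[i]]; hi <- g[idx[i] + 1L]
    if (t - lo <= hi - t) lo else hi   # tie -> earlier reading
  }, numeric(1L))
  events$timestamp <- snapped
  events
}
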