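#' Build supervised forecasting samples from a patient series
#'
#' One sample per anchor time `t` combines `k+1` past glucose readings
#' `G(t), G(t-dt), ..., G(t-k*dt)`, the `h+1` future absorption values
#' `I(t)..I(t+h*dt)` and `C(t)..C(t+h*dt)` (known ahead of time because
#' dosing and meals are logged events), the `k` backward differences
#' `dG(t, t-j*dt) = G(t) - G(t-j*dt)`, and the target `G(t+h*dt)` with its
#' glycemic class.  Any window touching a missing glucose reading (past or
#' target) is discarded entirely — missing data are never imputed.  The
#' train/test tag is inherited from the anchor's segment.
#'
#' With the defaults `k = 12`, `h = 6` and 5-minute sampling this is a
#' 30-minute-ahead forecast from a 60-minute history.
#'
#' @param series A [patient_series()].
#' @param signals Optional list with numeric vectors `I` and `C` on the
#'   series grid; computed from the series' own events via
#'   [insulin_signal()]/[carb_signal()] when `NULL`.
#' @param k Past-window length in steps (default 12).
#' @param h Forecast horizon in steps (default 6).
#' @param params [absorption_params()] used when `signals` is `NULL`.
#' @return A data frame of class `"ge_samples"` with columns
#'   `g0..g<k>`, `i0..i<h>`, `c0..c<h>`, `dg1..dg<k>`, `target_glucose`,
#'   `target_class`, `split`, `t`; attributes `k`, `h`, `patient_id`.
#' @export
build_samples <- function(series, signals = NULL, k = 12, h = 6,
                          params = absorption_params()) {
  if (k <= 0 || h <= 0) stop("`k` and `h` must be positive", call. = FALSE)
  g <- series$grid
  n <- nrow(g)
  if (is.null(signals)) {
    ev <- series_events(series)
    signals <- list(
      I = insulin_signal(ev[ev$kind %in% c("bolus", "basal"), , drop = FALSE],
                         params, g$t),
      C = carb_signal(ev[ev$kind == "meal", , drop = FALSE], params, g$t))
  }
  if (length(signals$I) != n || length(signals$C) != n)
    stop("signals must be on the series grid", call. = FALSE)
  anchors <- seq.int(k + 1L, n - h)
  if (length(anchors) == 0L || n < k + h + 1L)
    return(.empty_samples(k, h, series$patient_id))
  G <- g$glucose
  ok <- vapply(anchors, function(i)
    !anyNA(G[(i - k):i]) && !is.na(G[i + h]), logical(1L))
  anchors <- anchors[ok]
  if (length(anchors) == 0L) return(.empty_samples(k, h, series$patient_id))
  cols <- list()
  for (j in 0:k) cols[[paste0("g", j)]] <- G[anchors - j]
  for (j in 0:h) cols[[paste0("i", j)]] <- signals$I[anchors + j]
  for (j in 0:h) cols[[paste0("c", j)]] <- signals$C[anchors + j]
  for (j in 1:k) cols[[paste0("dg", j)]] <- G[anchors] - G[anchors - j]
  cols$target_glucose <- G[anchors + h]
  cols$target_class <- to_class(cols$target_glucose)
  cols$split <- g$split[anchors]
  cols$t <- g$t[anchors]
  out <- as.data.frame(cols, stringsAsFactors = FALSE)
  structure(out, k = k, h = h, patient_id = series$patient_id,
            class = c("ge_samples", "data.frame"))
}

.empty_samples <- function(k, h, id) {
  nm <- c(paste0("g", 0:k), paste0("i", 0:h), paste0("c", 0:h),
          paste0("dg", 1:k), "target_glucose", "target_class", "split", "t")
  out <- as.data.frame(setNames(rep(list(numeric(0)), length(nm)), nm))
  out$split <- character(0)
  structure(out, k = k, h = h, patient_id = id,
            class = c("ge_samples", "data.frame"))
}

#' Split samples by train/test tag
#'
#' @param samples A `"ge_samples"` data frame.
#' @param split `"train"` or `"test"`.
#' @return The matching subset (attributes preserved).
#' @export
sample_split <- function(samples, split = c("train", "test")) {
  split <- match.arg(split)
  out <- samples[samples$split == split, , drop = FALSE]
  attributes(out)[c("k", "h", "patient_id")] <-
    attributes(samples)[c("k", "h", "patient_id")]
  class(out) <- class(samples)
  out
}
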