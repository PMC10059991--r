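#' Clinical glycemic band table
#'
#' Seven ordered glucose classes used throughout the package, following the
#' 2017 international consensus bounds for hypo- and hyperglycemia, with the
#' euglycemic range split into three bands so that drifts towards hypo- or
#' hyperglycemia raise a warning class before the event itself.
#'
#' Intervals are half-open on the right: a boundary value belongs to the
#' upper band (e.g. 3.9 mmol/L is class 2, not class 1).  Together the bands
#' partition (0, Inf).
#'
#' @return A data frame with columns `class` (integer id 0-6), `label`,
#'   `lower` and `upper` (mmol/L, `lower` inclusive, `upper` exclusive).
#' @examples
#' glycemic_bands()
#' @export
glycemic_bands <- function() {
  data.frame(
    class = 0:6,
    label = c("very low", "low", "normal-closing-to-hypo", "normal",
              "normal-closing-to-hyper", "high", "very high"),
    lower = c(0, 3.0, 3.9, 5.0, 7.8, 10.0, 13.9),
    upper = c(3.0, 3.9, 5.0, 7.8, 10.0, 13.9, Inf),
    stringsAsFactors = FALSE
  )
}

# Interior band bounds; x >= bound selects the upper band.
.band_bounds <- c(3.0, 3.9, 5.0, 7.8, 10.0, 13.9)

#' Map glucose concentration to its glycemic class
#'
#' @param g Glucose in mmol/L; finite and strictly positive.  Vectorised.
#' @return Integer class id(s) in 0-6.
#' @examples
#' to_class(c(2.5, 6.0, 14.0)) # 0 3 6
#' to_class(3.9)               # 2: boundaries belong to the upper band
#' @seealso [glycemic_bands()], [mgdl_to_mmoll()]
#' @export
to_class <- function(g) {
  if (!is.numeric(g) || length(g) == 0L)
    stop("`g` must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(g)) || any(g <= 0))
    stop("glucose values must be finite and strictly positive", call. = FALSE)
  findInterval(g, .band_bounds)
}

# Total banding for model predictions: non-finite or non-positive values map
# to NA_integer_ (the "invalid" sentinel counted as an unconditional miss).
band_or_na <- function(g) {
  cls <- rep(NA_integer_, length(g))
  ok <- is.finite(g) & g > 0
  cls[ok] <- findInterval(g[ok], .band_bounds)
  cls
}

#' Convert glucose from mg/dL to mmol/L
#'
#' The banding table pairs 54 mg/dL with 3.0 mmol/L and 90 mg/dL with
#' 5.0 mmol/L, which fixes the conversion factor at exactly 18.
#'
#' @param v Glucose in mg/dL, non-negative.  Vectorised.
#' @return Glucose in mmol/L.
#' @examples
#' mgdl_to_mmoll(90) # 5
#' @export
mgdl_to_mmoll <- function(v) {
  if (!is.numeric(v) || any(v < 0, na.rm = TRUE))
    stop("mg/dL values must be non-negative", call. = FALSE)
  v / 18.0
}
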