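#' Confusion matrix over the seven glycemic classes
#'
#' Rows are true classes, columns predicted classes.  Predictions may be
#' `NA` (an invalid model output, e.g. a non-finite forecast); these are
#' collected in an extra `"invalid"` column so that they count as false
#' negatives for their true class but never as true positives.
#'
#' @param true Integer vector of true class ids (0-6).
#' @param pred Integer vector of predicted class ids (0-6) or `NA`.
#' @param n_classes Number of classes (default 7).
#' @return An integer matrix, `n_classes` rows; `n_classes` columns plus an
#'   `"invalid"` column when any prediction is `NA`.
#' @export
confusion_matrix <- function(true, pred, n_classes = 7L) {
  if (length(true) != length(pred))
    stop("`true` and `pred` must have the same length", call. = FALSE)
  if (length(true) == 0L) stop("empty sample set", call. = FALSE)
  if (any(true < 0L | true >= n_classes))
    stop("true classes out of range", call. = FALSE)
  p <- ifelse(is.na(pred), n_classes, as.integer(pred))
  if (any(p < 0L | p > n_classes))
    stop("predicted classes out of range", call. = FALSE)
  ncol_out <- n_classes + 1L
  counts <- tabulate(as.integer(true) * ncol_out + p + 1L,
                     nbins = n_classes * ncol_out)
  cm <- matrix(counts, nrow = n_classes, ncol = ncol_out, byrow = TRUE)
  dimnames(cm) <- list(true = paste0("C", 0:(n_classes - 1L)),
                       predicted = c(paste0("C", 0:(n_classes - 1L)), "invalid"))
  if (all(cm[, ncol_out] == 0L)) cm <- cm[, -ncol_out, drop = FALSE]
  cm
}

#' Binary (one-vs-rest) F1 score
#'
#' `F1 = tp / (tp + 0.5 * (fp + fn))`.  With all three counts zero the
#' class is absent from both truth and predictions and the score is defined
#' as 0 (it then carries zero weight in the weighted average anyway).
#'
#' @param tp,fp,fn Non-negative counts of true positives, false positives
#'   and false negatives.
#' @return F1 in \[0, 1\].
#' @examples
#' binary_f1(1, 1, 1) # 0.5
#' @export
binary_f1 <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative", call. = FALSE)
  denom <- tp + 0.5 * (fp + fn)
  ifelse(denom > 0, tp / denom, 0)
}

# per-class one-vs-rest counts from a confusion matrix (rows = truth;
# extra columns beyond the class columns contribute misses, never tp/fp)
.class_counts <- function(cm) {
  nc <- nrow(cm)
  tp <- diag(cm[, seq_len(nc), drop = FALSE])
  fp <- colSums(cm[, seq_len(nc), drop = FALSE]) - tp
  fn <- rowSums(cm) - tp
  list(nc = nc, tp = tp, fp = fp, fn = fn,
       support = rowSums(cm), total = sum(cm))
}

#' Class-frequency-weighted F1 score
#'
#' One-vs-rest F1 per class, averaged with weights `p_i` equal to the
#' fraction of samples truly in class `i`.  Empty classes have zero weight.
#' This is the fitness function of the evolved forecasting models: the data
#' are heavily imbalanced (hypoglycemic bands are rare), so unweighted
#' accuracy would reward ignoring exactly the classes that matter most.
#'
#' @param cm Confusion matrix as produced by [confusion_matrix()] (rows =
#'   true classes; an `"invalid"` column is honoured).
#' @return Weighted F1 in \[0, 1\]; 1 iff the matrix is diagonal.
#' @export
weighted_f1 <- function(cm) {
  k <- .class_counts(cm)
  if (k$total == 0) stop("empty confusion matrix", call. = FALSE)
  f1 <- binary_f1(k$tp, k$fp, k$fn)
  sum(k$support / k$total * f1)
}

#' Full score report from a confusion matrix
#'
#' Weighted-average precision, recall and F1 (weights = true class
#' frequencies) plus overall accuracy (trace/total).  Degenerate classes
#' (no support) carry zero weight; a class never predicted has precision 0.
#'
#' @inheritParams weighted_f1
#' @return An object of class `"score_report"`: a list with elements
#'   `precision`, `recall`, `f1`, `accuracy`, `per_class` (data frame of
#'   tp/fp/fn, per-class scores and weights) and `n`.
#' @export
score_report <- function(cm) {
  k <- .class_counts(cm)
  if (k$total == 0) stop("empty confusion matrix", call. = FALSE)
  w <- k$support / k$total
  prec_i <- ifelse(k$tp + k$fp > 0, k$tp / (k$tp + k$fp), 0)
  rec_i  <- ifelse(k$tp + k$fn > 0, k$tp / (k$tp + k$fn), 0)
  f1_i   <- binary_f1(k$tp, k$fp, k$fn)
  acc <- sum(diag(cm[, seq_len(k$nc), drop = FALSE])) / k$total
  structure(list(
    precision = sum(w * prec_i),
    recall    = sum(w * rec_i),
    f1        = sum(w * f1_i),
    accuracy  = acc,
    per_class = data.frame(class = seq_len(k$nc) - 1L, tp = k$tp, fp = k$fp,
                           fn = k$fn, precision = prec_i, recall = rec_i,
                           f1 = f1_i, weight = w, row.names = NULL),
    n = k$total
  ), class = "score_report")
}

#' @export
print.score_report <- function(x, digits = 4, ...) {
  cat("Weighted classification scores (", x$n, " samples)\n", sep = "")
  cat(sprintf("  precision %.*f  recall %.*f  F1 %.*f  accuracy %.*f\n",
              digits, x$precision, digits, x$recall,
              digits, x$f1, digits, x$accuracy))
  invisible(x)
}

#' Serialise a score report to JSON
#'
#' @param x A `"score_report"`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
score_report_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "score_report"))
  js <- jsonlite::toJSON(unclass(x), dataframe = "columns", auto_unbox = TRUE,
                         digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Relative improvement of one score over another, in percent
#'
#' @param a,b Scores; `b` (the baseline) must be positive.
#' @return `100 * (a - b) / b`.
#' @examples
#' relative_improvement(0.68, 0.66) # 3.0303...
#' @export
relative_improvement <- function(a, b) {
  if (any(b <= 0)) stop("baseline score must be positive", call. = FALSE)
  100 * (a - b) / b
}

#' Mean and standard deviation of per-patient scores
#'
#' The standard deviation uses the population (n) denominator, the
#' convention that reproduces the dispersion margins of published
#' cross-evaluation tables for the OhioT1DM benchmark; set
#' `population = FALSE` for the sample (n-1) convention.
#'
#' @param scores Non-empty numeric vector.
#' @param population Use the n denominator (default `TRUE`).
#' @return Named numeric vector `c(mean, sd)`.
#' @export
aggregate_scores <- function(scores, population = TRUE) {
  if (length(scores) == 0L || !is.numeric(scores))
    stop("`scores` must be a non-empty numeric vector", call. = FALSE)
  m <- mean(scores)
  n <- length(scores)
  s <- if (n == 1L) 0 else {
    v <- sum((scores - m)^2) / (if (population) n else n - 1L)
    sqrt(v)
  }
  c(mean = m, sd = s)
}
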