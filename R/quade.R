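#' Quade test for comparing algorithms across problems
#'
#' Nonparametric k-algorithm, n-problem comparison that, unlike the
#' Friedman test, weights problems by the spread of their results: problems
#' on which the algorithms differ more count more.  Within each problem the
#' algorithms are ranked (rank 1 = best); the problems themselves are
#' ranked by their score range `Q_i`; the weighted centred products
#' `S_ij = Q_i (r_ij - (k+1)/2)` yield the statistic
#' `F = (n-1) B / (A - B)` with `A = sum S_ij^2`, `B = sum_j S_j^2 / n`,
#' referred to the F distribution with `(k-1, (n-1)(k-1))` degrees of
#' freedom.  Ties anywhere use midranks.
#'
#' @param scores Numeric n x k matrix (rows = problems/subjects, columns =
#'   algorithms, column names used as labels); no missing cells, `n >= 2`,
#'   `k >= 2`.
#' @param higher_is_better If `TRUE` (default) larger scores get rank 1.
#' @return Object of class `"quade_test"`: weighted average ranks `T_j`
#'   (summing to `k(k+1)/2`), `statistic`, degrees of freedom, `p.value`,
#'   and the internal ranks.
#' @examples
#' m <- cbind(a = c(.9, .8, .7), b = c(.85, .82, .60))
#' quade_test(m)
#' @export
quade_test <- function(scores, higher_is_better = TRUE) {
  scores <- as.matrix(scores)
  if (anyNA(scores)) stop("score matrix has missing cells", call. = FALSE)
  n <- nrow(scores); k <- ncol(scores)
  if (n < 2L || k < 2L) stop("need at least 2 problems and 2 algorithms",
                             call. = FALSE)
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("alg", seq_len(k))
  dir <- if (higher_is_better) -1 else 1
  r <- t(apply(dir * scores, 1L, rank))           # within-problem midranks
  Q <- rank(apply(scores, 1L, function(z) diff(range(z))))
  S <- Q * (r - (k + 1) / 2)
  Sj <- colSums(S)
  A <- sum(S^2)
  B <- sum(Sj^2) / n
  if (A == B)
    stop("all cells are tied: the Quade statistic is undefined (A == B)",
         call. = FALSE)
  statistic <- (n - 1) * B / (A - B)
  Tj <- colSums(Q * r) / (n * (n + 1) / 2)
  df <- c(k - 1, (n - 1) * (k - 1))
  structure(list(ranks = setNames(Tj, colnames(scores)),
                 statistic = statistic, df = df,
                 p.value = pf(statistic, df[1], df[2], lower.tail = FALSE),
                 within_ranks = r, problem_ranks = Q, n = n, k = k,
                 scores = scores),
            class = "quade_test")
}

#' @export
print.quade_test <- function(x, digits = 5, ...) {
  cat("Quade ranks test (", x$n, " problems, ", x$k, " algorithms)\n",
      sep = "")
  for (j in order(x$ranks))
    cat(sprintf("  %-12s rank %.5f\n", names(x$ranks)[j], x$ranks[j]))
  cat(sprintf("  Statistic: %.*f   p-value: %.*f  (F with %d, %d df)\n",
              digits, x$statistic, digits, x$p.value, x$df[1], x$df[2]))
  invisible(x)
}

#' Post-hoc comparisons against a control after a Quade test
#'
#' Compares every algorithm to the control via the normal approximation
#' `z = (T_j - T_control) / SE` with
#' `SE = sqrt(k(k+1)(2n+1)(k-1) / (18 n (n+1)))` and two-sided p-values,
#' then adjusts the `k - 1` p-values with the Bonferroni-Dunn, Holm,
#' Hochberg, Finner and Li procedures.  With a single comparison all five
#' adjustments return the raw p-value.
#'
#' @param qt A `"quade_test"`.
#' @param control Control algorithm: name or column index (default: the
#'   best-ranked algorithm).
#' @param alpha Significance level recorded in the result (default 0.05).
#' @return Object of class `"quade_posthoc"`: a data frame `comparisons`
#'   with the z statistic (positive when the control ranks better), raw and
#'   adjusted p-values, plus `control`, `SE` and `alpha`.
#' @export
quade_posthoc <- function(qt, control = NULL, alpha = 0.05) {
  stopifnot(inherits(qt, "quade_test"))
  labs <- names(qt$ranks)
  if (is.null(control)) control <- labs[which.min(qt$ranks)]
  if (is.numeric(control)) control <- labs[control]
  if (!control %in% labs) stop("unknown control algorithm: ", control,
                               call. = FALSE)
  n <- qt$n; k <- qt$k
  SE <- sqrt(k * (k + 1) * (2 * n + 1) * (k - 1) / (18 * n * (n + 1)))
  others <- setdiff(labs, control)
  z <- (qt$ranks[others] - qt$ranks[control]) / SE
  p <- 2 * pnorm(-abs(z))
  adj <- .adjust_pvalues(p)
  structure(list(
    comparisons = data.frame(comparison = paste(control, "vs.", others),
                             z = as.numeric(z), p = as.numeric(p),
                             bonferroni_dunn = adj$bonferroni_dunn,
                             holm = adj$holm, hochberg = adj$hochberg,
                             finner = adj$finner, li = adj$li,
                             row.names = NULL, stringsAsFactors = FALSE),
    control = control, SE = SE, alpha = alpha),
    class = "quade_posthoc")
}

# the five control-vs-all adjustments over m = length(p) comparisons
.adjust_pvalues <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  i <- seq_len(m)
  bd <- pmin(1, m * ps)
  holm <- pmin(1, cummax((m - i + 1) * ps))
  hoch <- rev(cummin(rev((m - i + 1) * ps)))
  hoch <- pmin(1, hoch)
  finner <- pmin(1, cummax(1 - (1 - ps)^(m / i)))
  li <- ps / (ps + 1 - ps[m])
  unsort <- function(v) { out <- numeric(m); out[o] <- v; out }
  lapply(list(bonferroni_dunn = bd, holm = holm, hochberg = hoch,
              finner = finner, li = li), unsort)
}

#' @export
print.quade_posthoc <- function(x, digits = 5, ...) {
  cat("Post-hoc procedures (control:", x$control, ")\n")
  df <- x$comparisons
  df[-1] <- lapply(df[-1], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Reject/retain decisions from adjusted p-values
#'
#' The null hypothesis of equivalence with the control is rejected for a
#' comparison iff its adjusted p-value is strictly below `alpha`; a
#' p-value equal to `alpha` retains.
#'
#' @param ph A `"quade_posthoc"`.
#' @param alpha Significance level in (0, 1) (default: the level stored in
#'   `ph`).
#' @return Logical matrix (comparisons x procedures), `TRUE` = reject.
#' @export
decide <- function(ph, alpha = NULL) {
  stopifnot(inherits(ph, "quade_posthoc"))
  alpha <- alpha %||% ph$alpha
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  procs <- c("bonferroni_dunn", "holm", "hochberg", "finner", "li")
  out <- sapply(procs, function(pr) ph$comparisons[[pr]] < alpha)
  out <- matrix(out, nrow = nrow(ph$comparisons),
                dimnames = list(ph$comparisons$comparison, procs))
  out
}
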