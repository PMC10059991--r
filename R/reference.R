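#' Published OhioT1DM benchmark scores
#'
#' Per-subject weighted F1 scores reported for the OhioT1DM cohort by the
#' federated-vs-isolated glucose forecasting benchmark: the 6x6
#' cross-evaluation matrices of the isolated (`non_fl`) and federated
#' (`flea`) arms over the six learning subjects (559-591), the two global
#' models' F1 on the six held-out subjects (540-596), and the held-out
#' precision/recall/F1/accuracy summary.  The underlying CGM data set is
#' access-restricted and not included — these are the published summary
#' scores only, shipped so that the statistical comparison machinery can
#' be exercised and checked against its published outcome.
#'
#' @return A list:
#'   \describe{
#'     \item{nonfl, flea}{6x6 matrices, rows = models (by training
#'       subject), columns = evaluated-on subjects.}
#'     \item{holdout}{2x6 matrix, rows `non_fl`/`flea`, columns = held-out
#'       subjects.}
#'     \item{holdout_scores}{Data frame of per-subject precision, recall,
#'       F1 and accuracy for both arms.}
#'   }
#' @export
ohio_reference_scores <- function() {
  path <- function(f) system.file("extdata", f, package = "gefed",
                                  mustWork = TRUE)
  as_mat <- function(f) {
    d <- read.csv(path(f), check.names = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- as.character(d[[1]])
    colnames(m) <- sub("^p", "", colnames(m))
    m
  }
  list(nonfl = as_mat("ohio_f1_nonfl.csv"),
       flea = as_mat("ohio_f1_flea.csv"),
       holdout = as_mat("ohio_f1_holdout.csv"),
       holdout_scores = read.csv(path("ohio_scores_holdout.csv"),
                                 stringsAsFactors = FALSE))
}

#' Twelve-subject paired F1 matrix of the two benchmark global models
#'
#' Assembles the subjects x algorithms matrix on which the published
#' algorithm comparison was run: each arm is represented by its selected
#' global model (the best-average row of its cross-evaluation matrix —
#' model 570 for `non_fl`, model 575 for `flea`) over the six learning
#' subjects, concatenated with the same models' scores on the six held-out
#' subjects.
#'
#' @return A 12x2 numeric matrix with columns `flea`, `non_fl` and the
#'   subject ids as row names, ready for [quade_test()].
#' @export
ohio_result_matrix <- function() {
  ref <- ohio_reference_scores()
  sel <- function(m) rownames(m)[which.max(rowMeans(m))]
  nonfl <- c(ref$nonfl[sel(ref$nonfl), ], ref$holdout["non_fl", ])
  flea <- c(ref$flea[sel(ref$flea), ], ref$holdout["flea", ])
  cbind(flea = flea, non_fl = nonfl)
}
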