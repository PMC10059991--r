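#' Federated orchestration parameters
#'
#' Controls the master/slave FLEA protocol: every `migration_interval`
#' generations each slave's best model is relayed through the master to all
#' other slaves, which score it on their own data and integrate it by
#' worst-replacement.  Only serialised model expressions and fitness values
#' ever travel; raw samples never leave a slave.  `mode = "non_fl"` is the
#' baseline: identical in every respect except that migration is disabled.
#'
#' @param migration_interval Generations between exchanges (default 100);
#'   with the default 500 generations this yields exactly five
#'   communication phases.  An interval larger than the generation count
#'   disables communication, making `"flea"` and `"non_fl"` coincide.
#' @param ge A [ge_control()] applied on every slave.
#' @param mode `"flea"` or `"non_fl"`.
#' @param seed Master seed; per-slave seeds are drawn from it, so whole
#'   experiments replay bit-identically.
#' @return List of class `"flea_control"`.
#' @export
flea_control <- function(migration_interval = 100L, ge = ge_control(),
                         mode = c("flea", "non_fl"), seed = 1L) {
  mode <- match.arg(mode)
  if (migration_interval < 1L)
    stop("`migration_interval` must be a positive integer", call. = FALSE)
  structure(list(migration_interval = as.integer(migration_interval),
                 ge = ge, mode = mode, seed = as.integer(seed)),
            class = "flea_control")
}

# coerce a cohort (list of patient_series or ge_samples) to sample tables
.cohort_samples <- function(cohort, k, h, params) {
  lapply(cohort, function(x) {
    if (inherits(x, "ge_samples")) x
    else if (inherits(x, "patient_series"))
      build_samples(x, k = k, h = h, params = params)
    else stop("cohort elements must be patient_series or ge_samples",
              call. = FALSE)
  })
}

.swap_rng_in <- function(saved) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", saved, envir = globalenv())
  old
}
.swap_rng_out <- function() get(".Random.seed", envir = globalenv())

#' Fit federated (or isolated) per-patient forecasting models
#'
#' Runs one Grammatical Evolution population per patient ("slave") under a
#' synchronous in-process master.  In `"flea"` mode, after generations
#' `interval, 2*interval, ...` each slave sends its best model to the
#' master, receives the other slaves' bests, scores the immigrants on its
#' local training data and replaces its worst members with strictly better
#' immigrants.  Migration is never triggered at the random initial
#' population.  At termination the final best models are cross-evaluated on
#' every patient's test set and the global model — the one with the best
#' average cross-evaluation F1 — is selected (ties to the lower patient
#' index).
#'
#' Each slave owns a private RNG stream seeded from the master seed, so a
#' single-slave federation, or any run with `migration_interval` greater
#' than the generation count, is generation-for-generation identical to
#' isolated [ge_fit()] runs.
#'
#' @param cohort List of [patient_series()] or `"ge_samples"` objects, one
#'   per patient (training uses the `train` split, cross-evaluation the
#'   `test` split).
#' @param control A [flea_control()].
#' @param grammar Optional `"ge_grammar"` shared by all slaves.
#' @param k,h Window sizes used when `cohort` holds series.
#' @param params [absorption_params()] for preprocessing series.
#' @return Object of class `"flea_fit"`: per-patient `models`
#'   (`"ge_model"`), the `cross_eval` matrix, `global_id`/`global_model`,
#'   the migration `message_log` (one row per model relayed to the master:
#'   sender, generation, phenotype, sender-side fitness — never sample
#'   data), and the control/seed bookkeeping.
#' @export
flea_fit <- function(cohort, control = flea_control(), grammar = NULL,
                     k = 12, h = 6, params = absorption_params()) {
  samples <- .cohort_samples(cohort, k, h, params)
  n_slaves <- length(samples)
  if (n_slaves == 0L) stop("empty cohort", call. = FALSE)
  train <- lapply(samples, sample_split, "train")
  test <- lapply(samples, sample_split, "test")
  if (any(vapply(train, nrow, integer(1L)) == 0L))
    stop("every patient needs non-empty training samples", call. = FALSE)
  if (is.null(grammar))
    grammar <- glucose_grammar(k = attr(samples[[1L]], "k") %||% k,
                               h = attr(samples[[1L]], "h") %||% h)
  ctl <- control$ge
  slave_seeds <- with_private_seed(control$seed,
                                   sample.int(.Machine$integer.max - 1L,
                                              n_slaves))
  # initialise slaves, each under its own RNG stream
  slaves <- vector("list", n_slaves)
  rng <- vector("list", n_slaves)
  keep <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  for (i in seq_len(n_slaves)) {
    set.seed(slave_seeds[i])
    slaves[[i]] <- ea_new(train[[i]], grammar, ctl)
    rng[[i]] <- .swap_rng_out()
  }
  log_sender <- integer(0); log_gen <- integer(0)
  log_pheno <- character(0); log_fit <- numeric(0)
  interval <- control$migration_interval
  for (g in seq_len(ctl$generations)) {
    for (i in seq_len(n_slaves)) {
      .swap_rng_in(rng[[i]])
      ea_step(slaves[[i]])
      rng[[i]] <- .swap_rng_out()
    }
    if (control$mode == "flea" && g %% interval == 0L && n_slaves > 1L) {
      bests <- lapply(slaves, .ea_best)
      log_sender <- c(log_sender, seq_len(n_slaves))
      log_gen <- c(log_gen, rep(g, n_slaves))
      log_pheno <- c(log_pheno,
                     vapply(bests, `[[`, character(1L), "phenotype"))
      log_fit <- c(log_fit, vapply(bests, `[[`, numeric(1L), "fitness"))
      for (i in seq_len(n_slaves)) {
        imms <- lapply(bests[-i], function(b) {
          list(genome = b$genome, phenotype = b$phenotype,
               fitness = .cached_fitness(slaves[[i]], b$phenotype))
        })
        ea_integrate(slaves[[i]], imms)
      }
    }
  }
  if (!is.null(keep)) assign(".Random.seed", keep, envir = globalenv())

  ids <- vapply(seq_len(n_slaves), function(i)
    attr(samples[[i]], "patient_id") %||% paste0("patient", i), character(1L))
  models <- lapply(seq_len(n_slaves), function(i) {
    b <- .ea_best(slaves[[i]])
    structure(list(phenotype = b$phenotype, genome = b$genome,
                   fitness = b$fitness, history = slaves[[i]]$history,
                   generations = slaves[[i]]$generation, control = ctl,
                   grammar = grammar, n_train = nrow(train[[i]]),
                   patient_id = ids[i]), class = "ge_model")
  })
  ce <- cross_evaluate(models, test, ids)
  gid <- select_global_model(ce)
  structure(list(
    mode = control$mode, models = models, cross_eval = ce,
    global_id = gid, global_model = models[[gid]],
    message_log = data.frame(slave = log_sender, generation = log_gen,
                             phenotype = log_pheno, fitness = log_fit,
                             stringsAsFactors = FALSE),
    n_migrations = if (n_slaves > 1L && control$mode == "flea")
      ctl$generations %/% interval else 0L,
    control = control, slave_seeds = slave_seeds, patient_ids = ids),
    class = "flea_fit")
}

#' @export
print.flea_fit <- function(x, ...) {
  cat(sprintf("flea_fit (%s): %d patients, %d generations, %d migration rounds\n",
              x$mode, length(x$models), x$models[[1L]]$generations,
              x$n_migrations))
  cat(sprintf("  global model: patient %s  (cross-eval mean F1 %.4f)\n",
              x$patient_ids[x$global_id],
              x$cross_eval$row_margin[x$global_id, "mean"]))
  cat("  formula:", x$global_model$phenotype, "\n")
  invisible(x)
}

#' Cross-evaluate per-patient models on every patient's test set
#'
#' @param models List of `"ge_model"` objects or phenotype strings.
#' @param test_samples List of `"ge_samples"` (test splits), same order.
#' @param ids Optional labels for both axes.
#' @return Object of class `"cross_eval_matrix"`: `scores` (cell `(i, j)` =
#'   weighted F1 of model `i` on patient `j`'s test samples), plus
#'   `row_margin` and `col_margin` (mean and population SD per
#'   [aggregate_scores()]).
#' @export
cross_evaluate <- function(models, test_samples, ids = NULL) {
  if (length(models) == 0L) stop("no models", call. = FALSE)
  if (any(vapply(test_samples, nrow, integer(1L)) == 0L))
    stop("every patient needs non-empty test samples", call. = FALSE)
  phenos <- vapply(models, function(m)
    if (inherits(m, "ge_model")) m$phenotype else m, character(1L))
  if (is.null(ids)) ids <- paste0("patient", seq_along(models))
  S <- matrix(NA_real_, length(models), length(test_samples),
              dimnames = list(model = ids, evaluated_on = ids))
  for (i in seq_along(phenos))
    for (j in seq_along(test_samples))
      S[i, j] <- model_fitness(phenos[i], test_samples[[j]])
  rm_ <- t(apply(S, 1L, aggregate_scores))
  cm_ <- t(apply(S, 2L, aggregate_scores))
  structure(list(scores = S, row_margin = rm_, col_margin = cm_),
            class = "cross_eval_matrix")
}

#' @export
print.cross_eval_matrix <- function(x, digits = 4, ...) {
  cat("Cross-evaluation weighted F1 (rows = models, cols = patients):\n")
  print(round(x$scores, digits))
  cat("Row margins (mean, population sd):\n")
  print(round(x$row_margin, digits))
  invisible(x)
}

#' Select the global model from a cross-evaluation matrix
#'
#' The model with the best average performance over all patients; ties go
#' to the lower patient index.
#'
#' @param ce A `"cross_eval_matrix"`.
#' @return Row index of the selected model.
#' @export
select_global_model <- function(ce) {
  stopifnot(inherits(ce, "cross_eval_matrix"))
  unname(which.max(ce$row_margin[, "mean"]))
}

#' Run the two-arm federation experiment
#'
#' For each master seed, fits the cohort's learning patients in both the
#' federated (`"flea"`) and isolated (`"non_fl"`) modes with identical
#' per-slave seeds, selects each arm's global model by cross-evaluation,
#' and measures its generalisation: the weighted F1 on the test sets of
#' held-out patients who took no part in learning.
#'
#' @param learning List of learning-patient inputs (series or samples).
#' @param holdout List of held-out-patient inputs.
#' @param control A [flea_control()]; its `mode` and `seed` are overridden
#'   per arm and per element of `seeds`.
#' @param seeds Integer vector of master seeds.
#' @param modes Arms to run.
#' @inheritParams flea_fit
#' @return Object of class `"flea_experiment"`: per-seed `fits`, a
#'   `holdout` table of per-patient F1 for each arm and seed, `holdout_mean`
#'   (seeds x modes), and a per-seed `result_matrix` (subjects x algorithms:
#'   the selected global model's F1 on every learning patient's and every
#'   held-out patient's test set) ready for [quade_test()].
#' @export
flea_experiment <- function(learning, holdout, control = flea_control(),
                            seeds = 1L, modes = c("flea", "non_fl"),
                            k = 12, h = 6, params = absorption_params()) {
  learn_s <- .cohort_samples(learning, k, h, params)
  hold_s <- .cohort_samples(holdout, k, h, params)
  hold_test <- lapply(hold_s, sample_split, "test")
  if (any(vapply(hold_test, nrow, integer(1L)) == 0L))
    stop("held-out patients need non-empty test samples", call. = FALSE)
  hold_ids <- vapply(seq_along(hold_s), function(i)
    attr(hold_s[[i]], "patient_id") %||% paste0("holdout", i), character(1L))
  fits <- list()
  hold_rows <- list()
  result_matrices <- list()
  for (sd in seeds) {
    per_mode_scores <- list()
    for (mode in modes) {
      ctl <- control; ctl$mode <- mode; ctl$seed <- as.integer(sd)
      fit <- flea_fit(learn_s, ctl, k = k, h = h, params = params)
      key <- paste0(mode, "_seed", sd)
      fits[[key]] <- fit
      hf <- vapply(hold_test, function(ts)
        model_fitness(fit$global_model$phenotype, ts), numeric(1L))
      hold_rows[[key]] <- data.frame(
        seed = sd, mode = mode, patient = hold_ids, f1 = hf,
        stringsAsFactors = FALSE)
      per_mode_scores[[mode]] <-
        c(fit$cross_eval$scores[fit$global_id, ], setNames(hf, hold_ids))
    }
    result_matrices[[paste0("seed", sd)]] <-
      do.call(cbind, per_mode_scores)
  }
  hold_df <- do.call(rbind, hold_rows)
  rownames(hold_df) <- NULL
  hm <- tapply(hold_df$f1, list(seed = hold_df$seed, mode = hold_df$mode),
               mean)
  structure(list(fits = fits, holdout = hold_df, holdout_mean = hm,
                 result_matrix = result_matrices, seeds = seeds,
                 modes = modes),
            class = "flea_experiment")
}

#' @export
print.flea_experiment <- function(x, digits = 4, ...) {
  cat("Federated-vs-isolated experiment over seeds:",
      paste(x$seeds, collapse = ", "), "\n")
  cat("Mean held-out weighted F1 of the selected global model:\n")
  print(round(x$holdout_mean, digits))
  if (all(c("flea", "non_fl") %in% colnames(x$holdout_mean))) {
    wins <- sum(x$holdout_mean[, "flea"] >= x$holdout_mean[, "non_fl"])
    cat(sprintf("FLEA >= non-FL in %d of %d seeds\n", wins,
                nrow(x$holdout_mean)))
  }
  invisible(x)
}
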