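#' Protected arithmetic functions
#'
#' Total-on-the-reals variants of log, square root and division used inside
#' evolved expressions, so that every phenotype evaluates to a finite value
#' for finite inputs: `plog(x) = log(1 + |x|)`, `psqrt(x) = sqrt(|x|)`, and
#' the analytic quotient `aq(x, y) = x / sqrt(1 + y^2)`.
#'
#' @param x,y Numeric (vectorised).
#' @return Numeric of the common length.
#' @examples
#' plog(exp(1) - 1) # 1
#' psqrt(-4)        # 2
#' aq(3, 4)         # 3/sqrt(17)
#' @name protected
NULL

#' @rdname protected
#' @export
plog <- function(x) log(1 + abs(x))

#' @rdname protected
#' @export
psqrt <- function(x) sqrt(abs(x))

#' @rdname protected
#' @export
aq <- function(x, y) x / sqrt(1 + y^2)

.protected_env <- new.env(parent = baseenv())
assign("plog", plog, envir = .protected_env)
assign("psqrt", psqrt, envir = .protected_env)
assign("aq", aq, envir = .protected_env)

# parse a phenotype once; NULL if unparseable (cannot happen for grammar
# output, but the evaluator stays total)
.compile_phenotype <- function(pheno) {
  tryCatch(parse(text = pheno, keep.source = FALSE)[[1L]],
           error = function(e) NULL)
}

# evaluate a phenotype on a sample table -> forecast values (may be
# non-finite; never raises)
.eval_phenotype <- function(expr, samples) {
  if (is.null(expr)) return(rep(NA_real_, nrow(samples)))
  v <- tryCatch(eval(expr, samples, .protected_env),
                error = function(e) NA_real_)
  if (length(v) == 1L) v <- rep(v, nrow(samples))
  if (length(v) != nrow(samples)) return(rep(NA_real_, nrow(samples)))
  v
}

# weighted F1 from true classes and (possibly NA) predicted classes,
# without building a dimnamed matrix (hot path of the EA)
.wf1_fast <- function(true, pred) {
  p <- ifelse(is.na(pred), 7L, pred)
  counts <- tabulate(true * 8L + p + 1L, nbins = 56L)
  cm <- matrix(counts, nrow = 7L, ncol = 8L, byrow = TRUE)
  tp <- cm[cbind(1:7, 1:7)]
  fp <- colSums(cm[, 1:7, drop = FALSE]) - tp
  support <- rowSums(cm)
  fn <- support - tp
  denom <- tp + 0.5 * (fp + fn)
  f1 <- ifelse(denom > 0, tp / denom, 0)
  sum(support / sum(support) * f1)
}

#' Fitness of a model expression on a sample set
#'
#' Evaluates the expression on every sample, bands the forecasts
#' ([glycemic_bands()]), and returns the class-frequency-weighted F1
#' against the target classes.  Non-finite or non-positive forecasts are
#' sentinel misclassifications (they can never be true positives).  An
#' unparseable/invalid phenotype scores 0, the worst fitness; the EA
#' maximises this score.
#'
#' @param phenotype Model expression as a string (or a pre-parsed call).
#' @param samples A `"ge_samples"` data frame with a `target_class` column.
#' @return Weighted F1 in \[0, 1\].
#' @export
model_fitness <- function(phenotype, samples) {
  if (nrow(samples) == 0L) stop("empty sample set", call. = FALSE)
  expr <- if (is.character(phenotype)) .compile_phenotype(phenotype)
          else phenotype
  ghat <- .eval_phenotype(expr, samples)
  .wf1_fast(as.integer(samples$target_class), band_or_na(ghat))
}

#' EA control parameters
#'
#' Defaults follow the full-scale experimental setting of the forecasting
#' study: population 200 for 500 generations, tournament size 4, one-point
#' crossover at 90%, a 10% per-individual mutation probability with one
#' int-flip event, codon size 100000, grow initialisation with maximum
#' depth 10, and elitism of 1 (which makes the best-so-far fitness
#' monotone; set `elitism = 0` to disable).
#'
#' @param population_size,generations Population size and generation count.
#' @param tournament_size Tournament size for selection.
#' @param p_crossover,p_mutation Per-pair crossover and per-individual
#'   mutation probabilities.
#' @param codon_size Exclusive codon upper bound.
#' @param max_wraps Genome rereads allowed during mapping.
#' @param max_init_depth Grow-initialisation depth bound.
#' @param elitism Number of best individuals copied unchanged (0 or 1).
#' @param max_genome_length Genomes are truncated to this many codons.
#' @return List of class `"ge_control"`.
#' @export
ge_control <- function(population_size = 200L, generations = 500L,
                       tournament_size = 4L, p_crossover = 0.9,
                       p_mutation = 0.1, codon_size = 100000L,
                       max_wraps = 2L, max_init_depth = 10L, elitism = 1L,
                       max_genome_length = 500L) {
  ctl <- list(population_size = as.integer(population_size),
              generations = as.integer(generations),
              tournament_size = as.integer(tournament_size),
              p_crossover = p_crossover, p_mutation = p_mutation,
              codon_size = as.integer(codon_size),
              max_wraps = as.integer(max_wraps),
              max_init_depth = as.integer(max_init_depth),
              elitism = as.integer(elitism),
              max_genome_length = as.integer(max_genome_length))
  if (ctl$population_size < 1L || ctl$generations < 0L ||
      ctl$tournament_size < 1L || ctl$codon_size < 1L)
    stop("sizes must be positive", call. = FALSE)
  if (any(c(ctl$p_crossover, ctl$p_mutation) < 0) ||
      any(c(ctl$p_crossover, ctl$p_mutation) > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  structure(ctl, class = "ge_control")
}

#' Tournament selection
#'
#' Draws `size` population indices uniformly with replacement and returns
#' the index of the fittest; exact fitness ties go to the earlier
#' population index.
#'
#' @param fitness Numeric fitness vector of the population.
#' @param size Tournament size.
#' @return Selected population index.
#' @export
tournament_select <- function(fitness, size = 4L) {
  idx <- sample.int(length(fitness), size, replace = TRUE)
  f <- fitness[idx]
  min(idx[f == max(f)])
}

#' One-point variable-length crossover
#'
#' With probability `p` a cut point is drawn independently for each parent
#' within its used codons and the tails are swapped; otherwise the parents
#' are copied.  A cut at position 0 swaps the genomes entirely; a cut pair
#' that would leave a child empty degenerates to copying the parents, so
#' genomes stay non-empty and codon totals are conserved.
#'
#' @param g1,g2 Integer codon vectors.
#' @param p Crossover probability.
#' @param used1,used2 Used-codon counts (default: whole genome).
#' @param max_len Children are truncated to this length (`Inf` = never).
#' @return List of two genomes.
#' @export
one_point_crossover <- function(g1, g2, p = 0.9, used1 = length(g1),
                                used2 = length(g2), max_len = Inf) {
  if (runif(1) >= p) return(list(g1, g2))
  c1 <- sample.int(used1 + 1L, 1L) - 1L
  c2 <- sample.int(used2 + 1L, 1L) - 1L
  ch1 <- c(g1[seq_len(c1)], if (c2 < length(g2)) g2[(c2 + 1L):length(g2)])
  ch2 <- c(g2[seq_len(c2)], if (c1 < length(g1)) g1[(c1 + 1L):length(g1)])
  # a cut pair that would empty a genome degenerates to copying the parents
  if (length(ch1) == 0L || length(ch2) == 0L) return(list(g1, g2))
  if (length(ch1) > max_len) ch1 <- ch1[seq_len(max_len)]
  if (length(ch2) > max_len) ch2 <- ch2[seq_len(max_len)]
  list(ch1, ch2)
}

#' Int-flip mutation with one mutation event
#'
#' With probability `p` the genome undergoes exactly one mutation event: a
#' uniformly chosen codon is replaced by a uniform draw from
#' `[0, codon_size)`.  At most one position changes.
#'
#' @param g Integer codon vector.
#' @param p Per-individual mutation probability.
#' @param codon_size Exclusive codon upper bound.
#' @return The (possibly) mutated genome.
#' @export
int_flip_mutation <- function(g, p = 0.1, codon_size = 100000L) {
  if (runif(1) < p) {
    pos <- sample.int(length(g), 1L)
    g[pos] <- sample.int(codon_size, 1L) - 1L
  }
  g
}

# ---- EA engine (resumable state, used directly by the federation) -------

ea_new <- function(samples, grammar, control) {
  if (nrow(samples) == 0L) stop("no training samples", call. = FALSE)
  st <- new.env(parent = emptyenv())
  st$samples <- samples
  st$true_class <- as.integer(samples$target_class)
  st$grammar <- grammar
  st$control <- control
  st$cache <- new.env(parent = emptyenv(), hash = TRUE)
  st$generation <- 0L
  st$history <- numeric(0)
  st$genomes <- lapply(seq_len(control$population_size), function(i)
    grow_genome(grammar, control$max_init_depth, control$codon_size))
  .ea_evaluate(st)
  st$history <- .ea_best(st)$fitness
  st
}

.ea_evaluate <- function(st) {
  ctl <- st$control
  n <- length(st$genomes)
  st$phenos <- character(n)
  st$used <- integer(n)
  st$fitness <- numeric(n)
  for (i in seq_len(n)) {
    mp <- map_genome(st$genomes[[i]], st$grammar, ctl$max_wraps)
    st$used[i] <- mp$used
    if (!mp$valid) { st$phenos[i] <- NA_character_; st$fitness[i] <- 0; next }
    st$phenos[i] <- mp$phenotype
    st$fitness[i] <- .cached_fitness(st, mp$phenotype)
  }
  invisible(st)
}

.cached_fitness <- function(st, pheno) {
  key <- pheno
  hit <- get0(key, envir = st$cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  f <- .wf1_fast(st$true_class,
                 band_or_na(.eval_phenotype(.compile_phenotype(pheno),
                                            st$samples)))
  assign(key, f, envir = st$cache)
  f
}

.ea_best <- function(st) {
  i <- which.max(st$fitness)    # earliest index on ties
  list(index = i, genome = st$genomes[[i]], phenotype = st$phenos[i],
       fitness = st$fitness[i])
}

ea_step <- function(st) {
  ctl <- st$control
  n <- ctl$population_size
  n_child <- n - ctl$elitism
  elite <- if (ctl$elitism > 0L) .ea_best(st) else NULL
  children <- vector("list", n_child)
  filled <- 0L
  while (filled < n_child) {
    i1 <- tournament_select(st$fitness, ctl$tournament_size)
    i2 <- tournament_select(st$fitness, ctl$tournament_size)
    pair <- one_point_crossover(st$genomes[[i1]], st$genomes[[i2]],
                                ctl$p_crossover,
                                max(st$used[i1], 1L), max(st$used[i2], 1L),
                                ctl$max_genome_length)
    for (ch in pair) {
      if (filled >= n_child) break
      filled <- filled + 1L
      children[[filled]] <- int_flip_mutation(ch, ctl$p_mutation,
                                              ctl$codon_size)
    }
  }
  st$genomes <- c(if (!is.null(elite)) list(elite$genome), children)
  .ea_evaluate(st)
  st$generation <- st$generation + 1L
  st$history <- c(st$history, .ea_best(st)$fitness)
  invisible(st)
}

# replace the worst members with immigrants (already scored on local data),
# best immigrant first, strictly-better rule; population size is unchanged
ea_integrate <- function(st, immigrants) {
  if (length(immigrants) == 0L) return(invisible(st))
  ord <- order(vapply(immigrants, `[[`, numeric(1L), "fitness"),
               decreasing = TRUE)
  for (imm in immigrants[ord]) {
    w <- which.min(st$fitness)
    if (imm$fitness > st$fitness[w]) {
      st$genomes[[w]] <- imm$genome
      st$phenos[w] <- imm$phenotype
      st$fitness[w] <- imm$fitness
      mp <- map_genome(imm$genome, st$grammar, st$control$max_wraps)
      st$used[w] <- mp$used
    } else break  # sorted: later immigrants cannot beat the new worst either
  }
  invisible(st)
}

#' Fit a glucose forecasting model by Grammatical Evolution
#'
#' Evolves a population of codon genomes mapped through `grammar` into
#' arithmetic forecasting expressions, maximising the weighted F1 of the
#' banded forecasts on `samples` ([model_fitness()]).  Generational loop
#' with tournament selection, one-point crossover, int-flip mutation and
#' elitism of one, so the best fitness is non-decreasing over generations.
#' Fully reproducible given `seed`.
#'
#' @param samples Training samples from [build_samples()] (filter with
#'   [sample_split()] first if the series carries a test segment).
#' @param grammar A `"ge_grammar"`; default [glucose_grammar()] sized from
#'   the sample attributes.
#' @param control A [ge_control()].
#' @param seed Optional integer seed.
#' @param hook Optional `function(state)` called after each generation's
#'   evaluation (the entry point used by the federated orchestrator).
#' @return Object of class `"ge_model"`: the best expression (`phenotype`),
#'   its `genome`, training `fitness`, per-generation best-fitness
#'   `history`, and the fitting configuration.
#' @seealso [predict.ge_model()], [flea_fit()]
#' @export
ge_fit <- function(samples, grammar = NULL, control = ge_control(),
                   seed = NULL, hook = NULL) {
  if (is.null(grammar))
    grammar <- glucose_grammar(k = attr(samples, "k") %||% 12,
                               h = attr(samples, "h") %||% 6)
  if (!is.null(seed)) set.seed(seed)
  st <- ea_new(samples, grammar, control)
  if (!is.null(hook)) hook(st)
  for (g in seq_len(control$generations)) {
    ea_step(st)
    if (!is.null(hook)) hook(st)
  }
  best <- .ea_best(st)
  structure(list(phenotype = best$phenotype, genome = best$genome,
                 fitness = best$fitness, history = st$history,
                 generations = st$generation, control = control,
                 grammar = grammar, n_train = nrow(samples),
                 patient_id = attr(samples, "patient_id")),
            class = "ge_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ge_model <- function(x, ...) {
  cat("Grammatical-evolution glucose forecasting model\n")
  if (!is.null(x$patient_id)) cat("  patient:", x$patient_id, "\n")
  cat("  formula: G(t+h*dt) =", x$phenotype, "\n")
  cat(sprintf("  training weighted F1: %.4f  (%d samples, %d generations)\n",
              x$fitness, x$n_train, x$generations))
  invisible(x)
}

#' @export
summary.ge_model <- function(object, ...) {
  cat("Best-so-far fitness trajectory (", length(object$history),
      " generations incl. initial):\n", sep = "")
  print(summary(object$history))
  print(object)
  invisible(object)
}

#' Forecast glucose values and glycemic classes
#'
#' @param object A `"ge_model"`.
#' @param newdata A `"ge_samples"` data frame.
#' @param ... Unused.
#' @return Data frame with `g_hat` (forecast mmol/L) and `class`
#'   (predicted band 0-6, `NA` for an invalid forecast).
#' @export
predict.ge_model <- function(object, newdata, ...) {
  ghat <- .eval_phenotype(.compile_phenotype(object$phenotype), newdata)
  data.frame(g_hat = ghat, class = band_or_na(ghat))
}

#' Score a fitted model on a sample set
#'
#' @param model A `"ge_model"` (or a phenotype string).
#' @param samples A `"ge_samples"` data frame.
#' @return A [score_report()].
#' @export
score_model <- function(model, samples) {
  pheno <- if (inherits(model, "ge_model")) model$phenotype else model
  pr <- band_or_na(.eval_phenotype(.compile_phenotype(pheno), samples))
  score_report(confusion_matrix(as.integer(samples$target_class), pr))
}

#' @export
plot.ge_model <- function(x, ...) {
  plot(seq_along(x$history) - 1L, x$history, type = "s",
       xlab = "generation", ylab = "best weighted F1",
       main = "GE fitness trajectory", ...)
  invisible(x)
}
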