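small_ge <- function(pop = 12, gen = 6) {
  ge_control(population_size = pop, generations = gen)
}

test_that("a single-slave federation equals an isolated run seed-for-seed", {
  cohort <- fast_cohort(1)
  fed <- flea_fit(cohort, flea_control(migration_interval = 2,
                                       ge = small_ge(), seed = 11))
  tr <- sample_split(build_samples(cohort[[1]]), "train")
  iso <- ge_fit(tr, control = small_ge(), seed = fed$slave_seeds[1])
  expect_identical(fed$models[[1]]$phenotype, iso$phenotype)
  expect_identical(fed$models[[1]]$history, iso$history)
  expect_equal(nrow(fed$message_log), 0)
})

test_that("disabling communication reproduces the isolated baseline exactly", {
  cohort <- fast_cohort(2)
  # interval beyond the generation count: no communication is possible
  a <- flea_fit(cohort, flea_control(migration_interval = 100,
                                     ge = small_ge(), mode = "flea",
                                     seed = 21))
  b <- flea_fit(cohort, flea_control(migration_interval = 2,
                                     ge = small_ge(), mode = "non_fl",
                                     seed = 21))
  expect_identical(lapply(a$models, `[[`, "phenotype"),
                   lapply(b$models, `[[`, "phenotype"))
  expect_identical(lapply(a$models, `[[`, "history"),
                   lapply(b$models, `[[`, "history"))
  expect_equal(a$cross_eval$scores, b$cross_eval$scores)
})

test_that("migration follows the message-count law and logs no sample data", {
  cohort <- fast_cohort(2)
  fit <- flea_fit(cohort, flea_control(migration_interval = 3,
                                       ge = small_ge(gen = 10), seed = 31))
  # floor(10 / 3) = 3 rounds, one inbound best per slave per round
  expect_equal(fit$n_migrations, 3)
  expect_equal(nrow(fit$message_log), 2 * 3)
  expect_equal(sort(unique(fit$message_log$generation)), c(3, 6, 9))
  # privacy contract: messages carry only id, generation, expression, score
  expect_named(fit$message_log,
               c("slave", "generation", "phenotype", "fitness"))
  expect_type(fit$message_log$phenotype, "character")
  # an expression string is a model, never a data vector
  expect_true(all(nchar(fit$message_log$phenotype) < 10000))
  # per-slave best fitness never decreases across a migration event
  for (m in fit$models) expect_true(all(diff(m$history) >= 0))
})

test_that("immigrant integration replaces the worst, strictly-better only", {
  tr <- fast_train()
  g <- glucose_grammar()
  set.seed(44)
  st <- gefed:::ea_new(tr, g, ge_control(population_size = 10,
                                         generations = 1))
  pre_fit <- sort(st$fitness)
  pre_best <- max(st$fitness)
  # immigrants worse than everyone: population unchanged
  worst_imm <- list(list(genome = st$genomes[[1]], phenotype = st$phenos[1],
                         fitness = -1))
  gefed:::ea_integrate(st, worst_imm)
  expect_equal(sort(st$fitness), pre_fit)
  # three immigrants better than the three worst: exactly three replacements
  imms <- lapply(1:3, function(i) {
    genome <- grow_genome(g, 6)
    m <- map_genome(genome, g)
    list(genome = genome, phenotype = m$phenotype,
         fitness = pre_best + i / 10)
  })
  gefed:::ea_integrate(st, imms)
  expect_equal(length(st$fitness), 10)            # size preserved
  expect_equal(sort(st$fitness, decreasing = TRUE)[1:3],
               pre_best + c(3, 2, 1) / 10)
  expect_gte(max(st$fitness), pre_best)           # best never decreases
  expect_equal(sum(!sort(st$fitness) %in% pre_fit), 3)
})

test_that("cross-evaluation margins agree with the aggregation rule", {
  cohort <- fast_cohort(2)
  test_sets <- lapply(lapply(cohort, build_samples), sample_split, "test")
  models <- list("g0", "(g0-0+0)*1")
  ce <- cross_evaluate(models, test_sets, ids = c("a", "b"))
  expect_equal(dim(ce$scores), c(2, 2))
  for (i in 1:2)
    expect_equal(ce$row_margin[i, ], aggregate_scores(ce$scores[i, ]))
  # identical patients give constant rows
  ce2 <- cross_evaluate(models, test_sets[c(1, 1)])
  expect_equal(ce2$scores[, 1], ce2$scores[, 2])
})

test_that("global-model selection picks the best published row means", {
  ref <- ohio_reference_scores()
  for (cfg in list(list(m = ref$nonfl, want = "570"),
                   list(m = ref$flea, want = "575"))) {
    ce <- structure(list(scores = cfg$m,
                         row_margin = t(apply(cfg$m, 1, aggregate_scores))),
                    class = "cross_eval_matrix")
    expect_equal(rownames(cfg$m)[select_global_model(ce)], cfg$want)
  }
  one <- structure(list(scores = matrix(0.5, 1, 3),
                        row_margin = matrix(c(0.5, 0), 1,
                                            dimnames = list(NULL,
                                                            c("mean", "sd")))),
                   class = "cross_eval_matrix")
  expect_equal(select_global_model(one), 1L)
})

test_that("the experiment driver compares arms on held-out patients", {
  learning <- fast_cohort(2, seed = 61)
  holdout <- fast_cohort(1, seed = 62)
  ex <- flea_experiment(learning, holdout,
                        flea_control(migration_interval = 3,
                                     ge = small_ge(pop = 10, gen = 6)),
                        seeds = c(1, 2))
  expect_equal(dim(ex$holdout_mean), c(2, 2))
  expect_true(all(ex$holdout_mean >= 0 & ex$holdout_mean <= 1))
  # result matrices are subjects x algorithms with no missing cells
  rm1 <- ex$result_matrix[[1]]
  expect_equal(ncol(rm1), 2)
  expect_equal(nrow(rm1), 3)  # 2 learning + 1 held-out subject
  expect_false(anyNA(rm1))
  # both arms share per-slave seeds within a master seed
  expect_identical(ex$fits[["flea_seed1"]]$slave_seeds,
                   ex$fits[["non_fl_seed1"]]$slave_seeds)
})
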