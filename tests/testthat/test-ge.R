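test_that("protected functions are total and match their definitions", {
  expect_equal(plog(0), 0)
  expect_equal(plog(exp(1) - 1), 1)
  expect_equal(plog(-(exp(1) - 1)), 1)
  expect_equal(psqrt(-4), 2)
  expect_equal(aq(3, 0), 3)
  expect_equal(aq(3, 4), 3 / sqrt(17))
  x <- runif(100, -1e6, 1e6)
  expect_true(all(is.finite(plog(x)) & is.finite(psqrt(x)) &
                    is.finite(aq(x, rev(x)))))
})

test_that("model predictions band forecasts and flag invalid outputs", {
  sam <- structure(data.frame(g0 = 6.0, g1 = 4.0, target_glucose = 6.0,
                              target_class = 3L),
                   class = c("ge_samples", "data.frame"))
  m <- structure(list(phenotype = "g0"), class = "ge_model")
  pr <- predict(m, sam)
  expect_equal(pr$g_hat, 6.0)
  expect_equal(pr$class, 3L)
  m2 <- structure(list(phenotype = "psqrt(g0)*g1"), class = "ge_model")
  expect_equal(predict(m2, sam)$g_hat, sqrt(6) * 4)
  # a zero or non-finite forecast is the sentinel invalid class
  m3 <- structure(list(phenotype = "g0-g0"), class = "ge_model")
  expect_true(is.na(predict(m3, sam)$class))
  m4 <- structure(list(phenotype = "g0/0"), class = "ge_model")
  expect_true(is.na(predict(m4, sam)$class))
})

test_that("fitness is the weighted F1 of banded forecasts", {
  tr <- fast_train()
  # an oracle that reproduces the target exactly is perfect
  oracle <- tr; oracle$target_glucose <- tr$g0
  oracle$target_class <- to_class(tr$g0)
  expect_equal(model_fitness("g0", oracle), 1.0)
  # constant expression: verify against hand-built confusion counts
  sam <- structure(data.frame(g0 = 1, target_glucose = c(6, 6, 6, 11, 3.5),
                              target_class = c(3L, 3L, 3L, 5L, 1L)),
                   class = c("ge_samples", "data.frame"))
  f <- model_fitness("6.0", sam)   # predicts class 3 always
  # class 3: tp=3 fp=2 fn=0 w=3/5; classes 5,1: tp=0 fn=1 fp=0 w=1/5
  expect_equal(f, 3 / 5 * binary_f1(3, 2, 0))
  # invalid phenotypes score 0
  expect_equal(model_fitness("(((", sam), 0)
  expect_error(model_fitness("g0", sam[0, ]), "empty")
})

test_that("random expressions never raise and never yield NaN fitness", {
  g <- glucose_grammar()
  tr <- fast_train()
  set.seed(17)
  for (i in 1:100) {
    m <- map_genome(grow_genome(g, 8), g)
    f <- model_fitness(m$phenotype, tr)
    expect_true(is.finite(f) && f >= 0 && f <= 1)
  }
})

test_that("tournament selection is elitist within the tournament", {
  set.seed(1)
  expect_equal(tournament_select(0.7, size = 4), 1)     # population of one
  fit <- c(0.1, 0.9, 0.3)
  expect_equal(tournament_select(fit, size = 50), 2)    # best always drawn
  # ties break to the earlier index
  expect_equal(tournament_select(c(0.5, 0.5), size = 10), 1)
  # selection pressure: top quartile picked more often than bottom
  fit <- seq(0, 1, length.out = 20)
  picks <- replicate(5000, tournament_select(fit, 4))
  expect_gt(sum(picks > 15), sum(picks <= 5))
})

test_that("one-point crossover copies at p=0 and recombines tails at p=1", {
  g1 <- 1:10; g2 <- 101:110
  set.seed(2)
  expect_identical(one_point_crossover(g1, g2, p = 0), list(g1, g2))
  for (i in 1:50) {
    ch <- one_point_crossover(g1, g2, p = 1)
    # each child is a prefix of one parent plus a suffix of the other
    ok1 <- any(vapply(0:10, function(c1) {
      pre <- g1[seq_len(c1)]
      length(ch[[1]]) >= c1 && identical(ch[[1]][seq_len(c1)], pre) &&
        all(ch[[1]][-seq_len(c1)] %in% g2)
    }, logical(1)))
    expect_true(ok1)
    # total codon count is conserved (no truncation here)
    expect_equal(length(ch[[1]]) + length(ch[[2]]), 20)
  }
})

test_that("int-flip mutation changes at most one codon", {
  g <- rep(5L, 50)
  set.seed(3)
  expect_identical(int_flip_mutation(g, p = 0), g)
  hits <- integer(50)
  for (i in 1:2000) {
    m <- int_flip_mutation(g, p = 1, codon_size = 100000L)
    d <- which(m != g)
    expect_lte(length(d), 1)
    if (length(d)) hits[d] <- hits[d] + 1
  }
  # each position mutated with frequency about 1/length
  expect_true(all(hits > 0))
  expect_lt(max(hits) / max(1, min(hits)), 3)
})

test_that("the EA is reproducible, monotone under elitism, and bounded", {
  tr <- fast_train()
  ctl <- ge_control(population_size = 20, generations = 8)
  f1 <- ge_fit(tr, control = ctl, seed = 5)
  f2 <- ge_fit(tr, control = ctl, seed = 5)
  expect_identical(f1$phenotype, f2$phenotype)
  expect_identical(f1$history, f2$history)
  expect_true(all(diff(f1$history) >= 0))          # elitism monotonicity
  expect_true(all(f1$history >= 0 & f1$history <= 1))
  # zero generations returns the best of the random initial population
  f0 <- ge_fit(tr, control = ge_control(population_size = 15,
                                        generations = 0), seed = 6)
  expect_equal(length(f0$history), 1)
  expect_equal(f0$generations, 0)
  # evolved phenotypes keep the grammar shape
  expect_match(f1$phenotype, "^\\(.+\\)[-+*].+$")
})
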