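test_that("the published twelve-subject comparison reproduces exactly", {
  m <- ohio_result_matrix()
  expect_equal(dim(m), c(12L, 2L))
  qt <- quade_test(m)
  expect_equal(round(qt$statistic, 5), 2.19188)
  expect_equal(round(unname(qt$ranks["flea"]), 5), 1.26923)
  expect_equal(round(unname(qt$ranks["non_fl"]), 5), 1.73077)
  expect_equal(round(qt$p.value, 5), 0.16680)
  ph <- quade_posthoc(qt, "flea")
  expect_equal(round(ph$comparisons$z, 5), 1.99692)
  adj <- unlist(ph$comparisons[c("bonferroni_dunn", "holm", "hochberg",
                                 "finner", "li")])
  expect_equal(round(unname(adj), 5), rep(0.04583, 5))
})

test_that("a three-block toy matrix matches the hand computation", {
  m <- cbind(a = c(3, 2, 10), b = c(1, 5, 2))
  qt <- quade_test(m)
  # ranges 2,3,8 -> Q = 1,2,3; within-ranks give S_a = -1, S_b = 1,
  # A = 7, B = 2/3, statistic = 2*(2/3)/(7 - 2/3)
  expect_equal(qt$statistic, 2 * (2 / 3) / (7 - 2 / 3))
  expect_equal(unname(qt$ranks), c(8 / 6, 10 / 6))
})

test_that("quade agrees with the independent base-R implementation", {
  set.seed(8)
  for (i in 1:20) {
    m <- matrix(runif(5 * 3), 5, 3)
    ours <- quade_test(m)
    ref <- stats::quade.test(m)
    expect_equal(unname(ours$statistic), unname(ref$statistic),
                 tolerance = 1e-12)
    expect_equal(unname(ours$p.value), unname(ref$p.value),
                 tolerance = 1e-12)
  }
})

test_that("rank conservation and column symmetry hold", {
  set.seed(9)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    m <- matrix(runif(6 * k), 6, k)
    qt <- quade_test(m)
    expect_equal(sum(qt$ranks), k * (k + 1) / 2)
  }
  m <- matrix(runif(12 * 2), 12, 2, dimnames = list(NULL, c("x", "y")))
  qt <- quade_test(m)
  qs <- quade_test(m[, 2:1])
  expect_equal(unname(qt$ranks["x"]), unname(qs$ranks["x"]))
  expect_equal(qt$statistic, qs$statistic)
  # the algorithm with more weighted wins ranks better (lower)
  better <- cbind(good = rep(1, 12), bad = runif(12, 0, 0.9))
  expect_lt(quade_test(better)$ranks["good"],
            quade_test(better)$ranks["bad"])
  expect_error(quade_test(matrix(0.5, 4, 2)), "tied")
})

test_that("post-hoc adjustments collapse at m=1 and respect Holm/Hochberg", {
  m <- matrix(runif(12 * 2), 12, 2, dimnames = list(NULL, c("x", "y")))
  ph <- quade_posthoc(quade_test(m), "x")
  row <- ph$comparisons
  expect_equal(row$bonferroni_dunn, row$p)
  expect_equal(row$holm, row$p)
  expect_equal(row$hochberg, row$p)
  expect_equal(row$finner, row$p)
  expect_equal(row$li, row$p)
  # multi-comparison case: check against brute-force step rules and
  # the independent p.adjust implementations
  set.seed(10)
  m4 <- matrix(runif(8 * 4), 8, 4,
               dimnames = list(NULL, c("ctrl", "b", "c", "d")))
  ph4 <- quade_posthoc(quade_test(m4), "ctrl")
  p <- ph4$comparisons$p
  expect_equal(ph4$comparisons$holm, as.numeric(p.adjust(p, "holm")))
  expect_equal(ph4$comparisons$hochberg, as.numeric(p.adjust(p, "hochberg")))
  expect_equal(ph4$comparisons$bonferroni_dunn,
               as.numeric(p.adjust(p, "bonferroni")))
  # Finner: step-down on 1-(1-p)^(m/i); brute force
  o <- order(p); ps <- p[o]; mm <- length(p)
  fin <- cummax(1 - (1 - ps)^(mm / seq_len(mm)))
  expect_equal(ph4$comparisons$finner[o], pmin(1, fin))
  # Li: p_i / (p_i + 1 - p_max)
  expect_equal(ph4$comparisons$li, p / (p + 1 - max(p)))
  # all adjusted >= raw, in [0, 1]
  adj <- as.matrix(ph4$comparisons[c("bonferroni_dunn", "holm", "hochberg",
                                     "finner", "li")])
  expect_true(all(adj >= p - 1e-12 & adj <= 1))
  expect_error(quade_posthoc(quade_test(m4), "nope"), "unknown control")
})

test_that("decisions use strict inequality at the significance level", {
  m <- ohio_result_matrix()
  ph <- quade_posthoc(quade_test(m), "flea")
  expect_true(all(decide(ph, 0.05)))          # 0.04583 < 0.05: reject
  expect_false(any(decide(ph, 0.04583)))      # p == alpha: retain
  expect_false(any(decide(ph, 0.01)))
  expect_error(decide(ph, 1.5), "alpha")
})

test_that("the test is calibrated under a column-exchangeable null", {
  set.seed(123)
  rej <- replicate(1000, {
    m <- matrix(rnorm(12 * 2), 12, 2)
    quade_test(m)$p.value < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})
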