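test_that("survival probability matches direct arithmetic and clamping", {
  # s*tau*ln2 / 2^(t-1) evaluated by hand
  expect_equal(survival_probability(10, 2, 25), 2 * 25 * log(2) / 2^9)
  expect_lt(survival_probability(10, 2, 25), 0.10)
  # neutral lineages have vanishing survival under the approximation
  expect_identical(survival_probability(1, 0, 25), 0)
  # early strong mutants clamp at 1; raw value recoverable
  expect_identical(survival_probability(1, 0.5, 4), 1)
  expect_equal(survival_probability(1, 0.5, 4, clamp = FALSE),
               0.5 * 4 * log(2))
  expect_equal(extinction_probability(10, 2, 25),
               1 - 2 * 25 * log(2) / 2^9)
})

test_that("domain errors are raised for invalid survival queries", {
  expect_error(survival_probability(0, 1, 25), "t")
  expect_error(survival_probability(26, 1, 25), "tau")
  expect_error(survival_probability(5, -0.1, 25), "non-negative")
  expect_error(survival_probability(2.5, 1, 25), "integer")
  expect_error(required_selection_coefficient(5, 0, 25), "pi_target")
  expect_error(required_selection_coefficient(5, 1.2, 25), "pi_target")
})

test_that("required selection coefficient inverts the survival formula", {
  expect_equal(required_selection_coefficient(8, 1, 25), 128 / (25 * log(2)))
  # round trip at arbitrary targets
  for (t in c(1, 5, 12)) {
    for (pi in c(0.05, 0.3, 1)) {
      s <- required_selection_coefficient(t, pi, 25)
      expect_equal(survival_probability(t, s, 25, clamp = FALSE), pi)
    }
  }
  # s -> 0 as the target probability -> 0
  expect_lt(required_selection_coefficient(1, 1e-12, 25), 1e-11)
})

test_that("survival probabilities stay in [0,1] and are monotone", {
  set.seed(11)
  for (rep in 1:200) {
    tau <- sample(c(4L, 25L, sample(1:40, 1)), 1)
    t <- sample.int(tau, 1)
    s <- stats::rexp(1, rate = 0.5)
    p <- survival_probability(t, s, tau)
    expect_gte(p, 0)
    expect_lte(p, 1)
  }
  # monotone non-decreasing in s and tau, non-increasing in t (raw scale)
  s_grid <- seq(0, 3, by = 0.25)
  t_grid <- 1:20
  for (tau in c(4L, 25L)) {
    tt <- t_grid[t_grid <= tau]
    p_s <- survival_probability(5, s_grid, tau = 25, clamp = FALSE)
    expect_true(all(diff(p_s) >= 0))
    p_t <- survival_probability(tt, 1, tau, clamp = FALSE)
    expect_true(all(diff(p_t) <= 0))
  }
  expect_true(all(survival_probability(1:4, 1, 25, clamp = FALSE) <=
                    survival_probability(1:4, 1, 30, clamp = FALSE)))
})

test_that("survival surface evaluates the pointwise formula on the grid", {
  one <- survival_surface(10, 2, tau = 25)
  expect_equal(dim(one$survival), c(1L, 1L))
  expect_equal(one$survival[1, 1], survival_probability(10, 2, 25))

  surf <- survival_surface(1:25, c(0.25, 0.5, 1, 2, 6), tau = 25)
  expect_true(all(surf$survival >= 0 & surf$survival <= 1))
  # rows: non-decreasing along s; columns: non-increasing along t
  expect_true(all(apply(surf$survival, 1, function(r) all(diff(r) >= 0))))
  expect_true(all(apply(surf$survival, 2, function(cl) all(diff(cl) <= 0))))
  # spot check against scalar evaluation
  expect_equal(surf$survival[7, 3], survival_probability(7, 1, 25))

  df <- as.data.frame(surf)
  expect_equal(nrow(df), 25 * 5)
  expect_equal(df$survival[df$t == 10 & df$s == 2],
               survival_probability(10, 2, 25))
  expect_error(survival_surface(integer(0), 1, 25), "non-empty")
})
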