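test_that("median dichotomization labels strictly-below-median days improved", {
  d <- dichotomize_outcome(c(2, 3, 5, 5, 7))
  expect_equal(which(d$improved), c(1, 2))
  expect_equal(d$median, 5)
  d2 <- dichotomize_outcome(c(0, 10))
  expect_equal(which(d2$improved), 1)
  expect_error(dichotomize_outcome(c(1, 1, 1, 1)), "degenerate")
  # median equal to the minimum leaves the improved class empty
  d3 <- dichotomize_outcome(c(1, 1, 1, 2))
  expect_equal(d3$n_improved, 0)
})

test_that("candidate cutpoints are midpoints between distinct values", {
  expect_equal(enumerate_cutpoints(c(1, 2, 3, 4)), c(1.5, 2.5, 3.5))
  expect_equal(enumerate_cutpoints(c(5, 5, 5, 9)), 7)
  expect_error(enumerate_cutpoints(3), "no candidate")
})

test_that("a perfectly separated instance yields the obvious rule", {
  m <- fit_cutpoint_model(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE),
                          min_per_class = 1)
  expect_equal(m$direction, "le_improves")
  expect_equal(m$cutpoint, 2.5)
  expect_equal(m$mean_sensitivity, 1)
  expect_equal(m$ess, 100)
  # inverting labels flips the direction but keeps the cutpoint
  mi <- fit_cutpoint_model(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE),
                           min_per_class = 1)
  expect_equal(mi$direction, "ge_improves")
  expect_equal(mi$cutpoint, 2.5)
  expect_error(fit_cutpoint_model(1:10, rep(c(TRUE, FALSE), 5),
                                  min_per_class = 6), "insufficient class")
})

test_that("the fitted rule matches the brute-force scorer on random instances", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(10:30, 1)
    x <- sample(1:8, n, replace = TRUE)  # ties guaranteed
    improved <- runif(n) < 0.45
    if (sum(improved) < 2 || sum(!improved) < 2 ||
        length(unique(x)) < 2) next
    m <- fit_cutpoint_model(x, improved, min_per_class = 2)
    o <- oracle_fit(x, improved)
    expect_equal(m$mean_sensitivity, o$m, tolerance = 1e-12)
    expect_equal(m$cutpoint, o$cut)
    expect_equal(m$direction,
                 if (o$dir == "le") "le_improves" else "ge_improves")
    expect_equal(m$sens_improved, o$s1)
    expect_equal(m$sens_not_improved, o$s0)
  }
})

test_that("exact permutation p equals full enumeration", {
  x <- 1:8
  improved <- c(rep(TRUE, 4), rep(FALSE, 4))
  expect_equal(permutation_p_value(x, improved, method = "exact"), 2 / 70)
  set.seed(7)
  for (i in 1:10) {
    n <- sample(8:11, 1)
    x <- sample(1:5, n, replace = TRUE)
    improved <- runif(n) < 0.5
    if (sum(improved) < 2 || sum(!improved) < 2 ||
        length(unique(x)) < 2) next
    expect_equal(permutation_p_value(x, improved, method = "exact"),
                 oracle_exact_p(x, improved), tolerance = 1e-12)
  }
})

test_that("Monte Carlo permutation is seeded-deterministic and in (0, 1]", {
  x <- c(1, 2, 2, 3, 4, 5, 5, 6, 7, 8)
  improved <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE,
                FALSE, FALSE, TRUE, FALSE)
  p1 <- permutation_p_value(x, improved, method = "monte_carlo",
                            reps = 5000, seed = 31)
  p2 <- permutation_p_value(x, improved, method = "monte_carlo",
                            reps = 5000, seed = 31)
  expect_identical(p1, p2)
  expect_gt(p1, 0)
  expect_lte(p1, 1)
})

test_that("requesting exact enumeration beyond the bound is an error", {
  x <- rnorm(50)
  improved <- rep(c(TRUE, FALSE), 25)
  expect_error(permutation_p_value(x, improved, method = "exact"),
               "too large")
})

test_that("oda_test wires dichotomization, fit and significance together", {
  u <- make_planted_user(n = 60, seed = 5)
  ps <- extract_paired_series(u, "bed_time", "pain")
  m <- oda_test(ps$x, ps$rating, seed = 9,
                attribute_id = "bed_time", symptom_id = "pain")
  expect_equal(m$direction, "le_improves")
  expect_true(m$significant)
  expect_lte(m$p_value, 0.05)
  expect_equal(m$n_pairs, 60)
})
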