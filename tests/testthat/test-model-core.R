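test_that("parameter constructors enforce their bounds", {
  expect_error(sigmoid_params(-1, 10, 4, 0), "range")
  expect_error(sigmoid_params(100, -1, 4, 0), "slope")
  expect_error(sigmoid_params(100, 10, 11, 0), "x_offset")
  expect_error(sigmoid_params(100, 10, 4, 200), "y_offset")
  expect_error(sigmoid_params(NaN, 10, 4, 0), "finite")
  sp <- sigmoid_params(100, 10, 4, 0)
  expect_error(reuse_model(sp, 1.2), "reuse")
  expect_error(reuse_model(sp, -0.1), "reuse")
})

test_that("optimal_angle matches the closed form and its stated geometry", {
  sp <- sigmoid_params(133.3, 39.4, 4.4, 17.2)
  # inflection returns the y-offset
  expect_equal(optimal_angle(sp, 4.4), 17.2)
  # flat curve limit
  flat <- sigmoid_params(0, 0, 4.4, 10)
  expect_equal(optimal_angle(flat, 9), 10)
  # closed-form oracle at an off-inflection drawer
  expect_equal(optimal_angle(sp, 9),
               oracle_sigmoid(133.3, 39.4, 4.4, 17.2, 9), tolerance = 1e-12)
  # derivative at the inflection equals the slope parameter
  h <- 1e-6
  num_deriv <- (optimal_angle(sp, 4.4 + h) - optimal_angle(sp, 4.4 - h)) / (2 * h)
  expect_equal(num_deriv, 39.4, tolerance = 1e-5)
  # output bounded by the asymptotes
  d <- seq(-50, 50, length.out = 201)
  a <- optimal_angle(sp, d)
  expect_true(all(a >= 17.2 - 133.3 / 2 & a <= 17.2 + 133.3 / 2))
  expect_error(optimal_angle(sp, Inf), "finite")
})

test_that("blend reproduces the worked reuse example and stays between its inputs", {
  expect_equal(blend(74.0, 40.0, 0.30), 50.2, tolerance = 1e-12)
  expect_equal(blend(74.0, 40.0, 1.0), 74.0)
  expect_equal(blend(74.0, 40.0, 0.0), 40.0)
  expect_error(blend(74, 40, 1.5), "reuse")
  expect_error(blend(74, 40, -0.1), "reuse")
  set.seed(11)
  for (i in 1:50) {
    p <- rnorm(1, 0, 60); o <- rnorm(1, 0, 60); u <- runif(1)
    b <- blend(p, o, u)
    expect_true(b >= min(p, o) - 1e-12 && b <= max(p, o) + 1e-12)
  }
})

test_that("simulate_sequence follows the reuse recursion", {
  m <- reuse_model(sigmoid_params(120, 35, 4.5, 10), 0)
  d <- c(3, 7, 1, 9, 5)
  expect_equal(simulate_sequence(m, d), optimal_angle(m$sigmoid, d))
  m1 <- reuse_model(m$sigmoid, 1)
  expect_equal(simulate_sequence(m1, d),
               rep(optimal_angle(m$sigmoid, 3), 5))
  # drawer #6 -> #5 demonstration: previous 74.0, optimal 40.0, 30% reuse
  demo <- reuse_model(demo_sigmoid(), 0.30)
  expect_equal(simulate_sequence(demo, c(6, 5)), c(74.0, 50.2),
               tolerance = 1e-9)
  # a custom starting posture overrides the optimal first trial
  expect_equal(simulate_sequence(demo, c(6, 5), first_trial = 80)[1], 80)
})

test_that("simulate_sequence agrees with a naive loop on random draws", {
  set.seed(202)
  for (i in 1:100) {
    rg <- runif(1, 0, 200); sl <- runif(1, 0, 80)
    x0 <- runif(1, 0, 10); y0 <- runif(1, -90, 90); u <- runif(1)
    d <- sample(1:9, sample(2:9, 1))
    got <- simulate_sequence(reuse_model(sigmoid_params(rg, sl, x0, y0), u), d)
    expect_equal(got, oracle_sequence(rg, sl, x0, y0, u, d), tolerance = 1e-12)
  }
})

test_that("simulated angles stay within the sigmoid asymptotes", {
  set.seed(7)
  for (i in 1:50) {
    rg <- runif(1, 1, 200); sl <- runif(1, 0, 80)
    x0 <- runif(1, 0, 10); y0 <- runif(1, -90, 90); u <- runif(1)
    a <- simulate_sequence(reuse_model(sigmoid_params(rg, sl, x0, y0), u),
                           sample(1:9, 9))
    expect_true(all(a >= y0 - rg / 2 - 1e-9 & a <= y0 + rg / 2 + 1e-9))
  }
})

test_that("descending-pass angles are non-decreasing in the reuse fraction", {
  sp <- sigmoid_params(130, 40, 4.4, 16)
  reuses <- seq(0, 1, by = 0.05)
  sims <- sapply(reuses, function(u)
    simulate_sequence(reuse_model(sp, u), sequence_spec(9:1, "descending")))
  for (trial in 2:9)
    expect_true(all(diff(sims[trial, ]) >= -1e-12))
})

test_that("predict_task yields zero effect without reuse and positive effect with it", {
  sp <- sigmoid_params(131.9, 41.2, 4.4, 16.5)
  p0 <- predict_task(reuse_model(sp, 0), task_spec("ordered"))
  expect_identical(p0$mean_effect, 0)
  asc <- p0$profile$angle[p0$profile$direction == "ascending"]
  des <- p0$profile$angle[p0$profile$direction == "descending"]
  expect_equal(asc, des)
  p <- predict_task(reuse_model(sp, 0.156), task_spec("ordered"))
  expect_true(p$mean_effect > 0)
  expect_true(all(p$per_drawer_effect >= 0))
  expect_error(predict_task(reuse_model(sp, 0.1), task_spec("randomized")),
               "randomized")
})

test_that("two-drawer task reduces to the closed-form effect", {
  sp <- sigmoid_params(150, 50, 5, 0)
  u <- 0.5
  # two-drawer task outside the named designs
  tk <- structure(list(name = "custom2", drawer_set = c(1L, 9L),
                       n_repetitions = 1L), class = "task_spec")
  p <- predict_task(reuse_model(sp, u), tk)
  expected <- u * (optimal_angle(sp, 9) - optimal_angle(sp, 1))
  expect_equal(p$mean_effect, expected, tolerance = 1e-12)
})

test_that("skipping drawers increases the predicted hysteresis effect", {
  m <- reuse_model(sigmoid_params(131.9, 41.2, 4.4, 16.5), 0.156)
  skipped <- predict_task(m, task_spec("skipped"))$mean_effect
  ordered <- predict_task(m, task_spec("ordered"))$profile
  odd <- ordered$drawer %in% c(1, 3, 5, 7, 9)
  asc <- ordered$angle[ordered$direction == "ascending" & odd]
  des <- ordered$angle[ordered$direction == "descending" & odd]
  expect_true(skipped > mean(des - asc))
  # cross-check the skipped recursion against the independent loop
  or_asc <- oracle_sequence(131.9, 41.2, 4.4, 16.5, 0.156, c(1, 3, 5, 7, 9))
  or_des <- oracle_sequence(131.9, 41.2, 4.4, 16.5, 0.156, c(9, 7, 5, 3, 1))
  expect_equal(skipped, mean(rev(or_des) - or_asc), tolerance = 1e-12)
})

test_that("cost curves are convex with the argmin at the analytic optimum", {
  grid <- seq(0, 1, by = 0.001)
  sym <- cost_curves(grid, 1, 1, exponent = 2)
  expect_equal(sym$argmin_reuse, 0.5)
  expect_true(all(diff(sym$cognitive) <= 0))
  expect_true(all(diff(sym$mechanical) >= 0))
  heavier_mech <- cost_curves(grid, 0.4, 0.6, exponent = 2)
  expect_true(heavier_mech$argmin_reuse < 0.5)
  expect_equal(heavier_mech$argmin_reuse, oracle_cost_argmin(0.4, 0.6, 2),
               tolerance = 1e-3)
  expect_equal(cost_curves(grid, 0.3, 0.7, exponent = 3)$argmin_reuse,
               oracle_cost_argmin(0.3, 0.7, 3), tolerance = 1e-3)
  expect_error(cost_curves(grid, 1, 1, exponent = 1), "exponent")
  expect_error(cost_curves(grid, 0, 0), "weight")
})

test_that("sequence and task specs validate their structure", {
  expect_error(sequence_spec(integer(0)), "non-empty")
  expect_error(sequence_spec(c(1, 10)), "1..9")
  expect_error(sequence_spec(c(1, 3, 2), "ascending"), "increasing")
  expect_error(sequence_spec(c(5, 7), "descending"), "decreasing")
  expect_error(task_spec("skipped", drawer_set = 1:9), "1, 3, 5, 7, 9")
  expect_identical(task_spec("skipped")$drawer_set, c(1L, 3L, 5L, 7L, 9L))
})
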