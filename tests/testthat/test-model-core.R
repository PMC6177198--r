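test_that("the Fermi function has the logistic signature", {
  g <- fermi_function()
  expect_equal(g$evaluate(0), 0.5)
  expect_equal(g$derivative_at_zero, 0.25)
  expect_equal(g$second_derivative_at_zero, 0)
  # antisymmetry g(x) + g(-x) = 1 on a grid
  xs <- seq(-10, 10, by = 0.5)
  expect_equal(vapply(xs, g$evaluate, numeric(1)) +
                 vapply(-xs, g$evaluate, numeric(1)),
               rep(1, length(xs)))
  expect_true(validate_decision_function(g))
  expect_true(validate_decision_function(steep_logistic()))
})

test_that("decision-function axiom violations are caught", {
  bounded_wrong <- decision_function(function(x) pmin(pmax(x, -0.1), 1.1),
                                     derivative_at_zero = 1,
                                     second_derivative_at_zero = 0)
  expect_error(validate_decision_function(bounded_wrong), "strictly in")
  not_increasing <- decision_function(function(x) 0.5 + 0.4 * sin(x),
                                      derivative_at_zero = 0.4,
                                      second_derivative_at_zero = 0)
  expect_error(validate_decision_function(not_increasing), "increasing")
  expect_error(decision_function(identity, derivative_at_zero = -1,
                                 second_derivative_at_zero = 0),
               "positive")
})

test_that("switch_probability applies g(beta * (aspiration - payoff))", {
  g <- fermi_function()
  # beta = 0: blind switching at g(0) = 1/2 regardless of e and pi
  for (e in c(-3, 0, 10)) {
    expect_equal(switch_probability(g, 0, e, runif(1, -5, 5)), 0.5)
  }
  # zero argument through e = pi
  expect_equal(switch_probability(g, 1, 2, 2), 0.5)
  # direct evaluation: g(0.05 * (1 - 0)) = 1 / (1 + exp(-0.05))
  expect_equal(switch_probability(g, 0.05, 1, 0), 1 / (1 + exp(-0.05)))
  expect_error(switch_probability(g, -0.1, 1, 0), "nonnegative")
})

test_that("aspiration samplers reproduce their distributions", {
  # homogeneous: constant profile
  prof <- sample_aspirations(5, "homogeneous", value = 2)
  expect_equal(prof$e, rep(2, 5))

  # uniform support and argument checking
  u <- sample_aspirations(2000, "uniform", lo = 0, hi = 1, seed = 1)
  expect_true(all(u$e >= 0 & u$e <= 1))
  expect_error(sample_aspirations(10, "uniform", lo = 2, hi = 1), "below")
  expect_error(sample_aspirations(10, "cauchy"))

  # power law f(x) = 2 x^-3: minimum draw is 1, empirical CDF matches
  # F(x) = 1 - x^-2 (Kolmogorov-Smirnov at alpha = 0.01), median near sqrt(2)
  pl <- sample_aspirations(1e5, "powerlaw", seed = 2)
  expect_gte(min(pl$e), 1)
  ks <- suppressWarnings(
    stats::ks.test(pl$e, function(q) ifelse(q < 1, 0, 1 - q^-2)))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(stats::median(pl$e) - sqrt(2)), 0.02)

  # bimodal mixture mean 0.4*2.5 + 0.6*4.5 = 3.7 (mixture SD ~ 1.1)
  bm <- sample_aspirations(1e5, "bimodal", seed = 3)
  expect_lt(abs(mean(bm$e) - 3.7), 3 * 1.1 / sqrt(1e5))

  # seeding reproduces draws exactly
  expect_equal(sample_aspirations(50, "powerlaw", seed = 9)$e,
               sample_aspirations(50, "powerlaw", seed = 9)$e)
})

test_that("aspiration CSV round-trips and rejects malformed tables", {
  prof <- sample_aspirations(100, "uniform", lo = 0, hi = 5, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  save_aspirations(prof, path)
  back <- load_aspirations(path)
  expect_equal(back$n, 100)
  expect_equal(back$e, prof$e)
  expect_identical(back$source, "file")

  # duplicate index
  df <- data.frame(individual_index = c(1, 2, 2), aspiration = c(1, 2, 3))
  bad <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, bad, row.names = FALSE)
  expect_error(load_aspirations(bad), "unique")

  # gap in indices
  df2 <- data.frame(individual_index = c(1, 3), aspiration = c(1, 2))
  bad2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df2, bad2, row.names = FALSE)
  expect_error(load_aspirations(bad2), "no gaps")
})
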