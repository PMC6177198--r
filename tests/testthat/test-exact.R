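test_that("the transition matrix is a lazy single-flip stochastic matrix", {
  r4 <- make_ring(4)
  prof <- sample_aspirations(4, "uniform", lo = 0, hi = 5, seed = 1)
  ch <- build_chain(r4, reference_game(), prof, fermi_function(), beta = 0.05)
  P <- ch$P
  expect_lt(max(abs(Matrix::rowSums(P) - 1)), 1e-12)
  off <- P - Matrix::Diagonal(nrow(P), Matrix::diag(P))
  expect_lte(max(off), 1 / 4 + 1e-15)
  expect_true(all(ch$kappa >= 0))
  expect_equal(sum(ch$kappa), 1, tolerance = 1e-12)
  # stationarity residual
  expect_lt(max(abs(as.numeric(ch$kappa %*% P) - ch$kappa)), 1e-10)

  # spot-check: state (A,B,B,B) flipping individual 1, whose payoff is
  # a_0 = 3; the transition carries probability g(beta*(e_1 - 3)) / N
  s_from <- 1L + 1L  # state bits 0001 -> row 2
  s_to <- 0L + 1L    # flip of bit 1 -> all-B state, row 1
  expect_equal(P[s_from, s_to],
               stats::plogis(0.05 * (prof$e[1] - 3)) / 4)
})

test_that("beta = 0 makes the chain independent of payoffs and aspirations", {
  r4 <- make_ring(4)
  p1 <- sample_aspirations(4, "uniform", lo = -5, hi = 5, seed = 2)
  p2 <- sample_aspirations(4, "powerlaw", seed = 3)
  c1 <- build_chain(r4, reference_game(), p1, fermi_function(), beta = 0)
  c2 <- build_chain(r4, flat_table(7), p2, fermi_function(), beta = 0)
  expect_equal(as.matrix(c1$P), as.matrix(c2$P))
})

test_that("the stationary solve is confirmed by the dense eigenvector route", {
  r6 <- make_ring(6)
  prof <- sample_aspirations(6, "uniform", lo = 0, hi = 5, seed = 4)
  ch <- build_chain(r6, reference_game(), prof, fermi_function(), beta = 0.2)
  kappa_eig <- aspidyn:::stationary_eigen(ch$P)
  expect_lt(max(abs(ch$kappa - kappa_eig)), 1e-10)
})

test_that("abundance is exactly one half in the neutral cases", {
  # vanishing selection, any structure kind, heterogeneous aspirations and
  # even heterogeneous decision functions
  prof6 <- sample_aspirations(6, "uniform", lo = -5, hi = 5, seed = 5)
  g_mix <- c(rep(list(fermi_function()), 3), rep(list(steep_logistic()), 3))
  for (st in list(make_ring(6), make_well_mixed(6), make_complete(6))) {
    expect_equal(exact_x(st, reference_game(), prof6, beta = 0, g = g_mix), 0.5,
                 tolerance = 1e-10)
  }
  # equal payoff entries at any selection intensity (neutral-mutant case);
  # aspirations on the simulation range [0, 5] keep every flip probability
  # far enough from 0 for the stationary solve to stay well conditioned
  prof_pos <- sample_aspirations(6, "uniform", lo = 0, hi = 5, seed = 15)
  for (beta in c(0.1, 1, 5)) {
    expect_equal(exact_x(make_ring(6), flat_table(2), prof_pos, beta = beta,
                         g = g_mix),
                 0.5, tolerance = 1e-10)
  }
  # far outside that regime the solver detects near-reducibility and warns
  expect_warning(exact_x(make_ring(6), flat_table(2),
                         aspiration_profile(c(-40, rep(2, 5))), beta = 5),
                 "reducible")
  # averaged payoff scheme inherits both neutrality results
  expect_equal(exact_x(make_ring(6), flat_table(2), prof6, beta = 1,
                       scheme = "averaged_d_games"),
               0.5, tolerance = 1e-10)
})

test_that("the first-order abundance derivative ignores aspirations", {
  tab <- reference_game()
  r6 <- make_ring(6)
  ders <- vapply(1:20, function(s) {
    prof <- sample_aspirations(6, "uniform", lo = -5, hi = 5, seed = s)
    abundance_derivative(r6, tab, prof)
  }, numeric(1))
  expect_lt(max(ders) - min(ders), 1e-6)
  # flat games have a flat abundance curve
  prof <- sample_aspirations(6, "uniform", lo = -5, hi = 5, seed = 21)
  expect_lt(abs(abundance_derivative(r6, flat_table(3), prof)), 1e-6)
})

test_that("the derivative sign is predicted by the sigma-weighted criterion", {
  r6 <- make_ring(6)
  prof <- sample_aspirations(6, "uniform", lo = 0, hi = 5, seed = 6)
  set.seed(7)
  for (i in 1:50) {
    tab <- payoff_table(runif(3, -2, 2), runif(3, -2, 2))
    lhs <- criterion_lhs(tab)
    if (abs(lhs) < 1e-9) next
    der <- abundance_derivative(r6, tab, prof)
    expect_equal(sign(der), sign(lhs))
  }
})

test_that("numerically derived coefficients recover the binomial pattern", {
  for (st in list(make_ring(8), make_well_mixed(8))) {
    sig <- derive_sigma_numeric(st)
    expect_equal(sig$sigma, c(1, 2, 1), tolerance = 1e-3)
    expect_true(all(sig$sigma >= 0))
    expect_equal(sig$sigma, rev(sig$sigma), tolerance = 1e-6)  # palindrome
  }
  # the averaged payoff accumulation preserves the coefficients on the ring
  sig_av <- derive_sigma_numeric(make_ring(8),
                                 payoff_scheme = "averaged_d_games")
  expect_equal(sig_av$sigma, c(1, 2, 1), tolerance = 1e-3)
})

test_that("the enumeration cap and structural preconditions are enforced", {
  prof <- sample_aspirations(16, "homogeneous")
  expect_error(build_chain(make_ring(16), reference_game(), prof,
                           fermi_function(), beta = 0),
               "cap")
  ba <- make_random_graph(10, "barabasi_albert", m = 2, seed = 8)
  prof10 <- sample_aspirations(10, "uniform", lo = 0, hi = 5, seed = 9)
  # non-regular networks are exact for the single-game scheme (the coplayer
  # draw is marginalised) and neutrality holds there too ...
  expect_equal(exact_x(ba, reference_game(), prof10, beta = 0), 0.5,
               tolerance = 1e-10)
  # ... but the averaged accumulation is only defined on regular structures
  expect_error(build_chain(ba, reference_game(), prof10, fermi_function(),
                           beta = 0.05, payoff_scheme = "averaged_d_games"),
               "regular")
})
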