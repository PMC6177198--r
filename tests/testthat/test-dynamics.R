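test_that("single-game focal payoffs follow the payoff table", {
  tab <- reference_game()
  r4 <- make_ring(4)
  # ring degree 2 = d-1, so the coplayer draw is deterministic
  state <- c(1L, 0L, 0L, 0L)
  # focal 1 plays A against two B coplayers: a_0 = 3
  expect_equal(focal_payoff_single(r4, state, tab, 1), 3)
  # focal 2 plays B against coplayers (A, B): b_1 = 1
  expect_equal(focal_payoff_single(r4, state, tab, 2), 1)
  # all-A state forces k = d-1 for any focal
  expect_equal(focal_payoff_single(r4, rep(1L, 4), tab, 3), tab$a[3])
})

test_that("averaged payoffs combine the d games the focal joins", {
  tab <- reference_game()
  r4 <- make_ring(4)
  # homogeneous states: every game gives the same entry
  expect_equal(focal_payoff_averaged(r4, rep(0L, 4), tab, 2), 4)  # b_0
  expect_equal(focal_payoff_averaged(r4, rep(1L, 4), tab, 2), 1)  # a_2
  # state (A,B,B,B) on the 4-ring, focal = 2 (a B-player):
  #   own game, coplayers {1,3}: k=1 -> b_1 = 1
  #   game by 1, coplayers {1,4}: k=1 -> b_1 = 1
  #   game by 3, coplayers {3,4}: k=0 -> b_0 = 4
  expect_equal(focal_payoff_averaged(r4, c(1L, 0L, 0L, 0L), tab, 2),
               (1 + 1 + 4) / 3)
  # the focal A-player sees only B coplayers in all three games
  expect_equal(focal_payoff_averaged(r4, c(1L, 0L, 0L, 0L), tab, 1), 3)
  expect_error(focal_payoff_averaged(make_well_mixed(10), rep(0L, 10), tab, 1),
               "regular")
})

test_that("one elementary step changes at most one strategy", {
  tab <- reference_game()
  r <- make_ring(12)
  prof <- sample_aspirations(12, "uniform", lo = 0, hi = 5, seed = 1)
  cfg <- sim_config(beta = 0.5, n_steps = 10, burn_in = 0)
  set.seed(2)
  state <- rep(0L, 12)
  for (i in 1:100) {
    nxt <- step_chain(r, state, tab, prof, fermi_function(), cfg)
    expect_lte(sum(nxt != state), 1)
    state <- nxt
  }
})

test_that("a satisfied individual essentially never switches under strong selection", {
  # aspirations far below every payoff, large beta: flip probabilities are
  # logistic tails ~ exp(-beta * (pi - e)) ~ 0
  tab <- reference_game()
  r <- make_ring(10)
  prof <- aspiration_profile(rep(-100, 10))
  cfg <- sim_config(beta = 10, n_steps = 10, burn_in = 0)
  set.seed(3)
  state <- rep(1L, 10)
  for (i in 1:200) state <- step_chain(r, state, tab, prof, fermi_function(), cfg)
  expect_equal(state, rep(1L, 10))
})

test_that("neutral settings give abundance one half", {
  r <- make_ring(30)
  prof <- sample_aspirations(30, "uniform", lo = -5, hi = 5, seed = 4)
  # equal payoff entries, strong selection
  cfg <- sim_config(beta = 1, n_steps = 4e5, burn_in = 4e4, seed = 5)
  res <- run_chain(r, flat_table(), prof, fermi_function(), cfg)
  expect_lt(abs(res$mean_abundance_A - 0.5), 3 * res$std_error)
  # vanishing selection, non-neutral game
  cfg0 <- sim_config(beta = 0, n_steps = 4e5, burn_in = 4e4, seed = 6)
  res0 <- run_chain(r, reference_game(), prof, fermi_function(), cfg0)
  expect_lt(abs(res0$mean_abundance_A - 0.5), 3 * res0$std_error)
})

test_that("Monte Carlo agrees with the exact stationary abundance", {
  r6 <- make_ring(6)
  prof <- sample_aspirations(6, "uniform", lo = 0, hi = 5, seed = 7)
  tab <- reference_game()
  for (beta in c(0, 0.05, 0.5)) {
    truth <- exact_x(r6, tab, prof, beta)
    cfg <- sim_config(beta = beta, n_steps = 2e6, burn_in = 2e5,
                      seed = 100 + round(100 * beta))
    res <- run_chain(r6, tab, prof, fermi_function(), cfg)
    expect_lt(abs(res$mean_abundance_A - truth), 4 * res$std_error)
  }
})

test_that("the pure-R update loop matches the exact solver", {
  # non-Fermi, heterogeneous decision functions route through the R loop
  r <- make_ring(6)
  prof <- sample_aspirations(6, "uniform", lo = 0, hi = 5, seed = 8)
  g_list <- c(rep(list(steep_logistic()), 3), rep(list(fermi_function()), 3))
  truth <- exact_x(r, reference_game(), prof, beta = 0.3, g = g_list)
  cfg <- sim_config(beta = 0.3, n_steps = 3e5, burn_in = 3e4, seed = 9)
  res <- run_chain(r, reference_game(), prof, g_list, cfg)
  expect_lt(abs(res$mean_abundance_A - truth), 4 * res$std_error)
})

test_that("relabelling the strategies mirrors the abundance", {
  r <- make_ring(8)
  prof <- sample_aspirations(8, "uniform", lo = 0, hi = 5, seed = 10)
  tab <- reference_game()
  x <- exact_x(r, tab, prof, beta = 0.3)
  x_swapped <- exact_x(r, swap_strategies(tab), prof, beta = 0.3)
  expect_equal(x + x_swapped, 1, tolerance = 1e-12)
})

test_that("the chain is ergodic: all-A and all-B starts converge together", {
  r <- make_ring(20)
  prof <- sample_aspirations(20, "uniform", lo = 0, hi = 5, seed = 11)
  tab <- reference_game()
  cfg <- function(s) sim_config(beta = 0.05, n_steps = 1e6, burn_in = 2e5,
                                seed = s)
  up <- run_chain(r, tab, prof, fermi_function(), cfg(12),
                  init_state = rep(1L, 20))
  down <- run_chain(r, tab, prof, fermi_function(), cfg(13),
                    init_state = rep(0L, 20))
  joint_se <- sqrt(up$std_error^2 + down$std_error^2)
  expect_lt(abs(up$mean_abundance_A - down$mean_abundance_A), 4 * joint_se)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(beta = -1, n_steps = 100), "nonnegative")
  expect_error(sim_config(beta = 0, n_steps = 100, burn_in = 100), "below")
  expect_error(sim_config(beta = 0, n_steps = 100, init_fraction_A = 1.5),
               "probability")
  # averaged scheme refuses non-regular structures
  ba <- make_random_graph(30, "barabasi_albert", m = 2, seed = 14)
  prof <- sample_aspirations(30, "homogeneous")
  cfg <- sim_config(beta = 0.1, n_steps = 1000, burn_in = 100,
                    payoff_scheme = "averaged_d_games")
  expect_error(run_chain(ba, reference_game(), prof, fermi_function(), cfg),
               "regular")
})
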