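#' Simulation configuration
#'
#' @param beta Selection intensity, `>= 0`.
#' @param n_steps Total number of elementary updates (one randomly chosen
#'   focal individual per step).
#' @param burn_in Updates discarded before averaging; must be `< n_steps`.
#' @param init_fraction_A Probability that each individual starts with
#'   strategy A (independent Bernoulli initial state).
#' @param payoff_scheme `"single_game"` (the focal plays one d-player game it
#'   organises) or `"averaged_d_games"` (the focal's payoff is averaged over
#'   the d games organised by itself and each of its d-1 neighbours; regular
#'   structures of degree d-1 only).
#' @param seed Optional integer seed applied at the start of [run_chain()].
#' @param n_batches Number of batches for the batch-means standard error.
#' @param thin If positive, record the abundance every `thin` post-burn-in
#'   steps as a trajectory summary.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(beta, n_steps, burn_in = floor(n_steps / 10),
                       init_fraction_A = 0.5,
                       payoff_scheme = c("single_game", "averaged_d_games"),
                       seed = NULL, n_batches = 50L, thin = 0L) {
  payoff_scheme <- match.arg(payoff_scheme)
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0) {
    stop("'beta' must be a single nonnegative number", call. = FALSE)
  }
  n_steps <- as.numeric(n_steps)
  burn_in <- as.numeric(burn_in)
  if (burn_in >= n_steps) stop("burn_in must be below n_steps", call. = FALSE)
  if (init_fraction_A < 0 || init_fraction_A > 1) {
    stop("init_fraction_A must be a probability", call. = FALSE)
  }
  structure(list(beta = beta, n_steps = n_steps, burn_in = burn_in,
                 init_fraction_A = init_fraction_A,
                 payoff_scheme = payoff_scheme, seed = seed,
                 n_batches = as.integer(n_batches), thin = as.integer(thin)),
            class = "sim_config")
}

#' Payoff of a focal individual from a single d-player game
#'
#' Samples `d - 1` coplayers (see [sample_coplayers()]), counts how many of
#' them play A, and looks up the focal's payoff row.
#'
#' @param structure A [population_structure()].
#' @param state Integer 0/1 vector, 1 = strategy A.
#' @param table A [payoff_table()].
#' @param focal Focal individual id.
#' @return The realised payoff.
#' @export
focal_payoff_single <- function(structure, state, table, focal) {
  co <- sample_coplayers(structure, focal, table$d)
  k <- sum(state[co])
  payoff_entry(table, state[focal], k)
}

#' Payoff averaged over the d games the focal participates in
#'
#' On a regular structure of degree exactly `d - 1`, the focal takes part in
#' `d` games: one organised by itself and one by each neighbour, each game
#' comprising the organiser and the organiser's full neighbourhood. The
#' focal's final payoff is the average of its payoffs in those `d` games, so
#' it depends on the second-nearest neighbourhood too.
#'
#' @inheritParams focal_payoff_single
#' @return The averaged payoff.
#' @export
focal_payoff_averaged <- function(structure, state, table, focal) {
  if (structure$mode != "network" ||
      any(structure$degrees != table$d - 1L)) {
    stop("averaged payoff scheme needs a regular structure of degree d - 1",
         call. = FALSE)
  }
  organisers <- c(focal, structure$adj[[focal]])
  pays <- vapply(organisers, function(o) {
    members <- c(o, structure$adj[[o]])
    k <- sum(state[setdiff(members, focal)])
    payoff_entry(table, state[focal], k)
  }, numeric(1))
  mean(pays)
}

#' One elementary update of the aspiration dynamics
#'
#' Picks one focal individual uniformly at random, computes its payoff under
#' the configured scheme, and flips its strategy with probability
#' `g_i(beta * (e_i - pi_i))`. All other individuals are unchanged, so a
#' single step changes the state in at most one coordinate.
#'
#' @param structure A [population_structure()].
#' @param state Integer 0/1 strategy vector.
#' @param table A [payoff_table()].
#' @param profile An [aspiration_profile()].
#' @param g A [decision_function()] or a list of one per individual.
#' @param config A [sim_config()].
#' @return The updated state vector.
#' @export
step_chain <- function(structure, state, table, profile, g, config) {
  g_list <- as_g_list(g, structure$n)
  i <- sample.int(structure$n, 1L)
  pay <- if (config$payoff_scheme == "single_game") {
    focal_payoff_single(structure, state, table, i)
  } else {
    focal_payoff_averaged(structure, state, table, i)
  }
  p <- g_list[[i]]$evaluate(config$beta * (profile$e[i] - pay))
  if (runif(1) < p) state[i] <- 1L - state[i]
  state
}

#' Monte-Carlo estimate of the stationary abundance of strategy A
#'
#' Iterates the elementary update from an independent Bernoulli initial
#' state and averages the abundance `sum(s_i)/N` over the post-burn-in
#' steps. The chain is ergodic (no absorbing state), so the average
#' converges to the stationary expectation. The standard error is computed
#' by batch means over `config$n_batches` contiguous batches, the
#' single-run analogue of averaging independent runs.
#'
#' When every individual uses the Fermi decision function the inner loop
#' runs in compiled code; otherwise a pure-R reference loop supporting
#' arbitrary (heterogeneous) decision functions is used.
#'
#' @inheritParams step_chain
#' @param init_state Optional explicit initial 0/1 state (overrides
#'   `config$init_fraction_A`).
#' @return An object of class `stationary_result` with fields
#'   `mean_abundance_A`, `std_error`, `n_samples`, `trajectory`,
#'   `final_state`, `config`.
#' @examples
#' ring <- make_ring(20)
#' tab <- payoff_table(c(3, 2, 1), c(4, 1, 1))
#' prof <- sample_aspirations(20, "uniform", lo = 0, hi = 1, seed = 1)
#' cfg <- sim_config(beta = 0.05, n_steps = 2e5, burn_in = 2e4, seed = 1)
#' run_chain(ring, tab, prof, fermi_function(), cfg)
#' @export
run_chain <- function(structure, table, profile, g = fermi_function(),
                      config, init_state = NULL) {
  stopifnot(inherits(structure, "population_structure"),
            inherits(table, "payoff_table"),
            inherits(profile, "aspiration_profile"),
            inherits(config, "sim_config"))
  n <- structure$n
  if (profile$n != n) stop("profile length must equal population size",
                           call. = FALSE)
  g_list <- as_g_list(g, n)
  check_scheme(structure, table, config$payoff_scheme)
  if (!is.null(config$seed)) set.seed(config$seed)
  if (is.null(init_state)) {
    init_state <- as.integer(runif(n) < config$init_fraction_A)
  } else {
    init_state <- as.integer(init_state)
    stopifnot(length(init_state) == n, all(init_state %in% 0:1))
  }

  use_cpp <- is_all_fermi(g_list) &&
    !(structure$mode == "well_mixed" && table$d > 9)
  if (use_cpp) {
    csr <- structure_csr(structure)
    res <- cpp_run_chain(csr$adj, csr$offs,
                         structure$mode == "well_mixed",
                         table$d, table$a, table$b, profile$e,
                         config$beta, init_state,
                         config$n_steps, config$burn_in,
                         if (config$payoff_scheme == "single_game") 0L else 1L,
                         config$n_batches, config$thin)
  } else {
    res <- run_chain_r(structure, table, profile, g_list, config, init_state)
  }
  structure(list(mean_abundance_A = res$mean_abundance_A,
                 std_error = res$std_error,
                 n_samples = res$n_samples,
                 trajectory = res$trajectory,
                 final_state = res$final_state,
                 config = config),
            class = "stationary_result")
}

# flatten the adjacency to 0-based CSR for the compiled loop
structure_csr <- function(structure) {
  if (structure$mode == "well_mixed") {
    return(list(adj = integer(0), offs = integer(structure$n + 1L)))
  }
  lens <- structure$degrees
  offs <- c(0L, cumsum(lens))
  list(adj = as.integer(unlist(structure$adj) - 1L), offs = as.integer(offs))
}

check_scheme <- function(structure, table, scheme) {
  if (scheme == "averaged_d_games") {
    if (structure$mode != "network" ||
        any(structure$degrees != table$d - 1L)) {
      stop("averaged_d_games needs a regular network of degree d - 1",
           call. = FALSE)
    }
  } else if (structure$mode == "network" &&
             any(structure$degrees < table$d - 1L)) {
    stop("every individual needs at least d - 1 neighbours", call. = FALSE)
  }
  invisible(TRUE)
}

# pure-R reference loop (any decision functions); intended for small runs
run_chain_r <- function(structure, table, profile, g_list, config,
                        init_state) {
  state <- init_state
  n <- structure$n
  total <- config$n_steps
  burn <- config$burn_in
  t_post <- total - burn
  acc <- 0
  nb <- config$n_batches
  batch_len <- if (nb > 0) floor(t_post / nb) else 0
  batch_acc <- numeric(max(nb, 1L))
  traj <- numeric(0)
  count_a <- sum(state)
  for (t in seq_len(total)) {
    i <- sample.int(n, 1L)
    pay <- if (config$payoff_scheme == "single_game") {
      focal_payoff_single(structure, state, table, i)
    } else {
      focal_payoff_averaged(structure, state, table, i)
    }
    p <- g_list[[i]]$evaluate(config$beta * (profile$e[i] - pay))
    if (runif(1) < p) {
      count_a <- count_a + if (state[i] == 1L) -1L else 1L
      state[i] <- 1L - state[i]
    }
    if (t > burn) {
      u <- t - burn - 1
      x <- count_a / n
      acc <- acc + x
      if (batch_len > 0) {
        b <- u %/% batch_len + 1
        if (b <= nb) batch_acc[b] <- batch_acc[b] + x
      }
      if (config$thin > 0 && u %% config$thin == 0) traj <- c(traj, x)
    }
  }
  se <- NA_real_
  if (batch_len > 1 && nb > 1) {
    bm <- batch_acc / batch_len
    se <- sd(bm) / sqrt(nb)
  }
  list(mean_abundance_A = acc / t_post, std_error = se, n_samples = t_post,
       final_state = state, trajectory = traj)
}

#' @export
print.stationary_result <- function(x, ...) {
  cat(sprintf("stationary abundance of A: %.5f (batch-means SE %.2g, %g samples)\n",
              x$mean_abundance_A, x$std_error, x$n_samples))
  invisible(x)
}

#' @export
summary.stationary_result <- function(object, ...) {
  ci <- object$mean_abundance_A + c(-1.96, 1.96) * object$std_error
  cat(sprintf("mean abundance of A : %.5f\n", object$mean_abundance_A))
  cat(sprintf("batch-means SE      : %.3g\n", object$std_error))
  cat(sprintf("approx. 95%% CI      : [%.5f, %.5f]\n", ci[1], ci[2]))
  cat(sprintf("post-burn-in samples: %g\n", object$n_samples))
  invisible(object)
}
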