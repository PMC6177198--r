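# Shared builders for the test suite.

# the reference three-player game: a = (3, 2, 1), b = (4, 1, 1);
# criterion value 1*(3-1) + 2*(2-1) + 1*(1-4) = 1 > 0, so A is favoured
reference_game <- function() payoff_table(a = c(3, 2, 1), b = c(4, 1, 1))

# a neutral game: every entry equal
flat_table <- function(h = 2, d = 3) payoff_table(rep(h, d), rep(h, d))

# a steeper logistic: g(x) = plogis(2x), g'(0) = 1/2, g''(0) = 0
steep_logistic <- function() {
  decision_function(function(x) stats::plogis(2 * x),
                    derivative_at_zero = 0.5,
                    second_derivative_at_zero = 0,
                    name = "steep_logistic")
}

# exact stationary abundance for a given setup, defaulting to the Fermi rule
exact_x <- function(structure, table, profile, beta, g = fermi_function(),
                    scheme = "single_game") {
  exact_abundance(build_chain(structure, table, profile, g, beta,
                              payoff_scheme = scheme))
}
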