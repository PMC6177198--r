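#' Decision (switching-probability) functions
#'
#' A decision function `g` maps the scaled payoff shortfall
#' `x = beta * (e_i - pi_i)` to the probability that the focal individual
#' switches its strategy. The dynamics require `g` to be differentiable with
#' strictly positive derivative and bounded strictly between 0 and 1, so the
#' chain has no absorbing state and is ergodic.
#'
#' @param evaluate Function of one numeric argument returning probabilities.
#' @param derivative_at_zero `g'(0) > 0`.
#' @param second_derivative_at_zero `g''(0)` (enters the weak-selection
#'   validity bound; 0 for the Fermi function).
#' @param name Label for printing and dispatch (e.g. `"fermi"`).
#' @return An object of class `decision_function`.
#' @seealso [fermi_function()], [switch_probability()]
#' @export
decision_function <- function(evaluate, derivative_at_zero,
                              second_derivative_at_zero, name = "custom") {
  stopifnot(is.function(evaluate))
  derivative_at_zero <- as.numeric(derivative_at_zero)
  if (!is.finite(derivative_at_zero) || derivative_at_zero <= 0) {
    stop("derivative_at_zero must be a positive number (g' > 0)", call. = FALSE)
  }
  structure(
    list(evaluate = evaluate,
         derivative_at_zero = derivative_at_zero,
         second_derivative_at_zero = as.numeric(second_derivative_at_zero),
         name = name),
    class = "decision_function"
  )
}

#' @export
print.decision_function <- function(x, ...) {
  cat(sprintf("decision function '%s': g(0) = %.4g, g'(0) = %.4g, g''(0) = %.4g\n",
              x$name, x$evaluate(0), x$derivative_at_zero,
              x$second_derivative_at_zero))
  invisible(x)
}

#' The Fermi (logistic) decision function
#'
#' `g(x) = 1 / (1 + exp(-x))`, the standard choice in stochastic evolutionary
#' game theory. Satisfies `g(0) = 1/2`, `g'(0) = 1/4`, `g''(0) = 0`; the
#' vanishing curvature at 0 makes the weak-selection criterion valid without
#' a finite bound on the selection intensity (see [weak_selection_bound()]).
#'
#' @return A `decision_function` named `"fermi"`.
#' @examples
#' g <- fermi_function()
#' g$evaluate(0)      # 0.5
#' g$derivative_at_zero  # 0.25
#' @export
fermi_function <- function() {
  decision_function(
    evaluate = function(x) stats::plogis(x),
    derivative_at_zero = 0.25,
    second_derivative_at_zero = 0,
    name = "fermi"
  )
}

#' Probability that an individual switches strategy
#'
#' Evaluates `g(beta * (aspiration - payoff))`: an individual whose payoff
#' falls short of its aspiration is more likely to switch, and at `beta = 0`
#' every individual switches blindly with probability `g(0)`.
#'
#' @param g A [decision_function()].
#' @param beta Selection intensity, `beta >= 0`.
#' @param aspiration Aspiration level `e_i` (payoff units).
#' @param payoff Realised payoff `pi_i`.
#' @return Switching probability, strictly inside (0, 1).
#' @examples
#' switch_probability(fermi_function(), beta = 0.05, aspiration = 1, payoff = 0)
#' @export
switch_probability <- function(g, beta, aspiration, payoff) {
  stopifnot(inherits(g, "decision_function"))
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta < 0) {
    stop("'beta' must be a single nonnegative number", call. = FALSE)
  }
  g$evaluate(beta * (aspiration - payoff))
}

#' Check the decision-function axioms on a grid
#'
#' Verifies, on a finite grid, that `g` is strictly inside (0, 1), strictly
#' increasing, and positive at 0 (the hypothesis of the neutrality result).
#'
#' @param g A [decision_function()].
#' @param grid Numeric grid of evaluation points. The default spans
#'   `[-15, 15]`; far outside that range a saturating `g` can round to
#'   exactly 0 or 1 in double precision, which would spuriously violate the
#'   strict bound.
#' @return `TRUE` invisibly; errors describing the violated axiom otherwise.
#' @export
validate_decision_function <- function(g, grid = seq(-15, 15, by = 0.25)) {
  stopifnot(inherits(g, "decision_function"))
  v <- vapply(grid, g$evaluate, numeric(1))
  if (any(!is.finite(v))) stop("g not finite on grid", call. = FALSE)
  if (any(v <= 0) || any(v >= 1)) {
    stop("g must lie strictly in (0, 1)", call. = FALSE)
  }
  if (any(diff(v) <= 0)) {
    stop("g must be strictly increasing (g' > 0)", call. = FALSE)
  }
  if (g$evaluate(0) <= 0) stop("g(0) must be positive", call. = FALSE)
  invisible(TRUE)
}

# Expand a single decision function (or list) to a per-individual list of
# length N; heterogeneity in g is allowed everywhere the R/exact paths run.
as_g_list <- function(g, n) {
  if (inherits(g, "decision_function")) {
    return(rep(list(g), n))
  }
  if (is.list(g) && all(vapply(g, inherits, logical(1), "decision_function"))) {
    if (length(g) != n) {
      stop(sprintf("need %d decision functions, got %d", n, length(g)),
           call. = FALSE)
    }
    return(g)
  }
  stop("'g' must be a decision_function or a list of them", call. = FALSE)
}

# TRUE when every individual uses the built-in Fermi rule (C++ fast path).
is_all_fermi <- function(g_list) {
  all(vapply(g_list, function(g) identical(g$name, "fermi"), logical(1)))
}
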