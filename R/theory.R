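#' Structure-coefficient vector of the weak-selection abundance criterion
#'
#' Under weak selection, strategy A is more abundant than B if and only if
#' `sum_k sigma_k (a_k - b_{d-1-k}) > 0`, where the `d` structure
#' coefficients `sigma_k` depend on the population structure, size, payoff
#' accumulation and decision functions, but on neither the payoff entries
#' nor the aspiration levels. All coefficients are nonnegative and at least
#' one is positive.
#'
#' @param sigma Numeric vector of `d` nonnegative coefficients.
#' @return An object of class `sigma_vector` with fields `d`, `sigma`.
#' @export
sigma_vector <- function(sigma) {
  sigma <- as.numeric(sigma)
  if (length(sigma) < 2L) stop("need at least d = 2 coefficients", call. = FALSE)
  if (any(!is.finite(sigma))) stop("coefficients must be finite", call. = FALSE)
  if (any(sigma < -1e-9)) {
    stop("structure coefficients must be nonnegative", call. = FALSE)
  }
  if (all(sigma <= 1e-12)) {
    stop("at least one coefficient must be positive", call. = FALSE)
  }
  structure(list(d = length(sigma), sigma = sigma), class = "sigma_vector")
}

#' @export
print.sigma_vector <- function(x, ...) {
  cat(sprintf("structure coefficients (d = %d): %s\n", x$d,
              paste(signif(x$sigma, 6), collapse = ", ")))
  invisible(x)
}

#' Closed-form structure coefficients for regular networks of degree d - 1
#'
#' For aspiration dynamics on a regular network of degree `d - 1` (and
#' equally in the well-mixed population), the structure coefficients are the
#' binomial coefficients `sigma_k = choose(d-1, k)`, provided all
#' individuals share a decision function with non-vanishing derivative at 0.
#' For `d = 3` this gives `(1, 2, 1)`.
#'
#' @param d Group size, `>= 2`.
#' @return A [sigma_vector()].
#' @examples
#' sigma_theoretical(3)  # (1, 2, 1)
#' @export
sigma_theoretical <- function(d) {
  d <- as.integer(d)
  if (d < 2L) stop("group size d must be at least 2", call. = FALSE)
  sigma_vector(choose(d - 1L, 0:(d - 1L)))
}

#' Left-hand side of the weak-selection abundance criterion
#'
#' Evaluates `sum_k sigma_k (a_k - b_{d-1-k})`. Positive means strategy A is
#' more abundant than B under weak selection; negative means B; values
#' within `1e-12` of zero are neutral ties.
#'
#' @param table A [payoff_table()].
#' @param sigma A [sigma_vector()] with matching `d`; defaults to the
#'   binomial coefficients of [sigma_theoretical()].
#' @return The scalar criterion value.
#' @examples
#' criterion_lhs(payoff_table(c(3, 2, 1), c(4, 1, 1)))  # 1
#' @export
criterion_lhs <- function(table, sigma = sigma_theoretical(table$d)) {
  stopifnot(inherits(table, "payoff_table"), inherits(sigma, "sigma_vector"))
  if (sigma$d != table$d) stop("sigma and table dimensions differ", call. = FALSE)
  sum(sigma$sigma * (table$a - rev(table$b)))
}

#' Verdict of the abundance criterion
#'
#' @inheritParams criterion_lhs
#' @param tol Tie tolerance (default `1e-12`).
#' @return `"A"`, `"B"`, or `"neutral"`.
#' @export
criterion_verdict <- function(table, sigma = sigma_theoretical(table$d),
                              tol = 1e-12) {
  v <- criterion_lhs(table, sigma)
  if (abs(v) <= tol) "neutral" else if (v > 0) "A" else "B"
}

#' Critical value of one payoff entry
#'
#' Solves `sum_k sigma_k (a_k - b_{d-1-k}) = 0` for a single chosen entry,
#' holding all other entries fixed: the boundary at which the weak-selection
#' abundance ranking flips.
#'
#' @inheritParams criterion_lhs
#' @param which Entry id such as `"a0"` or `"b2"`.
#' @return The critical entry value.
#' @examples
#' # three-player game with a_1 = 2, a_2 = 1, b = (4, 1, 1): a_0 must
#' # exceed 2 for A to be favoured
#' critical_entry(payoff_table(c(0, 2, 1), c(4, 1, 1)), which = "a0")
#' @export
critical_entry <- function(table, sigma = sigma_theoretical(table$d),
                           which = "a0") {
  stopifnot(inherits(table, "payoff_table"), inherits(sigma, "sigma_vector"))
  m <- regmatches(which, regexec("^([ab])([0-9]+)$", which))[[1]]
  if (length(m) != 3L) stop("'which' must look like 'a0' or 'b2'", call. = FALSE)
  row <- m[2]
  k <- as.integer(m[3])
  if (k < 0L || k > table$d - 1L) stop("entry index out of range", call. = FALSE)
  # coefficient of the chosen entry in the criterion
  coef_entry <- if (row == "a") sigma$sigma[k + 1L] else
    -sigma$sigma[table$d - k]
  if (abs(coef_entry) < 1e-12) {
    stop("chosen entry has zero coefficient in the criterion", call. = FALSE)
  }
  cur <- if (row == "a") table$a[k + 1L] else table$b[k + 1L]
  cur - criterion_lhs(table, sigma) / coef_entry
}

#' Selection-intensity scale below which the weak-selection criterion holds
#'
#' The linear criterion is a first-order statement; it is valid whenever the
#' quadratic term of the switching-probability expansion is negligible,
#' i.e. for `beta` well below
#' `g'(0) / (|g''(0)| * (max|e_i| + max{|a_k|, |b_k|}))`.
#' The larger the largest aspiration, the weaker selection must be. For
#' decision functions with `g''(0) = 0` (such as the Fermi function) the
#' quadratic term vanishes identically and the bound is infinite. The value
#' is a scale, not a hard threshold.
#'
#' @param g A [decision_function()].
#' @param profile An [aspiration_profile()].
#' @param table A [payoff_table()].
#' @return The bound (possibly `Inf`).
#' @export
weak_selection_bound <- function(g, profile, table) {
  stopifnot(inherits(g, "decision_function"),
            inherits(profile, "aspiration_profile"),
            inherits(table, "payoff_table"))
  if (profile$n < 1L) stop("empty aspiration profile", call. = FALSE)
  g2 <- abs(g$second_derivative_at_zero)
  if (g2 == 0) return(Inf)
  g$derivative_at_zero /
    (g2 * (max(abs(profile$e)) + max(abs(c(table$a, table$b)))))
}
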