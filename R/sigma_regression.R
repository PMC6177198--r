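#' Payoff design for the sigma-recovery regression
#'
#' The structure coefficients can be estimated from simulation: with every
#' `b` entry fixed at zero, the first-order stationary abundance is
#' `1/2 + beta * lambda * sum_k sigma_k a_k`, so regressing the simulated
#' abundance deviation on the `a` entries recovers the coefficients up to a
#' common positive factor. The default design is the full factorial
#' `a_k in {-1, 0, 1}` minus the all-zero point (a neutral game that carries
#' no signal), i.e. `3^d - 1 = 26` tables for `d = 3`.
#'
#' @param d Group size.
#' @param levels Factor levels for each `a` entry.
#' @return A numeric matrix with `d` columns, one design point per row, of
#'   full column rank.
#' @export
build_design <- function(d = 3L, levels = c(-1, 0, 1)) {
  if (length(unique(levels)) < 2L) {
    stop("design needs at least two distinct levels", call. = FALSE)
  }
  grid <- as.matrix(expand.grid(rep(list(levels), d)))
  dimnames(grid) <- list(NULL, paste0("a", 0:(d - 1L)))
  grid <- grid[rowSums(grid != 0) > 0L, , drop = FALSE]
  if (qr(cbind(1, grid))$rank < d + 1L) {
    stop("rank-deficient design", call. = FALSE)
  }
  grid
}

#' Estimate structure coefficients by regression on simulated abundances
#'
#' Reproduces the simulation protocol for estimating the `sigma_k`: for each
#' payoff design point (a-row from `design`, b identically 0) the stationary
#' abundance is estimated by [run_chain()], and the deviation
#' `y = abundance - 1/2` is regressed on `(a_0, ..., a_{d-1})` with
#' intercept by ordinary least squares. Because the criterion only fixes the
#' coefficients up to a positive factor, the fit also reports the
#' ratio-normalised vector with `sigma_0 = 1`; for a ring or well-mixed
#' population under weak selection this should match the binomial pattern
#' `(1, 2, 1)` for `d = 3`, with intercept 0.
#'
#' @param structure A [population_structure()].
#' @param profile An [aspiration_profile()].
#' @param g A [decision_function()] (or per-individual list).
#' @param beta Selection intensity (weak relative to the design's payoff
#'   scale).
#' @param design Matrix from [build_design()].
#' @param n_steps,burn_in Per-design-point simulation budget (elementary
#'   updates).
#' @param init_fraction_A Initial Bernoulli fraction of A-players.
#' @param seed Optional integer seed; design point `j` uses `seed + j` so
#'   runs are independent but reproducible.
#' @return An object of class `sigma_fit`: raw OLS `coefficients` (response
#'   scale), `intercept`, `normalized` coefficients (first entry 1),
#'   `margins_of_error` (95% half-widths, raw scale),
#'   `normalized_margins` (delta-method 95% half-widths of the ratios),
#'   `abundances` (per-point estimates), `design`, and the `lm` fit.
#' @export
fit_sigma <- function(structure, profile, g = fermi_function(), beta,
                      design = build_design(), n_steps = 2.2e6,
                      burn_in = 2e5, init_fraction_A = 0.5, seed = NULL) {
  d <- ncol(design)
  npts <- nrow(design)
  ab <- numeric(npts)
  se <- numeric(npts)
  base_seed <- if (is.null(seed)) NULL else as.integer(seed)
  for (j in seq_len(npts)) {
    tab <- payoff_table(a = design[j, ], b = numeric(d))
    cfg <- sim_config(beta = beta, n_steps = n_steps, burn_in = burn_in,
                      init_fraction_A = init_fraction_A,
                      seed = if (is.null(base_seed)) NULL else base_seed + j)
    res <- run_chain(structure, tab, profile, g, cfg)
    ab[j] <- res$mean_abundance_A
    se[j] <- res$std_error
  }
  df <- data.frame(y = ab - 0.5, design, check.names = FALSE)
  fml <- stats::as.formula(paste("y ~", paste(colnames(design),
                                              collapse = " + ")))
  fit <- lm(fml, data = df)
  cf <- coef(fit)
  ci <- confint(fit, level = 0.95)
  margins <- (ci[, 2] - ci[, 1]) / 2
  raw <- cf[-1L]
  if (abs(raw[1]) <= margins[2L]) {
    stop("coefficient on a_0 not distinguishable from 0; cannot normalise",
         call. = FALSE)
  }
  normalized <- raw / raw[1]
  # delta-method margins for the ratios r_k = beta_k / beta_0
  V <- vcov(fit)[-1L, -1L, drop = FALSE]
  nm <- vapply(seq_along(raw), function(k) {
    if (k == 1L) return(0)
    gr <- numeric(length(raw))
    gr[1] <- -raw[k] / raw[1]^2
    gr[k] <- 1 / raw[1]
    1.96 * sqrt(drop(t(gr) %*% V %*% gr))
  }, numeric(1))
  structure(list(d = d,
                 coefficients = unname(raw),
                 intercept = unname(cf[1L]),
                 margins_of_error = unname(margins),
                 normalized = unname(normalized),
                 normalized_margins = unname(nm),
                 abundances = ab,
                 abundance_se = se,
                 design = design,
                 beta = beta,
                 n_steps = n_steps,
                 normalization = "ratio (sigma_0 = 1)",
                 lm_fit = fit),
            class = "sigma_fit")
}

#' @export
print.sigma_fit <- function(x, ...) {
  cat(sprintf("sigma regression fit (d = %d, beta = %g, %d design points)\n",
              x$d, x$beta, nrow(x$design)))
  cat("normalised coefficients (sigma_0 = 1):\n")
  for (k in seq_len(x$d)) {
    cat(sprintf("  sigma_%d = %.4f (+/- %.4f)\n", k - 1L, x$normalized[k],
                x$normalized_margins[k]))
  }
  cat(sprintf("intercept = %.3g (+/- %.3g, response scale)\n",
              x$intercept, x$margins_of_error[1L]))
  invisible(x)
}

#' @export
coef.sigma_fit <- function(object, normalized = TRUE, ...) {
  if (normalized) setNames(object$normalized,
                           paste0("sigma_", seq_len(object$d) - 1L))
  else setNames(object$coefficients,
                paste0("a", seq_len(object$d) - 1L))
}

#' @export
summary.sigma_fit <- function(object, ...) {
  print(object)
  cat("\nraw OLS fit (response = abundance - 1/2):\n")
  print(summary(object$lm_fit)$coefficients)
  invisible(object)
}
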