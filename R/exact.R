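#' Exact Markov chain of the aspiration dynamics
#'
#' Enumerates all `2^N` strategy states, builds the row-stochastic
#' single-flip transition matrix, and solves the stationary distribution
#' exactly. This is the verification oracle for the neutrality results and
#' the weak-selection sigma-rule: it supports arbitrary heterogeneous
#' aspirations and decision functions, the single-game scheme on any
#' structure with the degree floor `d - 1` (the random coplayer draw is
#' marginalised inside the flip probability with hypergeometric weights over
#' the focal's neighbourhood, or over the whole population in well-mixed
#' mode), and the averaged payoff scheme on regular networks of degree
#' `d - 1`.
#'
#' @param structure A [population_structure()].
#' @param table A [payoff_table()].
#' @param profile An [aspiration_profile()].
#' @param g A [decision_function()] or a per-individual list.
#' @param beta Selection intensity. Negative values are admitted here: the
#'   transition probabilities remain well defined, and the central finite
#'   difference of the abundance at `beta = 0` needs them.
#' @param payoff_scheme `"single_game"` or `"averaged_d_games"`.
#' @param max_n Safety cap on `N` (default 14, i.e. 16384 states).
#' @return An object of class `exact_chain` with the sparse transition
#'   matrix `P`, stationary vector `kappa`, the per-state A-counts, and the
#'   inputs.
#' @export
build_chain <- function(structure, table, profile, g = fermi_function(),
                        beta, payoff_scheme = c("single_game",
                                                "averaged_d_games"),
                        max_n = 14L) {
  payoff_scheme <- match.arg(payoff_scheme)
  stopifnot(inherits(structure, "population_structure"),
            inherits(table, "payoff_table"),
            inherits(profile, "aspiration_profile"))
  n <- structure$n
  if (n > max_n) {
    stop(sprintf("N = %d exceeds the exact-enumeration cap of %d", n, max_n),
         call. = FALSE)
  }
  if (profile$n != n) stop("profile length must equal N", call. = FALSE)
  g_list <- as_g_list(g, n)
  d <- table$d
  if (structure$mode == "network" && any(structure$degrees < d - 1L)) {
    stop("every individual needs at least d - 1 neighbours", call. = FALSE)
  }
  if (payoff_scheme == "averaged_d_games" &&
      (structure$mode != "network" || any(structure$degrees != d - 1L))) {
    stop("averaged_d_games needs a regular network of degree d - 1",
         call. = FALSE)
  }

  n_states <- 2L^n
  states <- 0:(n_states - 1L)
  pc <- popcount_table(n)

  # FP[s, i] = flip probability of individual i in state s
  fp <- matrix(0, n_states, n)
  for (i in seq_len(n)) {
    bit_i <- bitwShiftL(1L, i - 1L)
    s_i <- as.integer(bitwAnd(states, bit_i) > 0L)
    if (structure$mode == "well_mixed") {
      # expected flip probability over the hypergeometric coplayer draw
      m_others <- pc[states + 1L] - s_i     # A-players among the other N-1
      p_i <- numeric(n_states)
      for (k in 0:(d - 1L)) {
        w <- dhyper(k, m_others, (n - 1L) - m_others, d - 1L)
        pay <- ifelse(s_i == 1L, table$a[k + 1L], table$b[k + 1L])
        p_i <- p_i + w * g_list[[i]]$evaluate(beta * (profile$e[i] - pay))
      }
      fp[, i] <- p_i
    } else if (payoff_scheme == "single_game") {
      deg <- structure$degrees[i]
      mask <- neighbour_mask(structure$adj[[i]])
      m_nbr <- pc[bitwAnd(states, mask) + 1L]  # A-players in the neighbourhood
      if (deg == d - 1L) {
        pay <- ifelse(s_i == 1L, table$a[m_nbr + 1L], table$b[m_nbr + 1L])
        fp[, i] <- g_list[[i]]$evaluate(beta * (profile$e[i] - pay))
      } else {
        # marginalise the uniform (d-1)-subset coplayer draw exactly:
        # hypergeometric weights over the neighbourhood composition
        p_i <- numeric(n_states)
        for (k in 0:(d - 1L)) {
          w <- dhyper(k, m_nbr, deg - m_nbr, d - 1L)
          pay <- ifelse(s_i == 1L, table$a[k + 1L], table$b[k + 1L])
          p_i <- p_i + w * g_list[[i]]$evaluate(beta * (profile$e[i] - pay))
        }
        fp[, i] <- p_i
      }
    } else {
      # averaged over the d games organised by i and each neighbour
      organisers <- c(i, structure$adj[[i]])
      pay_tot <- numeric(n_states)
      for (o in organisers) {
        if (o == i) {
          k <- pc[bitwAnd(states, neighbour_mask(structure$adj[[i]])) + 1L]
        } else {
          bit_o <- bitwShiftL(1L, o - 1L)
          s_o <- as.integer(bitwAnd(states, bit_o) > 0L)
          k <- pc[bitwAnd(states, neighbour_mask(structure$adj[[o]])) + 1L] +
            s_o - s_i
        }
        pay_tot <- pay_tot +
          ifelse(s_i == 1L, table$a[k + 1L], table$b[k + 1L])
      }
      fp[, i] <- g_list[[i]]$evaluate(beta * (profile$e[i] - pay_tot / d))
    }
  }

  # ergodicity is guaranteed by 0 < g < 1, but numerically a flip
  # probability can underflow, leaving the chain (nearly) reducible and the
  # stationary vector ill-determined
  if (min(fp) < 1e-12) {
    warning(paste("some flip probabilities are numerically zero; the chain",
                  "is numerically reducible and the stationary distribution",
                  "is unreliable"), call. = FALSE)
  }

  # sparse transition matrix: off-diagonal flip moves + lazy diagonal
  from <- rep(states + 1L, n)
  to <- as.vector(vapply(seq_len(n), function(i) {
    bitwXor(states, bitwShiftL(1L, i - 1L)) + 1L
  }, integer(n_states)))
  p_off <- as.vector(fp) / n
  diag_p <- 1 - rowSums(fp) / n
  P <- Matrix::sparseMatrix(i = c(from, states + 1L), j = c(to, states + 1L),
                            x = c(p_off, diag_p),
                            dims = c(n_states, n_states))
  kappa <- stationary_linear(P)
  structure(list(n = n, P = P, kappa = kappa,
                 counts_A = pc[states + 1L],
                 beta = beta, table = table, profile = profile,
                 payoff_scheme = payoff_scheme,
                 structure_kind = structure$kind),
            class = "exact_chain")
}

popcount_table <- function(n) {
  n_states <- 2L^n
  pc <- integer(n_states)
  for (s in seq_len(n_states - 1L)) {
    pc[s + 1L] <- pc[bitwShiftR(s, 1L) + 1L] + bitwAnd(s, 1L)
  }
  pc
}

neighbour_mask <- function(nbrs) {
  Reduce(bitwOr, bitwShiftL(1L, nbrs - 1L), 0L)
}

# stationary vector by sparse linear solve of kappa' (P - I) = 0 with the
# normalisation sum(kappa) = 1 replacing the last (redundant) equation
stationary_linear <- function(P) {
  ns <- nrow(P)
  M <- Matrix::t(P) - Matrix::Diagonal(ns)
  M[ns, ] <- 1
  rhs <- c(rep(0, ns - 1L), 1)
  kappa <- as.numeric(Matrix::solve(M, rhs))
  # one step of iterative refinement tightens the residual near roundoff
  resid <- as.numeric(M %*% kappa) - rhs
  kappa <- kappa - as.numeric(Matrix::solve(M, resid))
  kappa / sum(kappa)
}

# dense eigenvector route (small chains): eigenvector of t(P) for the
# eigenvalue closest to 1; used to cross-check the linear solve
stationary_eigen <- function(P) {
  ev <- eigen(t(as.matrix(P)))
  idx <- which.min(abs(ev$values - 1))
  v <- Re(ev$vectors[, idx])
  v <- v / sum(v)
  if (any(v < -1e-8)) v <- -v
  v / sum(v)
}

#' @export
print.exact_chain <- function(x, ...) {
  cat(sprintf("exact aspiration-dynamics chain: N = %d (%d states), beta = %g, %s, %s\n",
              x$n, length(x$kappa), x$beta, x$structure_kind,
              x$payoff_scheme))
  cat(sprintf("  stationary abundance of A = %.8f\n", exact_abundance(x)))
  invisible(x)
}

#' Exact stationary abundance of strategy A
#'
#' The expectation of `sum(s_i)/N` under the stationary distribution kappa.
#'
#' @param chain An [build_chain()] result.
#' @return The exact average abundance in `[0, 1]`.
#' @export
exact_abundance <- function(chain) {
  stopifnot(inherits(chain, "exact_chain"))
  sum(chain$kappa * chain$counts_A) / chain$n
}

#' Exact derivative of the abundance with respect to selection intensity
#'
#' Central finite difference of the exact stationary abundance at
#' `beta = 0`: `(x(h) - x(-h)) / (2h)`. The sign of this derivative decides
#' which strategy is more abundant under weak selection, and by the
#' aspiration-independence result it does not depend on the aspiration
#' profile.
#'
#' @inheritParams build_chain
#' @param h_beta Finite-difference step (default `1e-4`).
#' @return The numerical derivative `d(abundance)/d(beta)` at 0.
#' @export
abundance_derivative <- function(structure, table, profile,
                                 g = fermi_function(),
                                 payoff_scheme = "single_game",
                                 h_beta = 1e-4) {
  xp <- exact_abundance(build_chain(structure, table, profile, g,
                                    beta = h_beta,
                                    payoff_scheme = payoff_scheme))
  xm <- exact_abundance(build_chain(structure, table, profile, g,
                                    beta = -h_beta,
                                    payoff_scheme = payoff_scheme))
  der <- (xp - xm) / (2 * h_beta)
  if (!is.finite(der)) stop("non-finite derivative", call. = FALSE)
  der
}

#' Structure coefficients derived numerically from the exact chain
#'
#' Because the first-order abundance criterion is linear in the payoff
#' entries with coefficients independent of payoffs and aspirations, the
#' coefficient `sigma_k` can be read off by setting `a_k = 1` and every
#' other entry to 0 and differentiating the exact abundance at `beta = 0`.
#' The `d` derivatives are returned rescaled so the first equals
#' `choose(d-1, 0) = 1`.
#'
#' @inheritParams build_chain
#' @param d Group size.
#' @param profile Aspiration profile; defaults to the homogeneous level 2
#'   (the result is aspiration-independent).
#' @param h_beta Finite-difference step.
#' @return A [sigma_vector()] of the `d` normalised coefficients.
#' @export
derive_sigma_numeric <- function(structure, g = fermi_function(),
                                 payoff_scheme = "single_game", d = 3L,
                                 profile = NULL, h_beta = 1e-4) {
  if (is.null(profile)) {
    profile <- sample_aspirations(structure$n, "homogeneous", value = 2)
  }
  raw <- vapply(seq_len(d), function(kk) {
    a <- numeric(d); a[kk] <- 1
    abundance_derivative(structure, payoff_table(a, numeric(d)), profile, g,
                         payoff_scheme = payoff_scheme, h_beta = h_beta)
  }, numeric(1))
  if (abs(raw[1]) < 1e-12) {
    stop("entry-0 derivative vanishes; cannot normalise", call. = FALSE)
  }
  sigma_vector(raw / raw[1])
}
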