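#' Per-individual aspiration profile
#'
#' Holds the aspiration (expectation) level `e_i` of every individual, in
#' payoff units. Aspirations may be negative or exceed every payoff entry; no
#' clipping is applied.
#'
#' @param e Numeric vector of finite aspiration levels, one per individual.
#' @param source Label recording where the values came from (a distribution
#'   name or `"file"`).
#' @return An object of class `aspiration_profile` with fields `e`, `n`,
#'   `source`.
#' @export
aspiration_profile <- function(e, source = "custom") {
  e <- as.numeric(e)
  if (length(e) < 1L || !all(is.finite(e))) {
    stop("aspirations must be a nonempty vector of finite values", call. = FALSE)
  }
  structure(list(e = e, n = length(e), source = source),
            class = "aspiration_profile")
}

#' @export
print.aspiration_profile <- function(x, ...) {
  cat(sprintf("aspiration profile: N = %d, source = %s\n", x$n, x$source))
  cat(sprintf("  range [%.4g, %.4g], mean %.4g\n",
              min(x$e), max(x$e), mean(x$e)))
  invisible(x)
}

#' Sample an aspiration profile from a named distribution
#'
#' Draws `n` i.i.d. aspiration levels from one of the distributions used in
#' the simulation studies:
#' \describe{
#'   \item{`homogeneous`}{every individual gets the constant `value`
#'     (default 2).}
#'   \item{`uniform`}{uniform on `[lo, hi]` (defaults 0 and 5).}
#'   \item{`bimodal`}{mixture `0.4 N(2.5, 0.5^2) + 0.6 N(4.5, 0.5^2)`,
#'     sampled by component indicator then an untruncated normal draw.}
#'   \item{`powerlaw`}{density `f(x) = 2 x^{-3}` on `x >= 1`, sampled by
#'     inversion: `x = (1 - u)^{-1/2}` (CDF `F(x) = 1 - x^{-2}`), so the
#'     minimum possible draw is 1.}
#' }
#'
#' @param n Number of individuals.
#' @param dist Distribution name.
#' @param value Constant for `homogeneous`.
#' @param lo,hi Interval for `uniform`.
#' @param seed Optional integer seed for reproducibility.
#' @return An [aspiration_profile()].
#' @examples
#' sample_aspirations(5, "homogeneous", value = 2)
#' sample_aspirations(100, "powerlaw", seed = 1)
#' @export
sample_aspirations <- function(n,
                               dist = c("homogeneous", "uniform", "bimodal",
                                        "powerlaw"),
                               value = 2, lo = 0, hi = 5, seed = NULL) {
  dist <- match.arg(dist)
  n <- as.integer(n)
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  e <- switch(
    dist,
    homogeneous = rep(as.numeric(value), n),
    uniform = {
      if (lo >= hi) stop("'lo' must be strictly below 'hi'", call. = FALSE)
      runif(n, lo, hi)
    },
    bimodal = {
      comp <- runif(n) < 0.4
      ifelse(comp, rnorm(n, 2.5, 0.5), rnorm(n, 4.5, 0.5))
    },
    powerlaw = (1 - runif(n))^(-0.5)
  )
  src <- switch(dist,
                homogeneous = sprintf("homogeneous(%g)", value),
                uniform = sprintf("uniform[%g,%g]", lo, hi),
                bimodal = "bimodal 0.4*N(2.5,0.25)+0.6*N(4.5,0.25)",
                powerlaw = "powerlaw f(x)=2x^-3, x>=1")
  aspiration_profile(e, source = src)
}

#' Read an aspiration profile from CSV
#'
#' Expects columns `individual_index` (1-based, consecutive) and
#' `aspiration`, the layout written by [save_aspirations()] and
#' [generate_fixtures()]. Rows may be in any order; the profile is returned
#' ordered by index.
#'
#' @param path CSV file path.
#' @return An [aspiration_profile()] with `source = "file"`.
#' @export
load_aspirations <- function(path) {
  df <- read.csv(path)
  need <- c("individual_index", "aspiration")
  if (!all(need %in% names(df))) {
    stop("CSV must have columns 'individual_index' and 'aspiration'",
         call. = FALSE)
  }
  idx <- df$individual_index
  if (anyNA(idx) || anyDuplicated(idx)) {
    stop("individual_index must be unique and non-missing", call. = FALSE)
  }
  if (!setequal(idx, seq_len(nrow(df)))) {
    stop("individual_index must be 1..N with no gaps", call. = FALSE)
  }
  e <- as.numeric(df$aspiration[order(idx)])
  if (anyNA(e)) stop("non-numeric aspiration values", call. = FALSE)
  aspiration_profile(e, source = "file")
}

#' Write an aspiration profile to CSV
#'
#' Inverse of [load_aspirations()]: writes `individual_index,aspiration`
#' with 1-based indices.
#'
#' @param profile An [aspiration_profile()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
save_aspirations <- function(profile, path) {
  stopifnot(inherits(profile, "aspiration_profile"))
  df <- data.frame(individual_index = seq_len(profile$n),
                   aspiration = profile$e)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
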