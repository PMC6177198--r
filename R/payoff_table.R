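#' Payoff table of a two-strategy d-player game
#'
#' The payoff to a focal individual depends on its own strategy (A or B) and
#' on the number `k` of its `d - 1` coplayers that use strategy A. An
#' A-player facing `k` A-coplayers receives `a_k`; a B-player receives `b_k`,
#' for `k = 0, ..., d - 1`.
#'
#' @param a Numeric vector of length `d`: payoffs `a_0, ..., a_{d-1}` to an
#'   A-player, indexed by the number of A-coplayers.
#' @param b Numeric vector of length `d`: payoffs `b_0, ..., b_{d-1}` to a
#'   B-player.
#' @return An object of class `payoff_table` with fields `d`, `a`, `b`.
#' @examples
#' # three-player game: a = (3, 2, 1), b = (4, 1, 1)
#' payoff_table(a = c(3, 2, 1), b = c(4, 1, 1))
#' @export
payoff_table <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b)) {
    stop("'a' and 'b' must have the same length d", call. = FALSE)
  }
  d <- length(a)
  if (d < 2) stop("group size d must be at least 2", call. = FALSE)
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("payoff entries must be finite", call. = FALSE)
  }
  structure(list(d = d, a = a, b = b), class = "payoff_table")
}

#' @export
print.payoff_table <- function(x, ...) {
  cat(sprintf("%d-player two-strategy payoff table\n", x$d))
  m <- rbind(A = x$a, B = x$b)
  colnames(m) <- paste0("k=", seq_len(x$d) - 1L)
  print(m)
  invisible(x)
}

#' @export
as.matrix.payoff_table <- function(x, ...) {
  m <- rbind(A = x$a, B = x$b)
  colnames(m) <- paste0("k=", seq_len(x$d) - 1L)
  m
}

# payoff lookup: strategy 1 = A, 0 = B; k = number of A coplayers (0-based)
payoff_entry <- function(table, strategy, k) {
  if (strategy == 1L) table$a[k + 1L] else table$b[k + 1L]
}

#' Relabel strategies of a payoff table
#'
#' Swapping the names of the strategies maps entry `a_k` to `b_{d-1-k}` and
#' vice versa: a B-player facing `k` A-coplayers is, after the relabelling,
#' an A-player facing `d-1-k` A-coplayers. Under this relabelling the
#' stationary abundance of A maps to one minus its original value.
#'
#' @param table A [payoff_table()].
#' @return The relabelled `payoff_table`.
#' @export
swap_strategies <- function(table) {
  payoff_table(a = rev(table$b), b = rev(table$a))
}
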