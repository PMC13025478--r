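# Independent oracles used across the suite.
#
# The package diagonalizes via a real similarity transform of the
# tridiagonal operator; the oracle route here builds the complex matrix
# entry by entry from the folded recurrence and calls the complex
# eigensolver directly, so the two paths share no code.

oracle_matrix <- function(q, Q, boundary = "mathieu") {
  A <- matrix(0 + 0i, Q + 1L, Q + 1L)
  for (m in 0:Q) A[m + 1L, m + 1L] <- m^2
  for (m in 1:Q) {
    b <- if (m == 1L && boundary == "mathieu") q * sqrt(2) / 4 else q / 4
    A[m, m + 1L] <- A[m + 1L, m] <- -1i * b
  }
  A
}

oracle_eigenvalues <- function(q, Q, boundary = "mathieu") {
  v <- eigen(oracle_matrix(q, Q, boundary), only.values = TRUE)$values
  v[order(Re(v), Im(v))]
}

# closed form for the two-mode model, (1 +/- sqrt(1 - q^2)) / 2
two_mode_closed_form <- function(q) {
  s <- sqrt(as.complex(1 - q^2))
  sort_by <- function(v) v[order(Re(v), Im(v))]
  sort_by(c((1 - s) / 2, (1 + s) / 2))
}

expect_close <- function(x, y, tol) {
  expect_lt(max(abs(x - y)), tol)
}
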