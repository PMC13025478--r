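#' Windowed log-log power-law exponent fit
#'
#' Ordinary least squares of \code{log(y)} on \code{log(x)} restricted to a
#' window in \code{x}.  Deterministic spectral sweeps carry no
#' heteroscedastic noise model, so plain (unweighted) OLS is used
#' throughout the package.
#'
#' @param xs,ys positive numeric vectors of equal length.
#' @param window numeric \code{c(x_lo, x_hi)}; defaults to the full range.
#' @param quantity label recorded with the fit (e.g. \code{"re_lambda0"}).
#' @return object of class \code{"exponent_fit"}: list with \code{slope},
#'   \code{stderr}, \code{intercept}, \code{window}, \code{n_points},
#'   \code{quantity}.
#' @examples
#' x <- 10^seq(0, 1, length.out = 10)
#' fit_loglog_slope(x, x^3)$slope    # 3
#' @export
fit_loglog_slope <- function(xs, ys, window = range(xs),
                             quantity = "quantity") {
  stopifnot(length(xs) == length(ys), length(window) == 2L,
            window[1] < window[2])
  keep <- xs >= window[1] & xs <= window[2]
  if (sum(keep) < 3L)
    stop(sprintf("only %d points inside the window; >= 3 needed", sum(keep)),
         call. = FALSE)
  x <- xs[keep]; y <- ys[keep]
  if (any(x <= 0) || any(y <= 0))
    stop("log-log fit requires strictly positive data in the window",
         call. = FALSE)
  fit <- stats::lm(log(y) ~ log(x))
  co <- suppressWarnings(summary(fit))$coefficients  # exact fits warn
  stderr <- if (nrow(co) >= 2L && ncol(co) >= 2L) co[2L, 2L] else 0
  if (!is.finite(stderr)) stderr <- 0
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 stderr = unname(stderr),
                 intercept = unname(stats::coef(fit)[1L]),
                 window = window, n_points = sum(keep), quantity = quantity),
            class = "exponent_fit")
}

#' @export
print.exponent_fit <- function(x, ...) {
  cat(sprintf("exponent fit [%s]: slope = %.4f +/- %.4f (%d points in [%g, %g])\n",
              x$quantity, x$slope, x$stderr, x$n_points,
              x$window[1], x$window[2]))
  invisible(x)
}

#' Constructor helper for exponent-fit objects
#'
#' @param slope,stderr,window,n_points,quantity see
#'   \code{\link{fit_loglog_slope}}.
#' @return an \code{"exponent_fit"} object.
#' @keywords internal
exponent_fit <- function(slope, stderr, window, n_points, quantity) {
  structure(list(slope = slope, stderr = stderr, intercept = NA_real_,
                 window = window, n_points = n_points, quantity = quantity),
            class = "exponent_fit")
}

# log-spaced grid with a fixed density per decade
log_grid <- function(window, points_per_decade = 20L) {
  n <- max(3L, ceiling(points_per_decade * log10(window[2] / window[1])) + 1L)
  10^seq(log10(window[1]), log10(window[2]), length.out = n)
}

# first eigenvalue collision of the operator; the low-activity window must
# stay below it and the high-activity window well above
Q_C_FIRST_EP <- 1.4687686

#' Scaling exponents of the slowest mode in both activity regimes
#'
#' Runs activity sweeps of the operator and extracts the power-law
#' exponents of \code{Re lambda0} (alpha) and of the polar projection
#' \code{c_1} (beta) in a low-activity window (expected: \code{alpha_low =
#' 2}, \code{beta_low = 1}) and/or an intermediate high-activity window
#' (expected: \code{alpha_high = 1/2}, \code{beta_high = -1/8}).  Window
#' preconditions are enforced: the low window must lie below the first
#' eigenvalue collision at \code{q ~ 1.4688}, the high window inside
#' \code{(10 q_c, Q^2 / 10)} so that the fit stays in the
#' truncation-faithful intermediate regime.
#'
#' @param Q truncation cutoff.
#' @param low_window,high_window numeric \code{c(q_lo, q_hi)} or
#'   \code{NULL} to skip a regime.
#' @param points_per_decade sweep density (default 20; estimates are stable
#'   beyond this).
#' @return data frame with one row per (regime, exponent) combination:
#'   columns \code{regime}, \code{exponent} (\code{"alpha"} or
#'   \code{"beta"}), \code{value}, \code{stderr}, \code{q_lo}, \code{q_hi},
#'   \code{n_points}, \code{Q}.
#' @examples
#' \donttest{
#' exponent_table(50, low_window = c(1e-3, 1e-2))
#' }
#' @export
exponent_table <- function(Q, low_window = NULL, high_window = NULL,
                           points_per_decade = 20L) {
  if (is.null(low_window) && is.null(high_window))
    stop("supply at least one of 'low_window', 'high_window'", call. = FALSE)
  rows <- list()
  fit_both <- function(window, regime) {
    sw <- sweep_spectrum(log_grid(window, points_per_decade), Q, n_proj = 2L)
    a <- fit_loglog_slope(sw$q, sw$re_lambda0, quantity = "re_lambda0")
    b <- fit_loglog_slope(sw$q, sw$c1, quantity = "c1")
    rbind(
      data.frame(regime = regime, exponent = "alpha", value = a$slope,
                 stderr = a$stderr, q_lo = window[1], q_hi = window[2],
                 n_points = a$n_points, Q = Q),
      data.frame(regime = regime, exponent = "beta", value = b$slope,
                 stderr = b$stderr, q_lo = window[1], q_hi = window[2],
                 n_points = b$n_points, Q = Q))
  }
  if (!is.null(low_window)) {
    if (low_window[2] >= Q_C_FIRST_EP) {
      warning("low window reaches the first eigenvalue collision; refusing",
              call. = FALSE)
      stop("low_window must lie below q ~ 1.4688", call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- fit_both(low_window, "low")
  }
  if (!is.null(high_window)) {
    if (high_window[1] < 10 * Q_C_FIRST_EP || high_window[2] > Q^2 / 10) {
      warning(sprintf(
        "high window must lie inside (%.3g, %.3g) for Q = %d; refusing",
        10 * Q_C_FIRST_EP, Q^2 / 10, Q), call. = FALSE)
      stop("high_window violates the intermediate-regime precondition",
           call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- fit_both(high_window, "high")
  }
  do.call(rbind, rows)
}
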