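#' Mean-field critical coupling of the flocking instability
#'
#' In the linearized mean-field closure an alignment interaction of angular
#' symmetry \code{n} (1 = polar, 2 = nematic, ...) excites the \code{n}-th
#' Fourier mode of the one-particle distribution with strength
#' \code{Gamma}.  The disordered state destabilizes when the excitation
#' overcomes the slowest free relaxation, which gives the threshold in two
#' equivalent forms:
#' \itemize{
#'   \item \code{method = "ratio"} (default): \code{Gamma_c = Re(lambda0) /
#'     c_n}, the slowest decay rate divided by the projection of the
#'     slowest mode onto harmonic \code{n}.
#'   \item \code{method = "exact"}: the smallest \code{Gamma >= 0} at which
#'     the perturbed decay matrix \code{A - Gamma e_n e_n^T} (the rank-one
#'     mode excitation) acquires an eigenvalue with non-positive real part,
#'     found by bisection.  For a complex-symmetric operator the first-order
#'     shift involves the bilinear rather than the Hermitian overlap, so
#'     the two methods may differ by an activity-dependent factor; both are
#'     exposed so they can be compared.
#' }
#'
#' @param q activity parameter, \code{> 0} (at \code{q = 0} the threshold
#'   is 0: the slowest mode is marginal).
#' @param Q truncation cutoff, \code{>= n}.
#' @param n interaction symmetry index, integer \code{>= 1}.
#' @param method \code{"ratio"} or \code{"exact"}.
#' @param tol relative bisection tolerance for \code{method = "exact"}.
#' @return object of class \code{"coupling_threshold"}: list with \code{q},
#'   \code{n}, \code{gamma_c}, \code{method}, \code{Q}.
#' @examples
#' critical_coupling(0.5, Q = 30, n = 1)$gamma_c
#' @export
critical_coupling <- function(q, Q, n, method = c("ratio", "exact"),
                              tol = 1e-8) {
  method <- match.arg(method)
  stopifnot(q >= 0, n >= 1, n == round(n), n <= Q)
  if (q == 0)
    return(structure(list(q = 0, n = as.integer(n), gamma_c = 0,
                          method = method, Q = as.integer(Q)),
                     class = "coupling_threshold"))
  gamma_c <- if (method == "ratio") {
    sm <- slowest_mode(diagonalize(build_decay_operator(q, Q)))
    c_n <- sm$projections$c_n[n + 1L]
    if (c_n < 1e-14)
      stop(sprintf("structural zero: the slowest mode has no component on harmonic %d",
                   n), call. = FALSE)
    Re(sm$lambda0) / c_n
  } else {
    min_re <- function(gam) {
      B <- real_form(q, Q)
      B[n + 1L, n + 1L] <- B[n + 1L, n + 1L] - gam
      min(Re(eigen(B, only.values = TRUE)$values))
    }
    hi <- 1
    while (min_re(hi) > 0) {
      hi <- hi * 2
      if (hi > 1e12) stop("no instability found up to Gamma = 1e12",
                          call. = FALSE)
    }
    lo <- 0
    while (hi - lo > tol * max(1, hi)) {
      mid <- (lo + hi) / 2
      if (min_re(mid) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  structure(list(q = q, n = as.integer(n), gamma_c = gamma_c,
                 method = method, Q = as.integer(Q)),
            class = "coupling_threshold")
}

#' @export
print.coupling_threshold <- function(x, ...) {
  cat(sprintf("critical coupling (n = %d, %s): Gamma_c = %.6g at q = %g (Q = %d)\n",
              x$n, x$method, x$gamma_c, x$q, x$Q))
  invisible(x)
}

#' Scaling exponent of the critical coupling
#'
#' Fits \code{log Gamma_c} against \code{log q} over an activity window.
#' With the ratio method this is by construction \code{gamma = alpha -
#' beta_n}: expected values are 1 (low activity, polar), 0 (low activity,
#' nematic) and 5/8 (high activity, polar).
#'
#' @param Q truncation cutoff.
#' @param n interaction symmetry index.
#' @param window numeric \code{c(q_lo, q_hi)}.
#' @param method passed to \code{\link{critical_coupling}}.
#' @param points_per_decade sweep density.
#' @return an \code{\link{exponent_fit}} with \code{quantity =
#'   "gamma_c"}.
#' @export
gamma_exponent <- function(Q, n, window, method = "ratio",
                           points_per_decade = 20L) {
  grid <- log_grid(window, points_per_decade)
  gc <- vapply(grid, function(q)
    critical_coupling(q, Q, n, method = method)$gamma_c, 0)
  fit <- fit_loglog_slope(grid, gc, quantity = "gamma_c")
  fit
}

#' Eigenvalue shift from spatial diffusion
#'
#' A small spatial diffusivity \code{D} adds \code{(D / (Dr l^2)) k^2} to
#' every decay rate (a uniform additive shift of the whole spectrum).  At
#' low activity this shift dominates the \code{q^2} free relaxation and
#' changes the scaling of the slowest rate from \code{~ Pe^2 k^2} to
#' \code{~ (D / (Dr l^2)) k^2}; at high activity it is irrelevant.
#'
#' @param lambda complex decay rate(s).
#' @param D_ratio spatial-to-rotational diffusivity ratio
#'   \code{D / (Dr l^2)}, \code{>= 0}.
#' @param k dimensionless wave number.
#' @return shifted decay rate(s) \code{lambda + D_ratio * k^2}.
#' @examples
#' diffusive_shift(0, 0.5, 0.2)   # 0.02
#' @export
diffusive_shift <- function(lambda, D_ratio, k) {
  stopifnot(D_ratio >= 0)
  lambda + D_ratio * k^2
}

#' Two-regime exponent summary for polar and nematic interactions
#'
#' Computes the full set of scaling exponents \code{alpha} (slowest decay
#' rate), \code{beta_n} (projection onto harmonic \code{n}) and
#' \code{gamma = alpha - beta_n} (critical coupling, ratio method) in the
#' low- and high-activity windows, for polar (\code{n = 1}) and
#' higher-symmetry (\code{n = 2}) alignment.  Expected values: polar
#' \code{(2, 1, 1)} low and \code{(1/2, -1/8, 5/8)} high; nematic
#' \code{(2, 2, 0)} low, with the high-activity \code{beta} mode-independent
#' at \code{-1/8}.
#'
#' @param Q_low,Q_high truncation cutoffs for the two regimes.
#' @param low_window,high_window activity windows.
#' @param points_per_decade sweep density.
#' @return data frame with columns \code{symmetry}, \code{n},
#'   \code{regime}, \code{alpha}, \code{beta}, \code{gamma} and standard
#'   errors \code{alpha_se}, \code{beta_se}, \code{gamma_se}.
#' @export
table1_report <- function(Q_low = 50L, Q_high = 400L,
                          low_window = c(1e-3, 1e-2),
                          high_window = c(1e3, 1e4),
                          points_per_decade = 20L) {
  regimes <- list(low = list(Q = Q_low, window = low_window),
                  high = list(Q = Q_high, window = high_window))
  rows <- list()
  for (regime in names(regimes)) {
    spec <- regimes[[regime]]
    sw <- sweep_spectrum(log_grid(spec$window, points_per_decade), spec$Q,
                         n_proj = 2L)
    a <- fit_loglog_slope(sw$q, sw$re_lambda0, quantity = "re_lambda0")
    for (n in 1:2) {
      cn <- sw[[paste0("c", n)]]
      b <- fit_loglog_slope(sw$q, cn, quantity = paste0("c", n))
      g <- fit_loglog_slope(sw$q, sw$re_lambda0 / cn, quantity = "gamma_c")
      rows[[length(rows) + 1L]] <- data.frame(
        symmetry = if (n == 1) "polar" else "nematic", n = n,
        regime = regime, alpha = a$slope, beta = b$slope, gamma = g$slope,
        alpha_se = a$stderr, beta_se = b$stderr, gamma_se = g$stderr)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
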