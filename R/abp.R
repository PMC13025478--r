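#' Parameters for a free active-Brownian-particle simulation
#'
#' The free dynamics in non-dimensional units (time in \code{1/Dr},
#' length in the interaction length \code{l}) are
#' \code{dphi = sqrt(2) dW} and \code{dr = Pe (cos phi, sin phi) dt}: the
#' Peclet number \code{Pe = v0 / (Dr l)} is the only physical parameter.
#'
#' @param Pe Peclet number, \code{>= 0}.
#' @param n_particles integer \code{>= 1}.
#' @param dt time step in units of \code{1/Dr}; must be \code{<= 0.05} so
#'   that the per-step angular variance \code{2 dt} stays small.
#' @param t_total total simulated duration.
#' @param seed integer root seed; every particle derives its own stream
#'   from it, so changing \code{n_particles} does not reshuffle existing
#'   particles' trajectories.
#' @param save_every store every \code{save_every}-th step (default chosen
#'   to keep about 400 stored frames).
#' @return list of class \code{"abp_params"}.
#' @export
abp_params <- function(Pe, n_particles, dt, t_total, seed,
                       save_every = NULL) {
  stopifnot(Pe >= 0, n_particles >= 1, n_particles == round(n_particles),
            dt > 0, t_total > 0, seed == round(seed))
  if (dt > 0.05)
    stop("dt > 0.05: reduce the step so the angular increment variance 2*dt stays small",
         call. = FALSE)
  n_steps <- ceiling(t_total / dt)
  if (is.null(save_every))
    save_every <- max(1L, floor(n_steps / 400))
  structure(list(Pe = Pe, n_particles = as.integer(n_particles), dt = dt,
                 t_total = t_total, seed = as.integer(seed),
                 n_steps = as.integer(n_steps),
                 save_every = as.integer(save_every)),
            class = "abp_params")
}

# deterministic per-particle seed derived from the root seed; a fixed
# multiplicative counter scheme keeps particle j's stream independent of
# the total particle count
particle_seed <- function(seed, j) {
  as.integer((as.double(seed) + as.double(j) * 1000003) %% 2147483647)
}

#' Simulate free active Brownian particles
#'
#' Euler-Maruyama integration of the free dynamics: per step,
#' \code{phi <- phi + sqrt(2 dt) N(0,1)} (the angular process is exactly
#' Gaussian, so this part carries no integrator bias) and
#' \code{(x, y) <- (x, y) + Pe dt (cos phi, sin phi)} (positional bias
#' \code{O(dt)}).  Each particle consumes its own seeded stream, so the
#' ensemble is reproducible bit-for-bit and extending the ensemble leaves
#' existing trajectories untouched.  All particles start at the origin
#' with angle 0; the measured observables (angular increments, Fourier-mode
#' decay) are invariant under the choice of initial condition after the
#' rotational decorrelation time of order 1.
#'
#' @param params an \code{\link{abp_params}} object.
#' @return object of class \code{"trajectory_ensemble"}: list with
#'   \code{times} (stored frame times, starting at 0), matrices \code{x},
#'   \code{y}, \code{phi} (frames x particles) and \code{params}.
#' @examples
#' tr <- simulate_abp(abp_params(Pe = 1, n_particles = 5, dt = 0.01,
#'                               t_total = 2, seed = 1))
#' dim(tr$x)
#' @export
simulate_abp <- function(params) {
  stopifnot(inherits(params, "abp_params"))
  ns <- params$n_steps
  keep <- seq(0L, ns, by = params$save_every)
  nf <- length(keep)
  x <- y <- phi <- matrix(0, nrow = nf, ncol = params$n_particles)
  sdt <- sqrt(2 * params$dt)
  for (j in seq_len(params$n_particles)) {
    set.seed(particle_seed(params$seed, j))
    ph <- cumsum(c(0, sdt * stats::rnorm(ns)))
    # displacement uses the pre-step angle (explicit Euler)
    xs <- c(0, params$Pe * params$dt * cumsum(cos(ph[-(ns + 1L)])))
    ys <- c(0, params$Pe * params$dt * cumsum(sin(ph[-(ns + 1L)])))
    x[, j] <- xs[keep + 1L]
    y[, j] <- ys[keep + 1L]
    phi[, j] <- ph[keep + 1L]
  }
  structure(list(times = keep * params$dt, x = x, y = y, phi = phi,
                 params = params),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  p <- x$params
  cat(sprintf("ABP ensemble: %d particles, Pe = %g, dt = %g, t = %g (%d frames)\n",
              p$n_particles, p$Pe, p$dt, p$t_total, length(x$times)))
  invisible(x)
}

#' Decay rate of a spatial Fourier mode from trajectories
#'
#' Measures the self-intermediate scattering function
#' \code{F(k, t) = < exp(i k (x(t0 + t) - x(t0))) >} (average over
#' particles and strided time origins; real by the x -> -x symmetry of the
#' free dynamics) and fits its tail over \code{t} in
#' \code{[2, 5] / Re(lambda_hat)}, where \code{lambda_hat} is the spectral
#' prediction for the slowest decay rate at activity \code{q = 2 k Pe}
#' (computed from the operator unless supplied).  Below the first
#' exceptional point the tail is a plain exponential and the fit is
#' log-linear; past it the slowest pair is complex-conjugate and the tail
#' is the damped oscillation
#' \code{F ~ exp(-r t) (u cos(w t) + v sin(w t))} with \code{w =
#' |Im(lambda_hat)|} fixed by the spectral module, and \code{r} is fitted
#' by profiled least squares.  In both cases the fitted rate recovers
#' \code{Re lambda0(q)} of the free Fokker-Planck operator; the
#' uncertainty is a seeded bootstrap over particles.
#'
#' @param traj a \code{"trajectory_ensemble"}.
#' @param k dimensionless wave number, \code{>= 0}; at \code{k = 0} the
#'   density is conserved and the rate is exactly 0.
#' @param lambda_hat optional (complex) decay-rate prediction fixing the
#'   fit window and oscillation frequency.
#' @param Q cutoff for the internal spectral prediction (default 60).
#' @param n_boot bootstrap resamples (default 1000).
#' @param boot_seed seed of the bootstrap resampling.
#' @return list with \code{rate}, \code{se} (bootstrap standard error),
#'   \code{ci} (2.5/97.5 percent bootstrap interval), \code{lambda_hat},
#'   \code{q}, \code{fit_window}, \code{n_lags}.
#' @export
estimate_mode_decay <- function(traj, k, lambda_hat = NULL, Q = 60L,
                                n_boot = 1000L, boot_seed = 1L) {
  stopifnot(inherits(traj, "trajectory_ensemble"), k >= 0)
  p <- traj$params
  if (k == 0)
    return(list(rate = 0, se = 0, ci = c(0, 0), lambda_hat = 0,
                q = 0, fit_window = c(NA, NA), n_lags = 0L))
  q <- 2 * k * p$Pe
  if (is.null(lambda_hat)) {
    sm <- slowest_mode(diagonalize(build_decay_operator(q, Q)))
    lambda_hat <- sm$lambda0
  }
  rl <- Re(lambda_hat)
  omega <- abs(Im(lambda_hat))
  oscillatory <- omega > 1e-9 * max(1, abs(lambda_hat))
  if (p$t_total < 10 / rl)
    stop(sprintf("t_total = %g too short: need >= 10 / Re(lambda) ~ %g",
                 p$t_total, 10 / rl), call. = FALSE)
  frame_dt <- traj$times[2L] - traj$times[1L]
  lag_lo <- max(1L, floor((2 / rl) / frame_dt))
  lag_hi <- min(length(traj$times) - 2L, ceiling((5 / rl) / frame_dt))
  lags <- unique(round(seq(lag_lo, lag_hi, length.out = 25L)))
  stride <- max(1L, round((1 / rl) / frame_dt))
  nf <- length(traj$times)
  # per-particle, per-lag origin-averaged phase factors
  z <- vapply(lags, function(l) {
    origins <- seq(1L, nf - l, by = stride)
    dx <- traj$x[origins + l, , drop = FALSE] -
      traj$x[origins, , drop = FALSE]
    colMeans(exp(1i * k * dx))
  }, complex(p$n_particles))
  z <- matrix(Re(z), nrow = p$n_particles)   # F is real by symmetry
  Fk <- colMeans(z)
  se_F <- apply(z, 2L, stats::sd) / sqrt(p$n_particles)
  if (sqrt(mean(Fk^2)) < 3 * sqrt(mean(se_F^2)))
    stop("insufficient signal: F(k, t) below 3x its standard error in the fit window",
         call. = FALSE)
  tt <- lags * frame_dt
  fit_rate <- if (!oscillatory) {
    function(Fvals) {
      keep <- Fvals > 0
      if (sum(keep) < 5L) return(NA_real_)
      -unname(stats::lsfit(tt[keep], log(Fvals[keep]))$coefficients[2L])
    }
  } else {
    # profiled least squares: linear in (u, v) at fixed rate r
    function(Fvals) {
      sse <- function(r) {
        X <- exp(-r * tt) * cbind(cos(omega * tt), sin(omega * tt))
        res <- stats::lsfit(X, Fvals, intercept = FALSE)$residuals
        sum(res^2)
      }
      stats::optimize(sse, c(rl / 4, rl * 4))$minimum
    }
  }
  rate <- fit_rate(Fk)
  set.seed(boot_seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(p$n_particles, replace = TRUE)
    fit_rate(colMeans(z[idx, , drop = FALSE]))
  }, 0)
  boots <- boots[is.finite(boots)]
  list(rate = rate, se = stats::sd(boots),
       ci = unname(stats::quantile(boots, c(0.025, 0.975))),
       lambda_hat = lambda_hat, q = q,
       fit_window = c(2, 5) / rl, n_lags = length(lags))
}
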