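#' Locate an exceptional point by bisection on the real-eigenvalue count
#'
#' The r-th exceptional point is the activity at which branches \code{2r}
#' and \code{2r + 1} coalesce and turn from a real pair into a
#' complex-conjugate pair; the count of real eigenvalues drops from
#' \code{Q + 1 - 2r} to \code{Q + 1 - 2(r + 1)} there.  Bisection on this
#' integer-valued, per-pair monotone count is robust to near-degeneracies
#' between non-coalescing branches, which is why it is preferred over
#' minimal eigenvalue-distance detection.  The defectiveness of the matrix
#' exactly at the exceptional point is not certified numerically (the
#' eigenvector condition number diverges there); the point is characterized
#' by the realness transition alone.
#'
#' @param r pair index (branches \code{2r}, \code{2r+1}), integer
#'   \code{>= 0}.
#' @param Q truncation cutoff, or \code{NULL} if \code{op} is a
#'   \code{\link{two_mode_model}}.
#' @param bracket numeric \code{c(q_lo, q_hi)} straddling exactly one
#'   realness transition of pair \code{r}.
#' @param tol bisection tolerance in \code{q}, default \code{1e-6}.
#' @param boundary passed to \code{\link{build_decay_operator}}.
#' @param two_mode logical; locate the exceptional point of the two-mode
#'   model (at \code{q = 1}) instead of the full truncation.
#' @return object of class \code{"exceptional_point"}: list with \code{r},
#'   \code{q_star}, \code{lambda_star} (eigenvalue at coalescence, taken as
#'   the mean of the coalescing pair just above \code{q_star}), \code{Q},
#'   \code{tol}.
#' @examples
#' locate_ep(0, Q = 3, bracket = c(1, 2), tol = 1e-4)$q_star  # ~1.4688
#' @export
locate_ep <- function(r, Q, bracket, tol = 1e-6, boundary = "mathieu",
                      two_mode = FALSE) {
  stopifnot(r >= 0, r == round(r), length(bracket) == 2L,
            bracket[1] < bracket[2], tol > 0)
  count <- function(q) {
    if (two_mode) count_real_eigenvalues(q, Q = NULL, op = two_mode_model(q))
    else count_real_eigenvalues(q, Q, boundary = boundary)
  }
  ntot <- if (two_mode) 2L else Q + 1L
  thresh <- ntot - 2L * r            # count at/above means pair r still real
  c_lo <- count(bracket[1]); c_hi <- count(bracket[2])
  if (c_lo < thresh || c_hi > thresh - 2L)
    stop(sprintf(paste0("bracket does not straddle the transition of pair ",
                        "r = %d: counts %d (at q = %g) and %d (at q = %g), ",
                        "expected >= %d and <= %d"),
                 r, c_lo, bracket[1], c_hi, bracket[2], thresh, thresh - 2L),
         call. = FALSE)
  if (c_lo - c_hi != 2L)
    stop(sprintf(paste0("bracket contains more than one transition ",
                        "(count drops %d -> %d); narrow it"),
                 c_lo, c_hi), call. = FALSE)
  lo <- bracket[1]; hi <- bracket[2]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (count(mid) >= thresh) lo <- mid else hi <- mid
  }
  q_star <- (lo + hi) / 2
  vals <- if (two_mode) {
    diagonalize(two_mode_model(hi))$values
  } else {
    spectrum_values(hi, Q, boundary)
  }
  pair <- vals[order(Re(vals))][c(2L * r + 1L, 2L * r + 2L)]
  structure(list(r = as.integer(r), q_star = q_star,
                 lambda_star = mean(pair),
                 Q = if (two_mode) 1L else as.integer(Q), tol = tol),
            class = "exceptional_point")
}

#' @export
print.exceptional_point <- function(x, ...) {
  cat(sprintf("exceptional point r = %d: q* = %.8g, lambda* = %.6g%+.2gi (Q = %d)\n",
              x$r, x$q_star, Re(x$lambda_star), Im(x$lambda_star), x$Q))
  invisible(x)
}

#' Exceptional point of the two-mode model
#'
#' Locates the coalescence of the \code{\link{two_mode_model}} eigenvalues
#' \code{(1 +/- sqrt(1 - q^2))/2} by bisection on the realness transition;
#' the result is \code{q* = 1} with \code{lambda* = 1/2} to the requested
#' tolerance.
#'
#' @param tol bisection tolerance in \code{q}.
#' @return an \code{"exceptional_point"} object.
#' @export
two_mode_ep <- function(tol = 1e-10) {
  locate_ep(0L, Q = NULL, bracket = c(0.5, 1.5), tol = tol, two_mode = TRUE)
}

#' Scan the cascade of exceptional points
#'
#' Sweeps the count of real eigenvalues on a logarithmic activity grid and
#' bisects every decrement to localize the exceptional points up to
#' \code{q_max}.  Pair indices are assigned from the count itself,
#' \code{r = (Q + 1 - count_before) / 2}.
#'
#' Deep in the advective regime the operator is strongly non-normal and
#' individual eigenvalues in the crossover region of the spectrum carry a
#' large condition number, so the raw real-eigenvalue count can jitter at
#' fine activity scales.  The scan therefore works with the monotone
#' non-increasing envelope of the sampled counts (the count can only drop
#' as activity grows), clamps refinement evaluations into the locally
#' admissible count range, and — when several transitions persist inside an
#' interval narrower than \code{rel_floor} times the activity — records the
#' unresolved points jointly at the interval midpoint rather than failing.
#' In the well-conditioned regime this reduces exactly to per-transition
#' bisection.
#'
#' @param Q truncation cutoff, \code{>= 3}.
#' @param q_max upper activity bound; a warning is issued unless
#'   \code{q_max << Q^2} (the truncation-faithful regime).
#' @param q_min lower bound of the scan (default 1, below the first
#'   exceptional point of the operator).
#' @param points_per_decade scan grid density (default 60).
#' @param tol bisection tolerance in \code{q}.
#' @param rel_floor relative width below which clustered or
#'   noise-straddled transitions are no longer split (default \code{1e-3}).
#' @param validate \code{"none"} (return every detected transition) or
#'   \code{"mathieu"}: cross-check each detected point against the
#'   independent continued-fraction double point
#'   (\code{\link{mathieu_double_point}}) and truncate the cascade at the
#'   first disagreement beyond 0.5 percent — the double-precision
#'   reliability frontier, beyond which neither route can certify the
#'   realness of the relevant eigenvalue pair.  A warning reports how many
#'   detections were dropped.
#' @param boundary passed to \code{\link{build_decay_operator}}.
#' @return data frame of class \code{"ep_cascade"} with columns \code{r},
#'   \code{q_star}, \code{re_lambda_star}, \code{im_lambda_star}, \code{Q},
#'   \code{tol}, ordered by \code{q_star}.
#' @export
scan_cascade <- function(Q, q_max, q_min = 1, points_per_decade = 60L,
                         tol = 1e-6, rel_floor = 1e-3,
                         validate = c("none", "mathieu"),
                         boundary = "mathieu") {
  validate <- match.arg(validate)
  stopifnot(Q >= 3, q_max > q_min, q_min > 0)
  if (q_max > Q^2 / 10)
    warning("q_max is not small against Q^2; truncation artefacts likely",
            call. = FALSE)
  n_pts <- max(2L, ceiling(points_per_decade * log10(q_max / q_min)))
  grid <- 10^seq(log10(q_min), log10(q_max), length.out = n_pts)
  counts <- vapply(grid, count_real_eigenvalues, 0L, Q = Q,
                   boundary = boundary)
  env <- cummin(counts)               # physical count is non-increasing
  count_clamped <- function(q, c_hi, c_lo) {
    min(max(count_real_eigenvalues(q, Q, boundary = boundary), c_hi), c_lo)
  }
  eps <- list()
  push <- function(q_star, c_before) {
    r <- (Q + 1L - c_before) / 2L
    vals <- spectrum_values(q_star * (1 + 10 * rel_floor), Q, boundary)
    pair <- vals[order(Re(vals))][c(2L * r + 1L, 2L * r + 2L)]
    eps[[length(eps) + 1L]] <<- list(r = as.integer(r), q_star = q_star,
                                     lambda_star = mean(pair))
  }
  segment <- function(lo, hi, c_lo, c_hi) {
    n_tr <- (c_lo - c_hi) / 2L
    if (n_tr == 0L) return(invisible())
    if (n_tr == 1L) {
      a <- lo; b <- hi
      while (b - a > tol && (b - a) > rel_floor * a * 1e-3) {
        mid <- (a + b) / 2
        if (count_clamped(mid, c_hi, c_lo) >= c_lo) a <- mid else b <- mid
      }
      push((a + b) / 2, c_lo)
    } else if (hi - lo < rel_floor * lo) {
      # unresolved cluster: record all transitions at the midpoint
      for (j in seq_len(n_tr)) push(sqrt(lo * hi), c_lo - 2L * (j - 1L))
    } else {
      mid <- sqrt(lo * hi)
      c_mid <- count_clamped(mid, c_hi, c_lo)
      segment(lo, mid, c_lo, c_mid)
      segment(mid, hi, c_mid, c_hi)
    }
  }
  for (g in seq_len(n_pts - 1L)) {
    if (env[g] > env[g + 1L])
      segment(grid[g], grid[g + 1L], env[g], env[g + 1L])
  }
  out <- data.frame(
    r = vapply(eps, `[[`, 0L, "r"),
    q_star = vapply(eps, `[[`, 0, "q_star"),
    re_lambda_star = vapply(eps, function(e) Re(e$lambda_star), 0),
    im_lambda_star = vapply(eps, function(e) Im(e$lambda_star), 0),
    Q = rep(as.integer(Q), length(eps)), tol = rep(tol, length(eps)))
  out <- out[order(out$q_star), , drop = FALSE]
  rownames(out) <- NULL
  if (validate == "mathieu" && nrow(out) > 0L) {
    keep <- 0L
    for (i in seq_len(min(nrow(out), 21L))) {
      ref <- tryCatch(mathieu_double_point(out$r[i], tol = 1e-6),
                      error = function(e) NULL)
      if (is.null(ref) ||
          abs(out$q_star[i] - ref$q_star) > 5e-3 * ref$q_star) break
      keep <- i
    }
    if (keep < nrow(out)) {
      warning(sprintf(paste0(
        "cascade truncated at the double-precision reliability frontier: ",
        "%d of %d detections beyond q = %.4g failed the continued-fraction ",
        "cross-check and were dropped"),
        nrow(out) - keep, nrow(out),
        if (keep > 0L) out$q_star[keep] else q_min), call. = FALSE)
      out <- out[seq_len(keep), , drop = FALSE]
    }
  }
  class(out) <- c("ep_cascade", "data.frame")
  out
}

#' Density exponent of the exceptional-point cascade
#'
#' The cumulative number of exceptional points grows as
#' \code{N(q) ~ q^(1/2)}, i.e. the density \code{dN/dq ~ q^(-1/2)}.  This
#' fits \code{log N} against \code{log q_star} over a window and reports
#' the count slope minus one as the density exponent.
#'
#' @param eps an \code{"ep_cascade"} data frame (or any data frame with a
#'   \code{q_star} column, ordered or not).
#' @param window numeric \code{c(q_lo, q_hi)}; at least 5 exceptional
#'   points must fall inside.
#' @return an \code{\link{exponent_fit}} object; \code{slope} is the
#'   density exponent (count slope - 1), \code{quantity = "ep_density"}.
#' @export
ep_count_exponent <- function(eps, window) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  qs <- sort(eps$q_star)
  N <- seq_along(qs)
  keep <- qs >= window[1] & qs <= window[2]
  if (sum(keep) < 5L)
    stop(sprintf("only %d exceptional points inside the window; >= 5 needed",
                 sum(keep)), call. = FALSE)
  fit <- fit_loglog_slope(qs[keep], N[keep], quantity = "ep_count")
  fit$slope <- fit$slope - 1
  fit$quantity <- "ep_density"
  fit
}
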