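#' Coupled exceptional-point toy model
#'
#' A real 4x4 matrix built from two 2x2 blocks that each carry one
#' exceptional point — at \code{eps = 1} (eigenvalues \code{+/- sqrt(1 -
#' eps)}) and at \code{eps = 20} (eigenvalues \code{10 +/- sqrt(20 -
#' eps)}), the blocks being offset by 10 — plus a nearest-neighbour
#' coupling of strength \code{c} that grows with the control parameter.
#' The coupling growth \code{c * sqrt(eps)} mirrors the square-root growth
#' of the number of exceptional points in the full operator cascade; a
#' linear-in-\code{eps} variant is available for sensitivity analysis.
#' The model illustrates how the interplay of several coupled exceptional
#' points generates fractional power laws in eigenvector projections far
#' from any individual exceptional point.
#'
#' The block entries are a reconstruction: the block structure, the
#' uncoupled exceptional points at 1 and 20, the offset 10, and the
#' nearest-neighbour coupling pattern are fixed; the placement of
#' \code{1 - eps} versus 1 inside each block is verified through the
#' numerically detected exceptional-point locations rather than assumed.
#'
#' @param epsilon control parameter, \code{>= 0}.
#' @param c coupling constant (default 0.1).
#' @param coupling \code{"sqrt"} (default, coupling \code{c sqrt(eps)}) or
#'   \code{"linear"} (\code{c eps}).
#' @return object of class \code{"toy_ep_model"}: list with
#'   \code{matrix} (real 4x4), \code{epsilon}, \code{c}, \code{coupling}.
#' @examples
#' eigen(toy_matrix(0, c = 0)$matrix)$values   # 10 +/- sqrt(20), +/- 1
#' @export
toy_matrix <- function(epsilon, c = 0.1, coupling = c("sqrt", "linear")) {
  coupling <- match.arg(coupling)
  stopifnot(epsilon >= 0)
  M <- rbind(c(0, 1 - epsilon, 0, 0),
             c(1, 0,           0, 0),
             c(0, 0, 10, 20 - epsilon),
             c(0, 0, 1,  10))
  P <- rbind(c(0, 1, 0, 0),
             c(1, 0, 1, 0),
             c(0, 1, 0, 1),
             c(0, 0, 1, 0))
  g <- if (coupling == "sqrt") c * sqrt(epsilon) else c * epsilon
  structure(list(matrix = M + g * P, epsilon = epsilon, c = c,
                 coupling = coupling),
            class = "toy_ep_model")
}

# eigen-decomposition of the toy model with the package's ordering and
# phase conventions
toy_eigen <- function(model) {
  e <- eigen(model$matrix)
  ord <- order(Re(e$values), Im(e$values))
  vals <- e$values[ord]
  vecs <- apply(e$vectors[, ord, drop = FALSE], 2L, fix_phase)
  list(values = vals, vectors = vecs)
}

#' Sweep the toy model over its control parameter
#'
#' @param eps_grid vector of control-parameter values.
#' @param c coupling constant.
#' @param coupling see \code{\link{toy_matrix}}.
#' @return data frame with one row per (eps, eigenvalue index): columns
#'   \code{epsilon}, \code{index} (ascending real part), \code{re_lambda},
#'   \code{im_lambda}, \code{p4} (magnitude of the fourth component of the
#'   unit-norm eigenvector, the projection onto the \code{(0,0,0,1)}
#'   direction).
#' @export
toy_spectrum <- function(eps_grid, c = 0.1, coupling = "sqrt") {
  rows <- lapply(eps_grid, function(eps) {
    te <- toy_eigen(toy_matrix(eps, c, coupling))
    data.frame(epsilon = eps, index = 1:4,
               re_lambda = Re(te$values), im_lambda = Im(te$values),
               p4 = abs(te$vectors[4L, ]))
  })
  do.call(rbind, rows)
}

#' Exceptional points of the toy model
#'
#' Scans the control parameter for realness transitions of the spectrum
#' (the real matrix guarantees a conjugation-closed spectrum, so complex
#' eigenvalues appear in pairs) and bisects each transition.  With
#' \code{c = 0.1} the two exceptional points sit slightly above the
#' uncoupled locations 1 and 20, shifted by the perturbative coupling.
#'
#' @param c coupling constant.
#' @param eps_range scan range, default \code{c(0.1, 50)}.
#' @param n_scan number of scan points.
#' @param tol bisection tolerance in \code{eps}.
#' @param coupling see \code{\link{toy_matrix}}.
#' @return data frame with columns \code{eps_star} and \code{n_real_before},
#'   \code{n_real_after}.
#' @export
toy_exceptional_points <- function(c = 0.1, eps_range = c(0.1, 50),
                                   n_scan = 400L, tol = 1e-8,
                                   coupling = "sqrt") {
  n_real <- function(eps) {
    v <- eigen(toy_matrix(eps, c, coupling)$matrix, only.values = TRUE)$values
    sum(is_real_eigenvalue(as.complex(v)))
  }
  grid <- seq(eps_range[1], eps_range[2], length.out = n_scan)
  counts <- vapply(grid, n_real, 0L)
  idx <- which(diff(counts) != 0L)
  rows <- lapply(idx, function(i) {
    lo <- grid[i]; hi <- grid[i + 1L]
    c_lo <- counts[i]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (n_real(mid) == c_lo) lo <- mid else hi <- mid
    }
    data.frame(eps_star = (lo + hi) / 2, n_real_before = counts[i],
               n_real_after = counts[i + 1L])
  })
  if (length(rows) == 0L)
    return(data.frame(eps_star = numeric(), n_real_before = integer(),
                      n_real_after = integer()))
  do.call(rbind, rows)
}

#' Projection exponent of the toy model's slowest mode
#'
#' Sweeps the control parameter beyond both exceptional points, records the
#' magnitude of the fourth component of the unit-norm eigenvector of
#' minimal real part, and fits its log-log slope.  This is the toy-model
#' analogue of the \code{q^(-1/8)} Fourier-projection law of the full
#' operator: the sqrt-growing coupling of the two exceptional points
#' generates a small negative fractional exponent over the decades beyond
#' the second exceptional point.  With \code{c = 0}, the blocks decouple
#' and the projection is a structural zero, reported as an error.
#'
#' @param c coupling constant.
#' @param window control-parameter window \code{c(eps_lo, eps_hi)}; a
#'   warning is issued if it reaches below \code{eps = 25} (close to or
#'   before the second exceptional point, where the model is not meant to
#'   be faithful).
#' @param points_per_decade sweep density.
#' @param coupling see \code{\link{toy_matrix}}.
#' @return an \code{\link{exponent_fit}} with \code{quantity = "toy_p4"}.
#' @export
toy_projection_exponent <- function(c = 0.1, window = c(1e2, 1e4),
                                    points_per_decade = 20L,
                                    coupling = "sqrt") {
  stopifnot(length(window) == 2L, window[1] < window[2], window[1] > 0)
  if (window[1] < 25)
    warning(paste("window reaches below eps = 25: the low-eps behaviour of",
                  "the toy model is not faithful"), call. = FALSE)
  grid <- log_grid(window, points_per_decade)
  p4 <- vapply(grid, function(eps) {
    te <- toy_eigen(toy_matrix(eps, c, coupling))
    abs(te$vectors[4L, which.min(Re(te$values))])
  }, 0)
  if (all(p4 < 1e-13))
    stop("structural zero: the slowest mode has no fourth component (c = 0?)",
         call. = FALSE)
  fit_loglog_slope(grid, p4, quantity = "toy_p4")
}
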