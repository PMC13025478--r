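#' Truncated decay operator of a free active Brownian particle
#'
#' Builds the \code{(Q+1) x (Q+1)} matrix representation of the decay
#' operator governing the relaxation of the angular Fourier modes of the
#' one-particle distribution of a free active Brownian particle at wave
#' number \code{k} and Peclet number \code{Pe}.  The single control
#' parameter is the activity \code{q = 2 * k * Pe}; eigenvalues \code{lambda}
#' of this matrix are decay rates (\code{Re(lambda) >= 0} throughout the
#' package) and are related to the characteristic values \code{a} of the
#' Mathieu equation with purely imaginary parameter by \code{a = 4 * lambda}.
#'
#' The matrix acts on the even cosine sector \code{cos(m * phi)},
#' \code{m = 0, ..., Q}.  Its diagonal is \code{m^2} (rotational diffusion)
#' and the advection couples neighbouring harmonics with strength
#' \code{-i q / 4}.  Folding the full Fourier line \code{m in Z} onto
#' \code{m >= 0} makes the bond between the density mode \code{m = 0} and
#' the polar mode \code{m = 1} special: in the L2-orthonormal angular basis
#' it carries the weight \code{-i q sqrt(2) / 4}.  This is the
#' \code{boundary = "mathieu"} default, for which the truncated spectrum
#' converges to the even pi-periodic Mathieu characteristics
#' (\code{lambda0 = q^2/8 + O(q^4)} at small activity, first eigenvalue
#' collision at \code{q ~ 1.46877}).  \code{boundary = "uniform"} treats the
#' 0-1 bond like all others; that variant is the tridiagonal truncation
#' whose zero-diffusivity limit is an exact Toeplitz matrix and is the
#' reference operator for the advection-limit analysis in
#' \code{\link{toeplitz_limit}}.
#'
#' @param q activity parameter, non-negative scalar.
#' @param Q truncation cutoff, integer \code{>= 1}; harmonics
#'   \code{0, ..., Q} are retained.
#' @param boundary treatment of the 0-1 bond, \code{"mathieu"} (folded,
#'   default) or \code{"uniform"}.
#' @return An object of class \code{"decay_operator"}: a list with elements
#'   \code{matrix} (complex, tridiagonal, complex-symmetric), \code{q},
#'   \code{Q}, \code{boundary} and \code{trace}
#'   (\code{= Q (Q+1) (2Q+1) / 6}, independent of \code{q}).
#' @seealso \code{\link{diagonalize}}, \code{\link{two_mode_model}},
#'   \code{\link{activity_map}}
#' @examples
#' op <- build_decay_operator(q = 0.5, Q = 4)
#' Re(sum(diag(op$matrix)))          # 30 = 4*5*9/6
#' @export
build_decay_operator <- function(q, Q, boundary = c("mathieu", "uniform")) {
  boundary <- match.arg(boundary)
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0)
    stop("'q' must be a single non-negative number", call. = FALSE)
  if (!is.numeric(Q) || length(Q) != 1L || is.na(Q) || Q < 1 || Q != round(Q))
    stop("'Q' must be a single integer >= 1", call. = FALSE)
  Q <- as.integer(Q)
  b <- bond_strengths(q, Q, boundary)
  A <- diag((0:Q)^2) + 0i
  idx <- seq_len(Q)
  A[cbind(idx, idx + 1L)] <- -1i * b
  A[cbind(idx + 1L, idx)] <- -1i * b
  structure(
    list(matrix = A, q = q, Q = Q, boundary = boundary,
         trace = Q * (Q + 1) * (2 * Q + 1) / 6),
    class = "decay_operator"
  )
}

# off-diagonal bond magnitudes (entry is -1i * b); the folded 0-1 bond is
# sqrt(2)-weighted in the orthonormal cosine basis
bond_strengths <- function(q, Q, boundary) {
  b <- rep(q / 4, Q)
  if (boundary == "mathieu" && Q >= 1L) b[1L] <- q * sqrt(2) / 4
  b
}

# real similarity transform D A D^-1 with D = diag(i^m): tridiagonal real
# matrix with +/- b off-diagonals; same spectrum, eigenvectors map back via
# v_A = i^(-m) * v_B.  Keeps conjugate symmetry of the spectrum exact and
# real eigenvalues exactly real, which the exceptional-point bisection
# relies on.
real_form <- function(q, Q, boundary = "mathieu") {
  b <- bond_strengths(q, Q, boundary)
  B <- diag((0:Q)^2)
  idx <- seq_len(Q)
  B[cbind(idx, idx + 1L)] <- -b
  B[cbind(idx + 1L, idx)] <- b
  B
}

#' Map between activity, wave number and Peclet number
#'
#' The free dynamics depend on wave number \code{k} and Peclet number
#' \code{Pe} only through the combination \code{q = 2 k Pe}; decay rates
#' \code{lambda} correspond to Mathieu characteristic values \code{a = 4
#' lambda}.  Supply either \code{q} or both \code{k} and \code{Pe}.
#'
#' @param q activity parameter (optional if \code{k}, \code{Pe} given).
#' @param k dimensionless wave number, \code{>= 0}.
#' @param Pe Peclet number, \code{>= 0}.
#' @param lambda optional decay rate(s) for which the Mathieu scale
#'   \code{a = 4 lambda} is reported.
#' @return list with \code{q}, \code{k}, \code{Pe} (NA when not supplied)
#'   and \code{a}.
#' @examples
#' activity_map(k = 0.5, Pe = 1)$q   # 1
#' @export
activity_map <- function(q = NULL, k = NULL, Pe = NULL, lambda = NULL) {
  if (is.null(q)) {
    if (is.null(k) || is.null(Pe))
      stop("supply 'q' or both 'k' and 'Pe'", call. = FALSE)
    if (k < 0 || Pe < 0) stop("'k' and 'Pe' must be non-negative", call. = FALSE)
    q <- 2 * k * Pe
  } else {
    if (q < 0) stop("'q' must be non-negative", call. = FALSE)
    if (!is.null(k) && !is.null(Pe) &&
        abs(q - 2 * k * Pe) > 1e-12 * max(1, q))
      stop("inconsistent parameters: q != 2 * k * Pe", call. = FALSE)
  }
  list(q = q, k = if (is.null(k)) NA_real_ else k,
       Pe = if (is.null(Pe)) NA_real_ else Pe,
       a = if (is.null(lambda)) NULL else 4 * lambda)
}

#' Two-mode model of an exceptional point
#'
#' The minimal two-mode (density + polar) caricature of the decay operator,
#' \code{matrix(c(0, -iq/2, -iq/2, 1), 2, 2)}.  Its eigenvalues
#' \code{(1 +/- sqrt(1 - q^2)) / 2} are real and distinct for \code{q < 1},
#' coalesce at the exceptional point \code{q = 1} (where the matrix is
#' defective with the single eigenvalue 1/2) and form a complex-conjugate
#' pair with common real part 1/2 beyond it.
#'
#' @param q activity parameter, non-negative scalar.
#' @return object of class \code{"decay_operator"} with
#'   \code{boundary = "two_mode"}.
#' @seealso \code{\link{two_mode_ep}}
#' @export
two_mode_model <- function(q) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0)
    stop("'q' must be a single non-negative number", call. = FALSE)
  A <- matrix(c(0, -1i * q / 2, -1i * q / 2, 1), 2L, 2L)
  structure(list(matrix = A, q = q, Q = 1L, boundary = "two_mode", trace = 1),
            class = "decay_operator")
}

#' @export
print.decay_operator <- function(x, ...) {
  cat(sprintf("decay operator: Q = %d, q = %g, boundary = %s, trace = %g\n",
              x$Q, x$q, x$boundary, x$trace))
  invisible(x)
}

#' Diagonalize a decay operator
#'
#' Computes all eigenvalues and unit-norm right eigenvectors of a
#' \code{\link{build_decay_operator}} matrix.  Internally the complex
#' tridiagonal matrix is transformed by the diagonal similarity
#' \code{diag(i^m)} to a real matrix, so that the computed spectrum is
#' exactly closed under complex conjugation and eigenvalues below the first
#' exceptional point come out exactly real.  Eigenvalues are sorted by
#' ascending real part (ties: ascending imaginary part) and each
#' eigenvector's gauge is fixed by making its largest-magnitude component
#' real and positive.
#'
#' @param op a \code{"decay_operator"} object.
#' @return object of class \code{"spectral_decomposition"}: list with
#'   \code{values} (complex eigenvalues, sorted), \code{vectors} (complex
#'   matrix, one unit-norm column per eigenvalue), \code{residuals}
#'   (\code{max |A v - lambda v|} per pair), \code{q}, \code{Q},
#'   \code{boundary}, \code{trace}.
#' @examples
#' dec <- diagonalize(build_decay_operator(q = 0, Q = 4))
#' Re(dec$values)    # 0 1 4 9 16
#' @export
diagonalize <- function(op) {
  stopifnot(inherits(op, "decay_operator"))
  if (op$boundary == "two_mode") {
    e <- eigen(rbind(c(0, -op$q / 2), c(op$q / 2, 1)))
    D <- c(1, 1i)
  } else {
    e <- eigen(real_form(op$q, op$Q, op$boundary))
    D <- 1i^(0:op$Q)
  }
  vals <- as.complex(e$values)
  vecs <- (1 / D) * e$vectors          # back to the complex-symmetric basis
  ord <- order(Re(vals), Im(vals))
  vals <- vals[ord]
  vecs <- vecs[, ord, drop = FALSE]
  vecs <- apply(vecs, 2L, fix_phase)
  if (is.null(dim(vecs))) vecs <- matrix(vecs, ncol = length(vals))
  res <- vapply(seq_along(vals), function(j) {
    max(abs(op$matrix %*% vecs[, j] - vals[j] * vecs[, j]))
  }, 0)
  nrmA <- max(abs(op$matrix))
  if (any(!is.finite(res)) || max(res) > 1e-8 * max(1, nrmA))
    stop(sprintf("eigensolver failed residual contract at q = %g, Q = %d",
                 op$q, op$Q), call. = FALSE)
  structure(
    list(values = vals, vectors = vecs, residuals = res,
         q = op$q, Q = op$Q, boundary = op$boundary, trace = op$trace),
    class = "spectral_decomposition"
  )
}

# unit norm and largest-magnitude component real positive
fix_phase <- function(v) {
  v <- v / sqrt(sum(abs(v)^2))
  j <- which.max(abs(v))
  ph <- v[j] / abs(v[j])
  v / ph
}

#' @export
print.spectral_decomposition <- function(x, ...) {
  cat(sprintf("spectral decomposition: Q = %d, q = %g (%s)\n",
              x$Q, x$q, x$boundary))
  cat("slowest eigenvalues:\n")
  print(utils::head(x$values, 4L))
  invisible(x)
}

#' Number of real eigenvalues at a given activity
#'
#' Each exceptional point converts one pair of real eigenvalues into a
#' complex-conjugate pair, so the count of real eigenvalues equals
#' \code{(Q + 1) - 2 N(q)} with \code{N(q)} the number of exceptional points
#' below \code{q}.  An eigenvalue is deemed real when
#' \code{|Im(lambda)| <= tol * max(1, |lambda|)}.
#'
#' @param q activity parameter.
#' @param Q truncation cutoff (or a \code{"decay_operator"} via \code{op}).
#' @param op optional pre-built operator; overrides \code{q}, \code{Q}.
#' @param tol realness tolerance, default \code{1e-9}.
#' @param boundary passed to \code{\link{build_decay_operator}}.
#' @return integer count of real eigenvalues.
#' @export
count_real_eigenvalues <- function(q, Q, op = NULL, tol = 1e-9,
                                   boundary = "mathieu") {
  if (is.null(op)) {
    vals <- eigen(real_form(q, Q, boundary), only.values = TRUE)$values
  } else if (op$boundary == "two_mode") {
    vals <- eigen(rbind(c(0, -op$q / 2), c(op$q / 2, 1)),
                  only.values = TRUE)$values
  } else {
    vals <- eigen(real_form(op$q, op$Q, op$boundary),
                  only.values = TRUE)$values
  }
  sum(is_real_eigenvalue(as.complex(vals), tol))
}

is_real_eigenvalue <- function(lambda, tol = 1e-9) {
  abs(Im(lambda)) <= tol * pmax(1, abs(lambda))
}

# eigenvalues only, via the real form; used by sweeps and bisection
spectrum_values <- function(q, Q, boundary = "mathieu") {
  v <- as.complex(eigen(real_form(q, Q, boundary), only.values = TRUE)$values)
  v[order(Re(v), Im(v))]
}

#' Slowest relaxation mode and its Fourier projections
#'
#' Identifies the eigenvalue with minimal real part (the slowest decay; on a
#' tie the smaller \code{|Im|}, then the non-negative imaginary part, is
#' taken) and returns the magnitudes \code{c_n = |v_n|} of the components of
#' its unit-norm eigenvector on the angular harmonics \code{n = 0 ... Q}.
#' \code{c_1} is the polar ("density-order") projection that controls the
#' mean-field flocking instability for polar alignment; \code{c_2} the
#' nematic one.
#'
#' @param dec a \code{"spectral_decomposition"}.
#' @return list with \code{lambda0} (complex decay rate), \code{index}
#'   (position in \code{dec$values}) and \code{projections}, a data frame
#'   with columns \code{n} and \code{c_n} (\code{sum(c_n^2) = 1}).
#' @examples
#' sm <- slowest_mode(diagonalize(build_decay_operator(0, 50)))
#' sm$lambda0                      # 0
#' sm$projections$c_n[1]           # 1
#' @export
slowest_mode <- function(dec) {
  stopifnot(inherits(dec, "spectral_decomposition"))
  if (length(dec$values) == 0L) stop("empty decomposition", call. = FALSE)
  re <- Re(dec$values)
  cand <- which(re <= min(re) + 1e-12 * max(1, abs(min(re))))
  if (length(cand) > 1L) {
    cand <- cand[order(abs(Im(dec$values[cand])), -Im(dec$values[cand]))]
  }
  i0 <- cand[1L]
  v <- dec$vectors[, i0]
  list(lambda0 = dec$values[i0], index = i0,
       projections = data.frame(n = seq_along(v) - 1L, c_n = abs(v)))
}

#' Track spectral branches along an activity sweep
#'
#' Diagonalizes the operator on an increasing activity grid and connects
#' eigenvalues at consecutive grid points into continuous branches by
#' maximal eigenvector overlap \code{|v_prev^H v_new|} (greedy assignment in
#' decreasing overlap).  When the two best overlaps for a branch differ by
#' less than \code{1e-6} a warning is raised and the tie is broken
#' lexicographically (lower eigenvalue index wins), which keeps the
#' assignment deterministic.
#'
#' @param q_grid strictly increasing vector of activities, length >= 2.
#' @param Q truncation cutoff.
#' @param n_proj number of leading Fourier projections to report
#'   (capped at \code{min(Q, 8)}).
#' @param boundary passed to \code{\link{build_decay_operator}}.
#' @return data frame of class \code{"branch_table"} with columns \code{q},
#'   \code{branch} (0-based, ordered by real part at the first grid point),
#'   \code{re_lambda}, \code{im_lambda} and \code{c0 ... c<n_proj>}.
#' @export
track_branches <- function(q_grid, Q, n_proj = 8L, boundary = "mathieu") {
  if (length(q_grid) < 2L)
    stop("'q_grid' must contain at least 2 points", call. = FALSE)
  if (any(diff(q_grid) <= 0))
    stop("'q_grid' must be strictly increasing", call. = FALSE)
  n_proj <- min(n_proj, Q, 8L)
  decs <- lapply(q_grid, function(q)
    diagonalize(build_decay_operator(q, Q, boundary)))
  nb <- Q + 1L
  perm <- seq_len(nb)                 # branch id -> eigenvalue index
  rows <- vector("list", length(q_grid))
  prev_vectors <- decs[[1L]]$vectors
  for (g in seq_along(q_grid)) {
    dec <- decs[[g]]
    if (g > 1L) {
      ov <- abs(Conj(t(prev_vectors)) %*% dec$vectors)  # nb x nb overlaps
      new_perm <- integer(nb)
      taken <- rep(FALSE, nb)
      for (b in seq_len(nb)) {
        o <- ov[perm[b], ]
        o[taken] <- -Inf
        best <- max(o)
        j <- which(o >= best - 1e-6)
        if (length(j) > 1L)
          warning(sprintf(
            "ambiguous branch match at q = %g (overlap gap < 1e-6); %s",
            q_grid[g], "lexicographic tie-break applied"), call. = FALSE)
        new_perm[b] <- j[1L]
        taken[j[1L]] <- TRUE
      }
      perm <- new_perm
      prev_vectors <- dec$vectors
    }
    pr <- abs(dec$vectors[seq_len(n_proj + 1L), perm, drop = FALSE])
    rows[[g]] <- data.frame(
      q = q_grid[g], branch = seq_len(nb) - 1L,
      re_lambda = Re(dec$values[perm]), im_lambda = Im(dec$values[perm]),
      t(pr))
  }
  out <- do.call(rbind, rows)
  names(out)[-(1:4)] <- paste0("c", 0:n_proj)
  class(out) <- c("branch_table", "data.frame")
  out
}

#' Sweep the slowest mode over an activity grid
#'
#' Convenience wrapper: diagonalizes at each activity and collects the
#' slowest decay rate and its leading Fourier projections.  This is the
#' work-horse behind the scaling-exponent fits and the mean-field
#' thresholds.
#'
#' @inheritParams track_branches
#' @param q_grid vector of activities (any positive values).
#' @return data frame with columns \code{q}, \code{re_lambda0},
#'   \code{im_lambda0} and \code{c0 ... c<n_proj>}.
#' @export
sweep_spectrum <- function(q_grid, Q, n_proj = 8L, boundary = "mathieu") {
  n_proj <- min(n_proj, Q, 8L)
  rows <- lapply(q_grid, function(q) {
    sm <- slowest_mode(diagonalize(build_decay_operator(q, Q, boundary)))
    pr <- sm$projections$c_n[seq_len(n_proj + 1L)]
    cbind(data.frame(q = q, re_lambda0 = Re(sm$lambda0),
                     im_lambda0 = Im(sm$lambda0)),
          as.data.frame(as.list(stats::setNames(pr, paste0("c", 0:n_proj)))))
  })
  do.call(rbind, rows)
}
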