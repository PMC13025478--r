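#' Small-activity perturbation series for the decay rates
#'
#' Second-order perturbation theory around the purely diffusive spectrum
#' \code{lambda_r = r^2} gives, for the even-sector mode of index \code{r},
#' \deqn{\lambda_r(q) = r^2 - \frac{q^2}{8 (4 r^2 - 1)} + O(q^4),}
#' equivalently \code{a_{2r} = 4 r^2 - q^2 / (2 (4 r^2 - 1))} on the Mathieu
#' scale \code{a = 4 lambda}.  For the slowest mode (\code{r = 0}) this is
#' \code{lambda0 = q^2 / 8}, fixing the low-activity exponent
#' \code{alpha_low = 2}.
#'
#' @param r mode index, integer \code{>= 0}.
#' @param q activity parameter (vectorized).
#' @return real prediction(s) for \code{lambda_r(q)}.
#' @examples
#' lowq_characteristic(0, 0.1)   # 0.00125
#' @export
lowq_characteristic <- function(r, q) {
  stopifnot(r >= 0, r == round(r), all(q >= 0))
  r^2 - q^2 / (8 * (4 * r^2 - 1))
}

#' First-order eigenvector correction at small activity
#'
#' The first-order corrected eigenvector of mode \code{m} couples to the
#' neighbouring harmonics with purely imaginary amplitudes proportional to
#' \code{q}.  In the orthonormal angular basis (where the folded 0-1 bond
#' carries the \code{sqrt(2)} weight) the slowest mode acquires a polar
#' component \code{i q sqrt(2) / 4}, i.e. a projection magnitude
#' \code{|c_1| = q / (2 sqrt(2)) ~ 0.35355 q}: the low-activity exponent is
#' \code{beta_low = 1}, and the prefactor \code{1 / (2 sqrt(2))} agrees with
#' the Fourier expansion of the even Mathieu function of order zero (this
#' package's numerics confirm it; see the methods vignette for the
#' discussion of the discrepant printed value in the source literature).
#' The nematic component of the slowest mode is second order
#' (\code{c_2 ~ q^2}), which is what makes higher-symmetry interactions
#' scale differently at low activity.
#'
#' @param m mode index, integer \code{>= 0}.
#' @param q activity parameter; a warning is issued above 0.3 where the
#'   first-order expression degrades.
#' @param Q cutoff used to embed the correction vector (default
#'   \code{m + 2}).
#' @return list with \code{vector} (unnormalized first-order eigenvector in
#'   the orthonormal basis, complex), \code{polar_overlap} (the complex
#'   amplitude on harmonic 1 for \code{m = 0}, \code{i q sqrt(2)/4}) and
#'   \code{polar_magnitude}.
#' @export
lowq_mode_projection <- function(m, q, Q = max(m + 2L, 2L)) {
  stopifnot(m >= 0, m == round(m), q >= 0, Q >= m + 1)
  if (q > 0.3)
    warning("first-order perturbation theory degrades for q > 0.3",
            call. = FALSE)
  b <- bond_strengths(q, Q, "mathieu")
  v <- complex(real = rep(0, Q + 1))
  v[m + 1L] <- 1
  if (m + 1L <= Q)            # component on harmonic m + 1
    v[m + 2L] <- -1i * b[m + 1L] / (m^2 - (m + 1)^2)
  if (m >= 1L)                # component on harmonic m - 1
    v[m] <- -1i * b[m] / (m^2 - (m - 1)^2)
  list(vector = v,
       polar_overlap = if (m == 0L) v[2L] else v[2L],
       polar_magnitude = abs(v[2L]))
}

#' Advection (Toeplitz) limit of the truncated operator
#'
#' In the regime \code{q >> Q^2} the diffusive diagonal is a small
#' perturbation of the pure advection matrix.  For the uniform-bond
#' truncation the advection part is an imaginary tridiagonal Toeplitz
#' matrix with the closed-form spectrum
#' \deqn{\lambda_n^{(0)} = -\,i\,\frac{q}{2}\cos\frac{(n+1)\pi}{Q+2},
#'   \qquad v_{mn} \propto \sin\frac{(m+1)(n+1)\pi}{Q+2},}
#' \code{n = 0 ... Q}.  The leading real part is the first-order diffusive
#' correction, computed here as the contraction of the diagonal \code{m^2}
#' operator with the normalized sine eigenvector,
#' \code{Re lambda_n^{(1)} = sum_m m^2 sin^2(...) / sum_m sin^2(...)}.
#' The closed form is exact for \code{\link{advection_matrix}} and matches
#' full diagonalization of the \code{boundary = "uniform"} operator to
#' better than 1 percent once \code{q >= 10 Q^2}.
#'
#' @param Q truncation cutoff.
#' @param q activity parameter.
#' @return data frame with columns \code{n}, \code{re_lambda} (first-order
#'   diffusive correction), \code{im_lambda} (zeroth-order advection) and
#'   attribute \code{"vectors"}: the \code{(Q+1) x (Q+1)} matrix of
#'   normalized sine eigenvectors.
#' @export
toeplitz_limit <- function(Q, q) {
  stopifnot(Q >= 1, Q == round(Q), q >= 0)
  n <- 0:Q
  im <- -(q / 2) * cos((n + 1) * pi / (Q + 2))
  V <- outer(0:Q, n, function(m, nn) sin((m + 1) * (nn + 1) * pi / (Q + 2)))
  V <- sweep(V, 2L, sqrt(colSums(V^2)), "/")
  re <- colSums((0:Q)^2 * V^2)
  out <- data.frame(n = n, re_lambda = re, im_lambda = im)
  attr(out, "vectors") <- V
  out
}

#' Pure advection matrix of the uniform truncation
#'
#' The decay operator with its diffusive diagonal removed and uniform bonds
#' \code{-i q / 4}; its spectrum is exactly the zeroth order of
#' \code{\link{toeplitz_limit}}.
#'
#' @inheritParams toeplitz_limit
#' @return complex \code{(Q+1) x (Q+1)} matrix.
#' @export
advection_matrix <- function(Q, q) {
  A <- build_decay_operator(q, Q, boundary = "uniform")$matrix
  diag(A) <- 0
  A
}

#' Large-activity Mathieu asymptotics of the decay rates
#'
#' For \code{q >> 1} the characteristic value of the even Mathieu branch of
#' index \code{m} behaves, with \code{s = 2 m + 1}, as
#' \deqn{a_m(q) = 2 i q - (1 + i)\, s \sqrt{2 q} + \frac{s^2 + 1}{8}
#'   + O(q^{-1/2}),}
#' so on the decay scale \code{lambda = a / 4}:
#' \code{Re lambda_m = (s sqrt(2q) - (s^2+1)/8) / 4} and
#' \code{|Im lambda_m| = (2 q - s sqrt(2q)) / 4}, with signs fixed to the
#' decay convention \code{Re lambda >= 0} (conjugate partner implied).
#' This encodes the high-activity exponent \code{alpha_high = 1/2}.
#'
#' The index \code{m} is the Mathieu order.  The physically admissible
#' sector of the decay operator contains only the even orders, so the
#' r-th coalesced branch pair of \code{\link{diagonalize}} corresponds to
#' \code{m = 2 r}, i.e. \code{s = 4 r + 1}: consecutive pair plateaus sit
#' at real-part ratios 1 : 5 : 9 : ... at matched activity.
#'
#' @param m branch index (Mathieu order), integer \code{>= 0}; the decay
#'   operator's r-th pair is \code{m = 2 r}.
#' @param q activity (vectorized); a warning is issued below \code{q = 10}.
#' @return complex prediction(s) for \code{lambda_m(q)} (the member of the
#'   conjugate pair with positive imaginary part).
#' @examples
#' Re(highq_characteristic(0, 100))   # ~3.47
#' @export
highq_characteristic <- function(m, q) {
  stopifnot(m >= 0, m == round(m), all(q >= 0))
  if (any(q < 10))
    warning("large-q asymptotics requested below q = 10", call. = FALSE)
  s <- 2 * m + 1
  re <- (s * sqrt(2 * q) - (s^2 + 1) / 8) / 4
  im <- (2 * q - s * sqrt(2 * q)) / 4
  complex(real = re, imaginary = im)
}

#' Large-activity Fourier projections of the slowest mode
#'
#' In the boundary-layer regime \code{1 << q << Q^2} every Fourier
#' projection of the slowest eigenmode decays as \code{q^(-1/8)}; the
#' \code{l}-dependence enters only through a prefactor.  The absolute
#' prefactor printed in the asymptotic literature is typographically
#' ambiguous, so this function anchors the \code{q^(-1/8)} law numerically:
#' the prefactor for harmonic \code{l} is measured once from a full
#' diagonalization at a reference activity (\code{q_ref}, default 1000, at
#' cutoff \code{Q_ref = 400}) and the prediction is
#' \code{c_l(q) = c_l(q_ref) * (q / q_ref)^(-1/8)}.
#'
#' @param l Fourier harmonic index (vectorized), \code{0 <= l <= 8}.
#' @param q activity at which the projection is predicted.
#' @param q_ref,Q_ref reference point for the numeric prefactor
#'   calibration.
#' @return data frame with columns \code{l}, \code{prefactor} (measured
#'   \code{c_l(q_ref)}) and \code{c_l} (prediction at \code{q}).
#' @export
highq_fourier_coefficients <- function(l, q, q_ref = 1e3, Q_ref = 400L) {
  stopifnot(all(l >= 0), all(l == round(l)), all(l <= 8), q > 0)
  sm <- slowest_mode(diagonalize(build_decay_operator(q_ref, Q_ref)))
  pref <- sm$projections$c_n[l + 1L]
  data.frame(l = l, prefactor = pref, c_l = pref * (q / q_ref)^(-1 / 8))
}

#' Mathieu characteristic value of the slowest even branch
#'
#' Independent oracle for the package's eigensolver: computes the
#' characteristic value \code{a_0(q)} of the even pi-periodic Mathieu
#' function for the purely imaginary parameter regime relevant here
#' (equation \code{f'' + (a + 2 i q cos 2 psi) f = 0}) by the standard
#' continued-fraction form of the three-term Fourier recurrence,
#' \deqn{F(a) = a + \frac{2 q^2}{a - 4 - H_2(a)} = 0,\qquad
#'   H_r(a) = \frac{-q^2}{a - 4 r^2 - H_{r+1}(a)},}
#' truncated at depth \code{depth} and solved with a bracketing root
#' search.  Valid on the real branch, i.e. below the first double point
#' (\code{q < ~1.46877}); beyond it \code{a_0} ceases to be real and the
#' function stops.  \code{4 * lambda0} from
#' \code{\link{diagonalize}} converges to this value as \code{Q} grows.
#'
#' @param q activity parameter, \code{0 <= q < 1.46}.
#' @param depth truncation depth of the continued fraction (default 100).
#' @return the real characteristic value \code{a_0(q)}.
#' @examples
#' mathieu_a0(0.5)          # ~0.12863
#' @export
mathieu_a0 <- function(q, depth = 100L) {
  stopifnot(q >= 0)
  if (q >= 1.46)
    stop("a0(q) is real only below the first double point (q < ~1.46877)",
         call. = FALSE)
  if (q == 0) return(0)
  F <- function(a) {
    H <- 0
    for (r in depth:2) H <- -q^2 / (a - 4 * r^2 - H)
    a + 2 * q^2 / (a - 4 - H)
  }
  grid <- seq(-0.5, 3.5, by = 0.01)
  fv <- vapply(grid, F, 0)
  i <- which(fv[-length(fv)] < 0 & fv[-1L] >= 0)
  if (length(i) == 0L)
    stop("no bracketing interval found for the continued fraction root",
         call. = FALSE)
  stats::uniroot(F, grid[c(i[1L], i[1L] + 1L)], tol = 1e-14)$root
}
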