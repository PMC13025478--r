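test_that("small-activity series evaluates the closed form", {
  expect_equal(lowq_characteristic(0, 0.1), 0.00125)
  expect_equal(lowq_characteristic(1, 0.2), 1 - 0.04 / 24)
  # lambda0 ~ q^2 / 8: slope 2 on log-log axes
  q <- 10^seq(-3, -2, length.out = 10)
  fit <- fit_loglog_slope(q, lowq_characteristic(0, q))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
})

test_that("perturbative lambda0 has an O(q^4) residual against numerics", {
  qs <- c(0.01, 0.02, 0.04)
  resid <- vapply(qs, function(q) {
    lam <- Re(slowest_mode(diagonalize(build_decay_operator(q, 50)))$lambda0)
    abs(lam - q^2 / 8)
  }, 0)
  ratios <- resid[-1] / resid[-3]
  expect_true(all(ratios > 12 & ratios < 20))    # ~16x per doubling of q
})

test_that("first-order polar projection is q/(2 sqrt(2)) and linear in q", {
  pr <- lowq_mode_projection(0, 0.01)
  expect_equal(pr$polar_magnitude, 0.01 / (2 * sqrt(2)), tolerance = 1e-12)
  expect_equal(Re(pr$polar_overlap), 0, tolerance = 1e-15)
  # against full diagonalization: prefactor and slope
  qs <- 10^seq(-3, -2, length.out = 10)
  c1 <- vapply(qs, function(q)
    slowest_mode(diagonalize(build_decay_operator(q, 50)))$projections$c_n[2], 0)
  expect_close(c1 / qs, rep(1 / (2 * sqrt(2)), 10), 1e-4)
  expect_equal(fit_loglog_slope(qs, c1)$slope, 1, tolerance = 1e-4)
  expect_warning(lowq_mode_projection(0, 0.5), "degrades")
})

test_that("nematic projection of the slowest mode is second order in q", {
  qs <- 10^seq(-3, -2, length.out = 10)
  c2 <- vapply(qs, function(q)
    slowest_mode(diagonalize(build_decay_operator(q, 50)))$projections$c_n[3], 0)
  expect_equal(fit_loglog_slope(qs, c2)$slope, 2, tolerance = 0.01)
})

test_that("Toeplitz closed form is exact on the advection-only matrix", {
  for (Q in c(1, 4, 9)) {
    q <- 7
    tl <- toeplitz_limit(Q, q)
    ev <- eigen(advection_matrix(Q, q), only.values = TRUE)$values
    expect_close(sort(Im(ev)), sort(tl$im_lambda), 1e-9 * max(1, q))
    expect_close(Re(ev), rep(0, Q + 1), 1e-9 * max(1, q))
  }
  # Q = 1: advection eigenvalues -/+ i q cos(pi/3) / ... = -/+ i q / 4
  tl1 <- toeplitz_limit(1, 8)
  expect_close(sort(tl1$im_lambda), c(-2, 2), 1e-12)
  # equal-weight sine vectors give <m^2> = 1/2 for both modes
  expect_equal(tl1$re_lambda, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("Toeplitz limit predicts the uniform truncation deep in advection", {
  Q <- 6; q <- 1e4
  tl <- toeplitz_limit(Q, q)
  ev <- diagonalize(build_decay_operator(q, Q, boundary = "uniform"))$values
  o1 <- order(tl$im_lambda); o2 <- order(Im(ev))
  expect_lt(max(abs(tl$re_lambda[o1] - Re(ev)[o2]) / Re(ev)[o2]), 0.01)
  expect_lt(max(abs(tl$im_lambda[o1] - Im(ev)[o2])) / q, 1e-4)
})

test_that("large-activity characteristic matches numerics within 2 percent", {
  # |Re a_m| = s sqrt(2q) - (s^2+1)/8 with s = 2m + 1 and m the Mathieu
  # order; the operator's r-th pair is the even order m = 2r (s = 4r + 1)
  expect_warning(highq_characteristic(0, 5), "below q = 10")
  for (r in 0:2) {
    s <- 4 * r + 1
    q <- 100 * s^2
    pred <- highq_characteristic(2 * r, q)
    vals <- diagonalize(build_decay_operator(q, 400))$values
    lam <- vals[which.min(abs(Re(vals) - Re(pred)))]   # nearest-branch match
    expect_lt(abs(Re(pred) - Re(lam)) / Re(lam), 0.02)
    expect_lt(abs(abs(Im(pred)) - abs(Im(lam))) / abs(Im(lam)), 0.02)
  }
})

test_that("high-activity exponent 1/2 and even-sector pair ratios emerge", {
  qs <- 10^seq(3, 4, length.out = 8)
  rea <- vapply(qs, function(q) abs(Re(4 * highq_characteristic(0, q))), 0)
  fit <- fit_loglog_slope(qs, rea)
  expect_equal(fit$slope, 0.5, tolerance = 0.02)
  # formula: consecutive Mathieu orders have leading-term ratio 3 (s = 3 : 1)
  expect_equal(Re(highq_characteristic(1, 1e8)) /
                 Re(highq_characteristic(0, 1e8)), 3, tolerance = 1e-3)
  # spectrum: only even orders are admissible, so adjacent operator pairs
  # sit at s = 5 vs s = 1, real-part ratio -> 5
  re <- sort(Re(diagonalize(build_decay_operator(2000, 400))$values))
  expect_equal(re[3] / re[1], 5, tolerance = 0.02)
})

test_that("slowest-mode Fourier projections obey the q^(-1/8) law", {
  # scale ratio over a factor 16 in q
  p <- highq_fourier_coefficients(0, 16 * 1e3)
  p0 <- highq_fourier_coefficients(0, 1e3)
  expect_equal(p$c_l / p0$c_l, 16^(-1 / 8), tolerance = 1e-12)
  # measured: c0 and c1 slopes at -1/8; higher harmonics converge later
  qs <- 10^seq(3, 4, length.out = 8)
  pr <- vapply(qs, function(q)
    slowest_mode(diagonalize(build_decay_operator(q, 400)))$projections$c_n[1:5],
    numeric(5))
  slopes <- vapply(1:5, function(i) fit_loglog_slope(qs, pr[i, ])$slope, 0)
  expect_equal(slopes[1], -0.125, tolerance = 0.02 / 0.125)
  expect_equal(slopes[2], -0.125, tolerance = 0.02 / 0.125)
  expect_true(all(slopes < 0))
  # measured ratio c0(16 q) / c0(q) close to 16^(-1/8)
  r <- pr[1, 8] / pr[1, 1]   # q = 1e4 vs 1e3, factor 10
  expect_equal(r, 10^(-1 / 8), tolerance = 0.03)
})

test_that("Mathieu branch roots and double points agree with diagonalization", {
  rt <- mathieu_branch_roots(0.5, 1e-6, 10)
  expect_equal(rt[1], 0.1286301, tolerance = 1e-6)
  vals <- diagonalize(build_decay_operator(0.5, 60))$values
  expect_close(rt[1:2], 4 * Re(vals[1:2]), 1e-7)
  dp <- mathieu_double_point(1)
  expect_equal(dp$q_star, 16.4712, tolerance = 1e-4)
  expect_error(mathieu_double_point(25), "not certifiable")
})
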