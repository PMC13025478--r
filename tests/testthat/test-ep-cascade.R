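test_that("two-mode exceptional point sits at q = 1 with lambda = 1/2", {
  ep <- two_mode_ep(tol = 1e-10)
  expect_equal(ep$q_star, 1, tolerance = 1e-9)
  expect_equal(Re(ep$lambda_star), 0.5, tolerance = 1e-9)
  expect_lt(abs(Im(ep$lambda_star)), 1e-6)
})

test_that("first operator exceptional point converges quickly in Q", {
  q6 <- locate_ep(0, Q = 6, bracket = c(1, 2), tol = 1e-8)$q_star
  q60 <- locate_ep(0, Q = 60, bracket = c(1, 2), tol = 1e-8)$q_star
  q200 <- locate_ep(0, Q = 200, bracket = c(1, 2), tol = 1e-8)$q_star
  expect_lt(abs(q6 - q200), 1e-4)
  expect_lte(abs(q60 - q200), abs(q6 - q200))
  expect_equal(q200, 1.4687686, tolerance = 1e-6)
})

test_that("bad brackets raise bracketing errors with diagnostic counts", {
  expect_error(locate_ep(0, Q = 20, bracket = c(0.1, 0.5)),
               "does not straddle")
  expect_error(locate_ep(0, Q = 60, bracket = c(1, 20)),
               "more than one transition")
})

test_that("cascade scan finds exactly the expected low-activity points", {
  expect_equal(nrow(scan_cascade(50, q_max = 1.4, tol = 1e-5)), 0L)
  eps <- scan_cascade(50, q_max = 2, tol = 1e-5)
  expect_equal(nrow(eps), 1L)
  expect_equal(eps$r, 0L)
  expect_equal(eps$q_star, 1.46877, tolerance = 1e-4)
  eps2 <- scan_cascade(50, q_max = 60, tol = 1e-5)
  expect_equal(eps2$r, c(0L, 1L, 2L))
  expect_true(all(diff(eps2$q_star) > 0))
})

test_that("real-eigenvalue count drops by two per exceptional point", {
  eps <- scan_cascade(40, q_max = 60, tol = 1e-5)
  qs <- c(1, 10, 30, 55)                 # between consecutive q_star
  for (q in qs) {
    n_ep <- sum(eps$q_star < q)
    expect_equal(count_real_eigenvalues(q, 40), 41L - 2L * n_ep)
  }
})

test_that("post-EP pair has equal real parts and conjugate imaginaries", {
  for (dq in c(0.01, 0.1)) {
    vals <- diagonalize(build_decay_operator(1.4687686 + dq, 80))$values
    pair <- vals[order(Re(vals))][1:2]
    expect_lt(abs(Re(pair[1]) - Re(pair[2])), 1e-9)
    expect_lt(abs(Im(pair[1]) + Im(pair[2])), 1e-9)
    expect_gt(abs(Im(pair[1])), 1e-4)
  }
})

test_that("pre-EP gap closes as the square root of the distance", {
  qc <- locate_ep(0, Q = 80, bracket = c(1, 2), tol = 1e-9)$q_star
  d <- 10^seq(-3, -1, length.out = 10)
  gaps <- vapply(qc - d, function(q) {
    re <- sort(Re(diagonalize(build_decay_operator(q, 80))$values))
    re[2] - re[1]
  }, 0)
  fit <- fit_loglog_slope(d, gaps)
  expect_equal(fit$slope, 0.5, tolerance = 0.05)
})

test_that("EP count exponent recovers constructed and degenerate inputs", {
  # constructed cascade q_r = r^2  =>  N(q) = sqrt(q), count slope 1/2
  eps <- data.frame(q_star = (1:20)^2)
  fit <- ep_count_exponent(eps, window = c(1, 400))
  expect_equal(fit$slope, 0.5 - 1, tolerance = 1e-10)
  expect_equal(fit$quantity, "ep_density")
  expect_error(ep_count_exponent(data.frame(q_star = c(1, 4)), c(0.5, 5)),
               ">= 5")
})

test_that("continued-fraction cross-check truncates uncertified detections", {
  expect_warning(
    eps <- scan_cascade(200, q_max = 2000, tol = 1e-4, validate = "mathieu"),
    "reliability frontier")
  expect_gte(nrow(eps), 10L)
  expect_true(all(diff(eps$q_star) > 0))
  expect_equal(eps$r, seq_len(nrow(eps)) - 1L)
  # certified locations match the continuum double points closely
  for (i in c(2L, 6L)) {
    dp <- mathieu_double_point(eps$r[i])
    expect_equal(eps$q_star[i], dp$q_star, tolerance = 1e-4)
  }
})
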