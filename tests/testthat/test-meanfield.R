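test_that("critical coupling vanishes with the marginal mode at q = 0", {
  expect_equal(critical_coupling(0, 30, 1)$gamma_c, 0)
  expect_equal(critical_coupling(0, 30, 2, method = "exact")$gamma_c, 0)
})

test_that("ratio threshold is Re(lambda0) / c_n", {
  q <- 0.5; Q <- 30
  sm <- slowest_mode(diagonalize(build_decay_operator(q, Q)))
  for (n in 1:2) {
    th <- critical_coupling(q, Q, n)
    expect_equal(th$gamma_c,
                 Re(sm$lambda0) / sm$projections$c_n[n + 1L],
                 tolerance = 1e-12)
  }
})

test_that("exact threshold destabilizes the rank-one perturbed operator", {
  q <- 2; Q <- 30; n <- 1
  th <- critical_coupling(q, Q, n, method = "exact")
  min_re <- function(gam) {
    A <- build_decay_operator(q, Q)$matrix
    A[n + 1, n + 1] <- A[n + 1, n + 1] - gam
    min(Re(eigen(A, only.values = TRUE)$values))
  }
  expect_gt(min_re(th$gamma_c * 0.99), 0)    # still stable just below
  expect_lt(min_re(th$gamma_c * 1.01), 0)    # unstable just above
})

test_that("ratio and exact thresholds agree up to a modest factor at high q", {
  grid <- 10^seq(log10(400), log10(625), length.out = 4)
  gr <- vapply(grid, function(q)
    critical_coupling(q, 400, 1)$gamma_c, 0)
  ge <- vapply(grid, function(q)
    critical_coupling(q, 400, 1, method = "exact")$gamma_c, 0)
  expect_true(all(ge / gr > 1 & ge / gr < 2.5))
  sr <- fit_loglog_slope(grid, gr)$slope
  se <- fit_loglog_slope(grid, ge)$slope
  expect_lt(abs(sr - se), 0.2)
})

test_that("structural zeros are reported for unexcitable symmetries", {
  expect_error(critical_coupling(1e-9, 30, 8), "structural zero")
})

test_that("low-activity gamma exponents separate polar from nematic", {
  g1 <- gamma_exponent(50, 1, window = c(1e-3, 1e-2))
  expect_equal(g1$slope, 1, tolerance = 0.05)
  g2 <- gamma_exponent(50, 2, window = c(1e-3, 1e-2))
  expect_equal(g2$slope, 0, tolerance = 0.05)
})

test_that("diffusive shift is a uniform additive k^2 term", {
  expect_equal(diffusive_shift(0.1, 0, 1), 0.1)
  expect_equal(diffusive_shift(0, 0.5, 0.2), 0.02)
  expect_equal(diffusive_shift(1 + 2i, 0.3, 2), 1 + 0.3 * 4 + 2i)
})

test_that("exponent report reproduces the two-regime structure", {
  tab <- table1_report(Q_low = 50L, Q_high = 120L,
                       low_window = c(1e-3, 1e-2),
                       high_window = c(60, 500),
                       points_per_decade = 10L)
  expect_equal(nrow(tab), 4L)
  low <- tab[tab$regime == "low", ]
  expect_equal(low$alpha, c(2, 2), tolerance = 0.03)
  expect_equal(low$beta[low$n == 1], 1, tolerance = 0.03)
  expect_equal(low$beta[low$n == 2], 2, tolerance = 0.05)
  expect_equal(low$gamma[low$n == 1], 1, tolerance = 0.05)
  expect_equal(low$gamma[low$n == 2], 0, tolerance = 0.05)
  # gamma = alpha - beta by construction of the ratio method
  expect_equal(tab$gamma, tab$alpha - tab$beta, tolerance = 1e-10)
})
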