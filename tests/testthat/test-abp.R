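test_that("parameter validation enforces the angular-step cap", {
  expect_error(abp_params(1, 10, dt = 0.1, t_total = 1, seed = 1),
               "dt > 0.05")
  expect_s3_class(abp_params(1, 10, dt = 0.05, t_total = 1, seed = 1),
                  "abp_params")
})

test_that("simulation is bit-reproducible and particle-count stable", {
  p <- abp_params(1, 20, dt = 0.01, t_total = 2, seed = 11)
  tr1 <- simulate_abp(p)
  tr2 <- simulate_abp(p)
  expect_identical(tr1$x, tr2$x)
  expect_identical(tr1$phi, tr2$phi)
  # adding particles leaves existing streams untouched
  p2 <- abp_params(1, 30, dt = 0.01, t_total = 2, seed = 11)
  tr3 <- simulate_abp(p2)
  expect_identical(tr3$x[, 1:20], tr1$x)
})

test_that("passive limit keeps positions fixed while angles diffuse", {
  p <- abp_params(0, 400, dt = 0.02, t_total = 8, seed = 3, save_every = 50L)
  tr <- simulate_abp(p)
  expect_true(all(tr$x == 0) && all(tr$y == 0))
  # MSD(phi) = 2 t
  msd <- rowMeans(tr$phi^2)
  expect_equal(msd[-1] / (2 * tr$times[-1]), rep(1, length(msd) - 1),
               tolerance = 0.15)
})

test_that("per-step speed equals Pe dt and increments are N(0, 2 dt)", {
  p <- abp_params(2, 50, dt = 0.02, t_total = 2, seed = 5, save_every = 1L)
  tr <- simulate_abp(p)
  sp <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  expect_equal(max(abs(sp - 2 * 0.02)), 0, tolerance = 1e-12)
  dphi <- diff(tr$phi)
  expect_equal(mean(dphi), 0, tolerance = 3 * sqrt(2 * 0.02 / length(dphi)))
  # variance 2 dt, and normality of increments
  expect_equal(stats::var(as.vector(dphi)), 2 * 0.02, tolerance = 0.06)
  expect_gt(stats::shapiro.test(as.vector(dphi)[1:3000])$p.value, 0.01)
})

test_that("positional spreading approaches 4 D_eff t with D_eff = Pe^2/2", {
  p <- abp_params(1, 3000, dt = 0.02, t_total = 60, seed = 9)
  tr <- simulate_abp(p)
  late <- tr$times > 30
  msd <- rowMeans(tr$x^2 + tr$y^2)[late]
  # MSD = 4 D_eff t - const; compare the late-time slope
  slope <- stats::coef(stats::lm(msd ~ tr$times[late]))[2]
  expect_equal(unname(slope), 4 * 0.5, tolerance = 0.15)
})

test_that("conserved density gives zero decay at k = 0", {
  p <- abp_params(1, 10, dt = 0.02, t_total = 2, seed = 2)
  est <- estimate_mode_decay(simulate_abp(p), k = 0)
  expect_equal(est$rate, 0)
})

test_that("measured mode decay matches the spectral rate at q = 1", {
  lam <- Re(slowest_mode(diagonalize(build_decay_operator(1, 50)))$lambda0)
  p <- abp_params(1, 2500, dt = 0.02, t_total = 40 / lam, seed = 21)
  tr <- simulate_abp(p)
  est <- estimate_mode_decay(tr, k = 0.5, n_boot = 300, boot_seed = 21)
  expect_lt(abs(est$rate - lam) / est$se, 3)
  expect_error(estimate_mode_decay(tr, k = 0.5, lambda_hat = 1e-3),
               "too short")
})
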