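test_that("operator matrix has the folded tridiagonal structure", {
  op <- build_decay_operator(q = 0.5, Q = 4)
  A <- op$matrix
  expect_equal(dim(A), c(5L, 5L))
  expect_equal(Re(diag(A)), (0:4)^2)
  expect_equal(A[1, 2], -1i * 0.5 * sqrt(2) / 4)
  expect_equal(A[2, 3], -1i * 0.5 / 4)
  expect_identical(A, t(A))                 # complex symmetric, not Hermitian
  expect_equal(A[1, 3], 0 + 0i)             # tridiagonal
  expect_equal(op$trace, 4 * 5 * 9 / 6)
  expect_equal(sum(diag(A)), op$trace + 0i)
})

test_that("invalid operator parameters are rejected", {
  expect_error(build_decay_operator(-1, 5), "non-negative")
  expect_error(build_decay_operator(1, 0), "integer >= 1")
  expect_error(build_decay_operator(1, 2.5), "integer >= 1")
})

test_that("zero activity gives the pure Fourier relaxation spectrum", {
  dec <- diagonalize(build_decay_operator(0, 4))
  expect_equal(dec$values, (0:4)^2 + 0i)
  expect_equal(abs(dec$vectors), diag(5), tolerance = 1e-12)
  sm <- slowest_mode(dec)
  expect_equal(sm$lambda0, 0 + 0i)
  expect_equal(sm$projections$c_n, c(1, 0, 0, 0, 0), tolerance = 1e-12)
})

test_that("two-mode model reproduces its closed-form eigenvalues", {
  for (q in c(0.5, 0.9, 2)) {
    dec <- diagonalize(two_mode_model(q))
    expect_close(dec$values, two_mode_closed_form(q), 1e-12)
  }
  # numeric values below and above the coalescence
  d1 <- diagonalize(two_mode_model(0.5))
  expect_close(Re(d1$values), c(0.0669873, 0.9330127), 1e-7)
  d2 <- diagonalize(two_mode_model(2))
  expect_equal(Re(d2$values), c(0.5, 0.5), tolerance = 1e-12)
  expect_close(sort(Im(d2$values)), c(-0.8660254, 0.8660254), 1e-7)
})

test_that("eigenpairs satisfy residual, conjugation and trace contracts", {
  set.seed(42)
  for (i in 1:50) {
    q <- stats::runif(1, 0, 50)
    Q <- sample(3:40, 1)
    op <- build_decay_operator(q, Q)
    dec <- diagonalize(op)
    nrmA <- max(abs(op$matrix))
    expect_lt(max(dec$residuals), 1e-9 * max(1, nrmA))
    # spectrum closed under conjugation as a multiset
    expect_close(sort(Re(dec$values)), sort(Re(Conj(dec$values))), 1e-9)
    expect_close(sort(Im(dec$values)), sort(Im(Conj(dec$values))), 1e-9)
    # trace conservation, relative 1e-9
    expect_lt(abs(sum(dec$values) - op$trace), 1e-9 * op$trace)
    # unit norm eigenvectors with real-positive dominant component
    nrm <- sqrt(colSums(abs(dec$vectors)^2))
    expect_close(nrm, rep(1, Q + 1), 1e-10)
    j <- apply(abs(dec$vectors), 2, which.max)
    dom <- dec$vectors[cbind(j, seq_len(Q + 1))]
    expect_true(all(abs(Im(dom)) < 1e-10) && all(Re(dom) > 0))
  }
})

test_that("real-form diagonalization agrees with the direct complex solver", {
  for (q in c(0.3, 1.2, 5, 20)) {
    dec <- diagonalize(build_decay_operator(q, 12))
    expect_close(dec$values, oracle_eigenvalues(q, 12), 1e-9)
  }
})

test_that("continued-fraction Mathieu characteristic matches 4*lambda0", {
  for (q in c(0.5, 1, 1.4)) {
    lam0 <- Re(slowest_mode(diagonalize(build_decay_operator(q, 60)))$lambda0)
    expect_lt(abs(mathieu_a0(q) - 4 * lam0), 1e-8)
  }
})

test_that("truncation error of the slowest mode decays monotonically", {
  for (q in c(1, 5, 10)) {
    lam <- vapply(c(20, 40, 80), function(Q)
      Re(slowest_mode(diagonalize(build_decay_operator(q, Q)))$lambda0), 0)
    err <- abs(diff(lam))
    expect_lt(err[2], max(1.5 * err[1], 1e-13))
  }
})

test_that("slowest-mode projections are a unit vector", {
  sm <- slowest_mode(diagonalize(build_decay_operator(3, 30)))
  expect_equal(sum(sm$projections$c_n^2), 1, tolerance = 1e-10)
  expect_true(all(sm$projections$c_n >= 0))
})

test_that("slowest-mode tie-break past the exceptional point picks +Im", {
  dec <- diagonalize(build_decay_operator(2, 30))   # lowest pair is complex
  sm <- slowest_mode(dec)
  expect_gt(abs(Im(sm$lambda0)), 1e-6)
  expect_gte(Im(sm$lambda0), 0)
})

test_that("branch tracking keeps real branches below the first EP", {
  br <- track_branches(c(0.1, 0.2), Q = 3)
  expect_equal(length(unique(br$branch)), 4L)
  expect_true(all(abs(br$im_lambda) < 1e-9))
  expect_error(track_branches(c(0.5), Q = 3), "at least 2")
  expect_error(track_branches(c(0.2, 0.1), Q = 3), "increasing")
})

test_that("branches acquire identical real parts beyond the first EP", {
  br <- suppressWarnings(track_branches(seq(1.3, 1.7, by = 0.05), Q = 40))
  post <- br[br$q > 1.47 & br$branch %in% c(0, 1), ]
  re0 <- post$re_lambda[post$branch == 0]
  re1 <- post$re_lambda[post$branch == 1]
  expect_close(re0, re1, 1e-9)
  im0 <- post$im_lambda[post$branch == 0]
  im1 <- post$im_lambda[post$branch == 1]
  expect_close(im0, -im1, 1e-9)
})

test_that("activity map enforces q = 2 k Pe and a = 4 lambda", {
  am <- activity_map(k = 0.5, Pe = 1, lambda = 0.25)
  expect_equal(am$q, 1)
  expect_equal(am$a, 1)
  expect_error(activity_map(q = 2, k = 0.5, Pe = 1), "inconsistent")
  expect_error(activity_map(), "supply")
})
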