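test_that("iPA entries follow the cosine of the phase difference", {
  m <- ipa_matrix(c(0, 0, pi, pi / 2))
  expect_equal(m[1, 2], 1)
  expect_equal(m[1, 3], -1)
  expect_equal(m[1, 4], 0, tolerance = 1e-12)
  expect_identical(m, t(m))
  expect_equal(diag(m), rep(1, 4))
  # PSD: c c' + s s' has no negative eigenvalue
  expect_gt(min(eigen(m, symmetric = TRUE)$values), -1e-12)
  expect_error(ipa_matrix(c(0, NA)), "non-finite")
})

test_that("closed-form eigenpairs match the dense eigensolver on random frames", {
  set.seed(101)
  for (n in c(2, 3, 10, 44, 200)) {
    for (rep in 1:10) {
      th <- random_phase_frame(n)
      d <- ipa_decompose(th)
      m <- ipa_matrix(th)
      e <- ipa_eigen_oracle(m)
      expect_lt(abs(d$lambda1 - e$values[1]), 1e-9 * n)
      expect_lt(abs(d$lambda2 - e$values[2]), 1e-9 * n)
      expect_lt(abs(d$lambda1 + d$lambda2 - n), 1e-9 * n)
      expect_true(d$lambda1 >= n / 2 - 1e-9 && d$lambda1 <= n + 1e-9)
      # all remaining oracle eigenvalues vanish: the matrix is rank <= 2
      if (n > 2) expect_lt(max(abs(e$values[-(1:2)])), 1e-8 * n)
      # eigenvector quality: unit norm, orthogonal, same 2-dim eigenspace
      expect_equal(sum(d$v1^2), 1, tolerance = 1e-9)
      expect_equal(sum(d$v2^2), 1, tolerance = 1e-9)
      expect_lt(abs(sum(d$v1 * d$v2)), 1e-8)
      expect_lt(max_principal_angle(cbind(d$v1, d$v2), e$vectors[, 1:2]),
                1e-6)
      # lossless: the two weighted eigenvectors rebuild the matrix
      expect_lt(max(abs(ipa_rebuild(d$lambda1, d$lambda2, d$v1, d$v2) - m)),
                1e-9)
    }
  }
})

test_that("degenerate configurations are resolved and flagged, never fail", {
  # rank 1: all phases in phase/antiphase -> lambda1 = N, lambda2 = 0, v2 = 0
  d <- ipa_decompose(gen_limit_case("all_in_phase", 44, theta0 = 0.7))
  expect_equal(d$lambda1, 44, tolerance = 1e-9)
  expect_equal(d$lambda2, 0)
  expect_true(d$degenerate)
  expect_equal(d$v2, numeric(44))
  expect_equal(d$v1, rep(1 / sqrt(44), 44), tolerance = 1e-12)

  d <- ipa_decompose(gen_limit_case("phase_antiphase", 10))
  expect_equal(d$lambda1, 10, tolerance = 1e-9)
  expect_equal(d$lambda2, 0)

  # all phases at +/- pi/2: the cosine vector collapses instead
  d <- ipa_decompose(c(rep(pi / 2, 3), rep(-pi / 2, 3)))
  expect_equal(d$lambda1, 6, tolerance = 1e-9)
  expect_true(d$degenerate)

  # doubly degenerate: lambda1 = lambda2 = N/2, orthonormal basis returned
  d <- ipa_decompose(gen_limit_case("quadrature_blocks", 44))
  expect_equal(d$lambda1, 22, tolerance = 1e-9)
  expect_equal(d$lambda2, 22, tolerance = 1e-9)
  expect_true(d$degenerate)
  expect_equal(sum(d$v1 * d$v2), 0, tolerance = 1e-9)

  # orthogonal c and s with distinct norms: c and s are the eigenpairs,
  # uniquely -> not flagged
  th <- c(0, 0, pi / 2)   # gamma = 2, sigma = 1, xi = 0
  d <- ipa_decompose(th)
  expect_false(d$degenerate)
  expect_equal(d$lambda1, 2)
  expect_equal(d$lambda2, 1)
  expect_equal(abs(d$v1), c(1, 1, 0) / sqrt(2))
  expect_equal(abs(d$v2), c(0, 0, 1))
})

test_that("the stable quadratic root survives near-cancellation regimes", {
  # tiny xi of either sign, sigma near gamma: stress both branches of B1
  for (eps in c(1e-7, -1e-7, 1e-10, -1e-10)) {
    th <- c(rep(0, 5), rep(pi / 2, 5)) + eps * (1:10)
    d <- ipa_decompose(th)
    m <- ipa_matrix(th)
    expect_lt(max(abs(ipa_rebuild(d$lambda1, d$lambda2, d$v1, d$v2) - m)),
              1e-9)
    expect_equal(d$lambda1 + d$lambda2, 10, tolerance = 1e-9)
  }
})

test_that("series decomposition is framewise, canonical and length-preserving", {
  # constant-in-time phases: every per-frame quantity is constant
  th <- random_phase_frame(8, seed = 3)
  ps <- phase_series(matrix(th, 8, 5), tr = 2)
  dec <- ipa_decompose_series(ps)
  expect_equal(length(dec$lambda1), 5)
  expect_true(all(dec$lambda1 == dec$lambda1[1]))
  expect_true(all(dec$v1 == dec$v1[, 1]))
  # T = 1 boundary
  d1 <- ipa_decompose_series(phase_series(matrix(th, 8, 1), tr = 2))
  expect_equal(length(d1$lambda1), 1)
  # canonical sign: the largest-magnitude component is positive
  dec <- ipa_decompose_series(random_phase_series(12, 30, seed = 9))
  for (t in 1:30) {
    expect_gt(dec$v1[which.max(abs(dec$v1[, t])), t], 0)
    expect_gt(dec$v2[which.max(abs(dec$v2[, t])), t], 0)
  }
})

test_that("rebuild is exact, sign-invariant and rank-1 when lambda2 = 0", {
  set.seed(77)
  for (rep in 1:100) {
    th <- random_phase_frame(9)
    d <- ipa_decompose(th)
    m <- ipa_matrix(th)
    expect_lt(max(abs(ipa_rebuild(d$lambda1, d$lambda2, d$v1, d$v2) - m)),
              1e-9)
    expect_equal(ipa_rebuild(d$lambda1, d$lambda2, -d$v1, d$v2),
                 ipa_rebuild(d$lambda1, d$lambda2, d$v1, -d$v2))
  }
  v <- c(3, 4) / 5
  expect_equal(qr(ipa_rebuild(2, 0, v, c(0, 0)))$rank, 1)
  expect_error(ipa_rebuild(1, 1, 1:3, 1:4), "mismatch")
})

test_that("the dense oracle validates symmetry and orders eigenvalues", {
  expect_equal(ipa_eigen_oracle(diag(5))$values, rep(1, 5))
  expect_error(ipa_eigen_oracle(matrix(1:4, 2)), "not symmetric")
  e <- ipa_eigen_oracle(ipa_matrix(random_phase_frame(20, seed = 2)))
  expect_true(all(diff(e$values) <= 0))
})

test_that("upper-triangle vectorisation is row-major and invertible", {
  m <- matrix(c(1, 9, 8, 9, 1, 7, 8, 7, 1), 3)
  expect_equal(upper_triangle(m), c(9, 8, 7))
  expect_equal(length(upper_triangle(diag(44))), 946)
  m <- ipa_matrix(random_phase_frame(13, seed = 4))
  expect_equal(ut_to_matrix(upper_triangle(m), diag_value = 1), m)
  expect_error(upper_triangle(matrix(1:6, 2)), "square")
  expect_error(ut_to_matrix(1:4), "N\\(N-1\\)/2")
})
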