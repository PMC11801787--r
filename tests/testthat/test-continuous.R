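test_that("reconfiguration speed matches brute-force Pearson on built matrices", {
  ps <- random_phase_series(8, 30, seed = 81)
  dec <- ipa_decompose_series(ps)
  sp <- reconfiguration_speed(dec)
  expect_length(sp, 29)
  expect_true(all(sp >= 0 & sp <= 1))
  manual <- vapply(2:30, function(t) {
    a <- upper_triangle(ipa_matrix(ps$theta[, t]))
    b <- upper_triangle(ipa_matrix(ps$theta[, t - 1]))
    1 - abs(cor(a, b))
  }, numeric(1))
  expect_equal(sp, manual, tolerance = 1e-9)
  # frozen dynamics: zero speed everywhere, zero spectral metastability
  frozen <- ipa_decompose_series(
    phase_series(matrix(ps$theta[, 1], 8, 10), 1))
  expect_equal(reconfiguration_speed(frozen), rep(0, 9), tolerance = 1e-9)
  expect_equal(spectral_metastability(frozen), 0)
})

test_that("eigenvector speed is flip-invariant and matches direct correlation", {
  ps <- random_phase_series(10, 25, seed = 82)
  dec <- ipa_decompose_series(ps)
  for (w in 1:2) {
    sp <- eigvec_speed(dec, w)
    v <- if (w == 1) dec$v1 else dec$v2
    manual <- vapply(2:25, function(t) 1 - abs(cor(v[, t], v[, t - 1])),
                     numeric(1))
    expect_equal(sp, manual, tolerance = 1e-12)
    expect_true(all(sp >= 0 & sp <= 1))
  }
  # flipping stored signs changes nothing (|R| is sign-blind)
  flipped <- dec
  flipped$v1 <- -flipped$v1
  expect_equal(eigvec_speed(flipped, 1), eigvec_speed(dec, 1))
  # constant eigenvector series moves nowhere
  frozen <- ipa_decompose_series(
    phase_series(matrix(ps$theta[, 3], 10, 8), 1))
  expect_equal(eigvec_speed(frozen, 1), rep(0, 7), tolerance = 1e-9)
})

test_that("KSD trajectories pair the right eigenvalue with the right speed", {
  tpl <- mode_templates(12)
  sim <- gen_planted_modes(tpl[c("in_phase", "quadrature")], 250, tr = 1,
                           dwell_mean = 8, jitter_kappa = 200, seed = 83)
  dec <- ipa_decompose_series(sim$phases)
  k <- ksd(dec, "full_matrix")
  expect_named(as.data.frame(k), c("frame", "position", "speed"))
  expect_equal(k$position, dec$lambda1[-1])
  expect_equal(k$speed, reconfiguration_speed(dec))
  expect_equal(ksd(dec, "eigvec2")$position, dec$lambda2[-1])
  # two planted templates -> positions concentrate near N and N/2
  expect_true(all(abs(k$position - 12) < 1 | abs(k$position - 6) < 1))
  # frozen dynamics collapse to a single point
  frozen <- ipa_decompose_series(
    phase_series(matrix(sim$phases$theta[, 1], 12, 6), 1))
  kf <- ksd(frozen, "full_matrix")
  expect_equal(diff(range(kf$position)), 0)
  expect_equal(max(abs(kf$speed)), 0, tolerance = 1e-9)
  # the matrix-level and first-eigenvector speeds co-vary
  k1 <- ksd(dec, "eigvec1")
  ok <- complete.cases(k$speed, k1$speed)
  expect_gt(cor(k$speed[ok], k1$speed[ok]), 0)
})

test_that("the FCD matrix is a symmetric zero-diagonal pairwise distance table", {
  ps <- random_phase_series(7, 40, seed = 84)
  dec <- ipa_decompose_series(ps)
  f <- fcd(dec)
  expect_equal(dim(f), c(40, 40))
  expect_equal(f, t(f))
  expect_equal(diag(f), rep(0, 40))
  expect_true(all(f >= 0 & f <= 1, na.rm = TRUE))
  # superdiagonal is the reconfiguration speed, by definition
  expect_equal(f[cbind(1:39, 2:40)], reconfiguration_speed(dec),
               tolerance = 1e-12)
  # brute-force pairwise check on a 20-frame subset
  u <- frames_upper_triangle(dec)
  for (i in 1:20) for (j in 1:20) if (i < j)
    expect_equal(f[i, j], 1 - abs(cor(u[i, ], u[j, ])), tolerance = 1e-12)
  # frozen dynamics: the whole table vanishes
  frozen <- ipa_decompose_series(phase_series(matrix(ps$theta[, 2], 7, 6), 1))
  expect_equal(max(abs(fcd(frozen))), 0, tolerance = 1e-9)
})

test_that("FCD summaries are the mean and population variance of the upper triangle", {
  z <- matrix(0, 5, 5)
  expect_equal(fcd_summary(z), list(mean = 0, variance = 0))
  # two-valued FCD with known counts
  f <- matrix(0, 4, 4)
  f[1, 2] <- f[2, 1] <- 0.2
  f[3, 4] <- f[4, 3] <- 0.8
  s <- fcd_summary(f)   # upper triangle: 0.2, 0, 0, 0, 0, 0.8
  expect_equal(s$mean, 1 / 6)
  expect_equal(s$variance, mean((c(0.2, 0, 0, 0, 0, 0.8) - 1 / 6)^2))
  ps <- random_phase_series(6, 15, seed = 85)
  f <- fcd(ipa_decompose_series(ps))
  u <- f[upper.tri(f)]
  s <- fcd_summary(f)
  expect_equal(s$mean, mean(u))
  expect_equal(s$variance, mean((u - mean(u))^2))
})

test_that("LZW reproduces a hand-traced code sequence", {
  # 24-symbol stream over the 26-letter alphabet, traced by hand:
  # emitted phrases T O B E O R N O T TO BE OR TOB EO RN OT
  sym <- match(strsplit("TOBEORNOTTOBEORTOBEORNOT", "")[[1]], LETTERS) - 1L
  enc <- lzw_encode(sym, 26)
  codes_for <- function(s) match(s, LETTERS)
  expect_equal(enc$codes[1:9], codes_for(c("T", "O", "B", "E", "O", "R",
                                           "N", "O", "T")))
  # phrases added in order: TO=27, OB, BE, EO, OR, RN, NO, OT, TT, TOB=36,
  # BEO, ORT, TOBE, EOR, RNO; the tail re-emits TO BE OR TOB EO RN OT
  expect_equal(enc$codes[10:16], c(27L, 29L, 31L, 36L, 30L, 32L, 34L))
  expect_length(enc$codes, 16)
  expect_equal(enc$dict_size, 26 + 15)
  expect_equal(enc$bits, 16 * ceiling(log2(41)))
  expect_error(lzw_encode(integer(0), 4), "empty")
  expect_error(lzw_encode(c(0, 5), 4), "range")
})

test_that("LZW orders streams by regularity", {
  # periodic vs shuffled, across seeds
  for (seed in 1:10) {
    set.seed(seed)
    periodic <- rep(c(0L, 1L), 300)
    shuffled <- sample(periodic)
    expect_lt(lzw_encode(periodic, 2)$bits, lzw_encode(shuffled, 2)$bits)
  }
  # constant stream beats an i.i.d.-uniform one of equal length and alphabet
  set.seed(1)
  expect_lt(lzw_encode(rep(3L, 500), 8)$bits,
            lzw_encode(sample(0:7, 500, replace = TRUE), 8)$bits)
})

test_that("complexity of the eigenvector stream falls as phase order rises", {
  tpl <- mode_templates(12)[c("in_phase", "antiphase")]
  kappas <- c(0.5, 2, 5, 20, 200)
  res <- t(vapply(kappas, function(kap) {
    sim <- gen_planted_modes(tpl, 200, tr = 1, dwell_mean = 5,
                             jitter_kappa = kap, seed = 911)
    dec <- ipa_decompose_series(sim$phases)
    c(mean_l1 = mean(dec$lambda1), bits = as.numeric(lzw_complexity(dec)))
  }, numeric(2)))
  expect_true(all(diff(res[, "mean_l1"]) > 0))   # order rises with kappa
  expect_lt(cor(res[, "mean_l1"], res[, "bits"], method = "spearman"), 0)
})

test_that("lzw_complexity records its symbolisation metadata", {
  dec <- ipa_decompose_series(random_phase_series(6, 20, seed = 86))
  cx <- lzw_complexity(dec, n_levels = 16, mode = "lambda_series")
  expect_equal(attr(cx, "n_levels"), 16L)
  expect_equal(attr(cx, "mode"), "lambda_series")
  expect_equal(attr(cx, "stream_length"), 20L)
  expect_gt(as.numeric(cx), 0)
})
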