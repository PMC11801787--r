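# shared fixture builders; everything is generated in code under fixed seeds

random_phase_frame <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  runif(n, -pi, pi + .Machine$double.eps)  # open at -pi
}

random_phase_series <- function(n, tt, tr = 2, seed = 1) {
  set.seed(seed)
  phase_series(matrix(runif(n * tt, -pi, pi), n, tt), tr)
}

# fraction of spectral power of x inside [lo, hi] Hz, by direct FFT
# periodogram (independent of the signal package's filtering path)
power_fraction_in_band <- function(x, tr, lo, hi) {
  n <- length(x)
  p <- Mod(fft(x - mean(x)))^2
  f <- (seq_len(n) - 1) / (n * tr)
  half <- f <= 1 / (2 * tr)
  sum(p[half & f >= lo & f <= hi]) / sum(p[half])
}

# orthonormal basis of the span of the columns of m
orthobasis <- function(m) qr.Q(qr(m))

# largest principal angle (radians) between the column spans of a and b
max_principal_angle <- function(a, b) {
  d <- svd(crossprod(orthobasis(a), orthobasis(b)))$d
  max(acos(pmin(pmax(d, -1), 1)))
}

# the three analytic mode templates used in planted-mode fixtures
mode_templates <- function(n) {
  list(in_phase = gen_limit_case("all_in_phase", n),
       antiphase = gen_limit_case("phase_antiphase", n),
       quadrature = gen_limit_case("quadrature_blocks", n))
}
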