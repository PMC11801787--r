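#' Analytic limit-case phase configurations
#'
#' Phase vectors whose iPA decomposition is known exactly:
#' \itemize{
#'   \item \code{all_in_phase}: all phases equal — lambda1 = N, lambda2 = 0.
#'   \item \code{phase_antiphase}: phases theta0 or theta0 + pi — still
#'     rank 1, lambda1 = N, lambda2 = 0, but the Kuramoto modulus drops to
#'     |n_plus - n_minus| / N.
#'   \item \code{quadrature_blocks}: first N/2 phases theta0, last N/2
#'     theta0 + pi/2 — lambda1 = lambda2 = N/2, the maximally irreducible
#'     configuration.
#' }
#'
#' @param kind one of \code{"all_in_phase"}, \code{"phase_antiphase"},
#'   \code{"quadrature_blocks"}.
#' @param n number of regions (>= 2; even for \code{quadrature_blocks}).
#' @param theta0 base phase, radians (default 0).
#' @param n_antiphase for \code{phase_antiphase}: how many of the n phases
#'   sit at theta0 + pi (default floor(n/2)).
#' @return Numeric phase vector of length n.
#' @export
gen_limit_case <- function(kind = c("all_in_phase", "phase_antiphase",
                                    "quadrature_blocks"),
                           n, theta0 = 0, n_antiphase = floor(n / 2)) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (n < 2L) stop("need n >= 2")
  theta <- rep(theta0, n)
  if (kind == "phase_antiphase") {
    if (n_antiphase < 0L || n_antiphase > n) stop("invalid n_antiphase")
    if (n_antiphase > 0L)
      theta[seq_len(n_antiphase)] <- theta0 + pi
  } else if (kind == "quadrature_blocks") {
    if (n %% 2L != 0L) stop("quadrature_blocks requires even n")
    theta[(n / 2L + 1L):n] <- theta0 + pi / 2
  }
  wrap_phase(theta)
}

# von Mises sampler, Best & Fisher (1979) wrapped-Cauchy rejection;
# kappa = 0 is uniform, kappa = Inf degenerates to the mean direction
rvonmises <- function(n, mu = 0, kappa = 0) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (!is.finite(kappa)) return(rep(wrap_phase(mu), n))
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3L)
    z <- cos(pi * u[1L])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2L] > 0 || log(cc / u[2L]) + 1 - cc >= 0) {
      out[i] <- sign(u[3L] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_phase(mu + out)
}

#' Planted-mode phase series with known labels
#'
#' Generates a label sequence by geometric (memoryless) dwells of mean
#' \code{dwell_mean} frames over the supplied phase templates, and per-frame
#' phases equal to the active template plus independent von Mises jitter of
#' concentration \code{jitter_kappa} (\code{Inf} = no jitter). The returned
#' true labels make end-to-end mode-recovery tests possible.
#'
#' @param templates list of >= 2 phase vectors of equal length N.
#' @param n_frames number of frames T.
#' @param tr sampling interval, seconds.
#' @param dwell_mean mean dwell in frames (>= 1).
#' @param jitter_kappa von Mises concentration (>= 0; Inf for none).
#' @param seed integer RNG seed.
#' @return List with \code{phases} (a \code{\link{phase_series}}) and
#'   \code{labels} (integer series of template indices, length T).
#' @export
gen_planted_modes <- function(templates, n_frames, tr = 1, dwell_mean = 5,
                              jitter_kappa = Inf, seed = 1L) {
  if (!is.list(templates) || length(templates) < 2L)
    stop("need at least 2 templates")
  n <- length(templates[[1L]])
  if (!all(vapply(templates, length, integer(1L)) == n))
    stop("templates must have equal length")
  if (dwell_mean < 1) stop("dwell_mean must be >= 1 frame")
  k <- length(templates)
  with_preserved_seed(seed, {
    labels <- integer(0)
    state <- sample.int(k, 1L)
    while (length(labels) < n_frames) {
      # geometric dwell with mean dwell_mean: 1 + rgeom(p = 1/dwell_mean)
      dwell <- 1L + stats::rgeom(1L, prob = 1 / dwell_mean)
      labels <- c(labels, rep(state, dwell))
      nxt <- sample.int(k - 1L, 1L)
      state <- if (nxt >= state) nxt + 1L else nxt  # switch to a different mode
    }
    labels <- labels[seq_len(n_frames)]
    theta <- matrix(0, n, n_frames)
    for (t in seq_len(n_frames)) {
      base <- templates[[labels[t]]]
      theta[, t] <- wrap_phase(base + rvonmises(n, 0, jitter_kappa))
    }
    list(phases = phase_series(theta, tr), labels = labels)
  })
}

#' Narrowband noise recording
#'
#' Independent white-noise region signals bandpass-filtered to the requested
#' band: a stationary, unstructured stand-in for filtered resting-state
#' parcel series. Deterministic per seed.
#'
#' @param n_regions N >= 2.
#' @param n_frames T.
#' @param tr sampling interval, seconds (default 2.75).
#' @param band two-element band in Hz (default c(0.01, 0.08)).
#' @param seed integer RNG seed.
#' @return A \code{\link{region_ts}}.
#' @export
gen_narrowband <- function(n_regions, n_frames, tr = 2.75,
                           band = c(0.01, 0.08), seed = 1L) {
  x <- with_preserved_seed(seed,
    matrix(stats::rnorm(n_regions * n_frames), n_regions, n_frames))
  bandpass(region_ts(x, tr), band[1L], band[2L])
}

#' Kuramoto oscillator recording
#'
#' Euler-integrated Kuramoto system
#' dtheta_i/dt = omega_i + (K/N) sum_j sin(theta_j - theta_i), with natural
#' frequencies omega drawn from N(omega_mean, omega_sd), integrated at
#' dt = tr/10 and subsampled to the TR grid; emits cos(theta_i(t)) as the
#' region signals. K = 0 gives incoherent drift, large K full synchrony, and
#' intermediate K the metastable regime of maximal order-parameter
#' fluctuation.
#'
#' @param n_regions N >= 2.
#' @param n_frames T output frames.
#' @param tr sampling interval, seconds.
#' @param coupling K >= 0.
#' @param omega_mean,omega_sd natural-frequency distribution, rad/s.
#' @param seed integer RNG seed.
#' @return List with \code{ts} (a \code{\link{region_ts}} of cosines) and
#'   \code{theta} (N x T matrix of wrapped oscillator phases).
#' @export
gen_kuramoto <- function(n_regions, n_frames, tr = 1, coupling = 1,
                         omega_mean = 2 * pi * 0.05, omega_sd = 2 * pi * 0.01,
                         seed = 1L) {
  if (coupling < 0) stop("coupling must be >= 0")
  dt <- tr / 10
  with_preserved_seed(seed, {
    omega <- stats::rnorm(n_regions, omega_mean, omega_sd)
    th <- stats::runif(n_regions, -pi, pi)
    theta <- matrix(0, n_regions, n_frames)
    for (t in seq_len(n_frames)) {
      for (s in 1:10) {
        z <- mean(exp(1i * th))
        # mean-field form of the pairwise sine coupling
        th <- th + dt * (omega + coupling * Mod(z) * sin(Arg(z) - th))
      }
      theta[, t] <- th
    }
    theta <- wrap_phase(theta)
    list(ts = region_ts(cos(theta), tr), theta = theta)
  })
}
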