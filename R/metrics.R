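# population standard deviation (divide by length, not length-1);
# the metastability convention used throughout
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Spectral metastability
#'
#' Standard deviation over time of the spectral radius lambda1 of the iPA
#' matrix. Since lambda2 = N - lambda1 it equals the standard deviation of
#' lambda2 exactly. Population convention (divide by T).
#'
#' @param lambda1 numeric series of first eigenvalues (length >= 2), or an
#'   \code{ipa_decomposition}.
#' @return Non-negative scalar.
#' @export
spectral_metastability <- function(lambda1) {
  if (inherits(lambda1, "ipa_decomposition")) lambda1 <- lambda1$lambda1
  if (length(lambda1) < 2L)
    stop("need at least 2 frames to compute metastability")
  pop_sd(lambda1)
}

#' Kuramoto order parameter series
#'
#' Per-frame modulus of the mean unit phasor, |mean(exp(i theta))|: 1 when
#' all phases coincide, 0 when they spread uniformly on the circle. Note the
#' contrast with the spectral radius: two equal groups in antiphase give
#' r = 0 but lambda1 = N (antiphase pairs cancel in the phasor sum yet are
#' perfectly aligned in the cos^2 sense).
#'
#' @param phases a \code{\link{phase_series}} or an N x T phase matrix.
#' @return Numeric series of length T with values in [0, 1].
#' @export
kuramoto_series <- function(phases) {
  theta <- if (inherits(phases, "phase_series")) phases$theta
           else as.matrix(phases)
  r <- Mod(colMeans(exp(1i * theta)))
  pmin(r, 1)
}

#' Kuramoto metastability
#'
#' Standard deviation over time of the Kuramoto order parameter modulus
#' (population convention).
#'
#' @inheritParams kuramoto_series
#' @return Non-negative scalar.
#' @export
kuramoto_metastability <- function(phases) {
  r <- kuramoto_series(phases)
  if (length(r) < 2L) stop("need at least 2 frames to compute metastability")
  pop_sd(r)
}

#' Irreducibility index
#'
#' Fraction of frames in which lambda1 falls below a stated fraction of N:
#' the share of the recording in which reducing the iPA matrix to its first
#' eigenvector would retain less than that fraction of the total (trace)
#' information. Thresholds at or below 0.5 are rejected since lambda1 >= N/2
#' always and the index would be identically 0 — almost certainly a unit
#' mistake.
#'
#' @param lambda1 numeric lambda1 series or an \code{ipa_decomposition}.
#' @param threshold_fraction single number in (0.5, 1): threshold as a
#'   fraction of N.
#' @param n_regions N; taken from the decomposition when one is supplied.
#' @return Fraction in [0, 1].
#' @export
irreducibility_index <- function(lambda1, threshold_fraction,
                                 n_regions = NULL) {
  if (inherits(lambda1, "ipa_decomposition")) {
    n_regions <- lambda1$n_regions
    lambda1 <- lambda1$lambda1
  }
  if (is.null(n_regions)) stop("n_regions required with a bare lambda1 series")
  if (threshold_fraction <= 0.5 || threshold_fraction >= 1)
    stop("threshold_fraction must lie in (0.5, 1); lambda1 is never below N/2")
  mean(lambda1 < threshold_fraction * n_regions)
}

# default threshold grid for irreducibility profiles
eida_default_thresholds <- c(0.55, 0.60, 0.65, 0.70)

#' Functional connectivity index
#'
#' Sum of squared entries of a connectivity matrix (diagonal included; for an
#' N x N correlation or iPA matrix the unit diagonal contributes a constant
#' N).
#'
#' @param m square numeric matrix.
#' @return Non-negative scalar.
#' @export
fc_index <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  sum(m^2)
}

#' Static Pearson functional connectivity
#'
#' Pairwise Pearson correlation matrix of the region signals.
#'
#' @param ts a \code{\link{region_ts}} with no constant row.
#' @return Symmetric N x N correlation matrix, unit diagonal.
#' @export
pearson_fc <- function(ts) {
  stopifnot(inherits(ts, "region_ts"))
  vr <- apply(ts$data, 1L, stats::var)
  if (any(vr == 0))
    stop("constant (zero-variance) signal in row(s): ",
         paste(which(vr == 0), collapse = ", "))
  stats::cor(t(ts$data))
}

#' Group mean of squared connectivity matrices
#'
#' Elementwise mean of the squared matrices: squaring removes the correlation
#' sign before averaging across recordings.
#'
#' @param matrices non-empty list of equally sized square matrices.
#' @return Matrix of the same size with the elementwise mean of squares.
#' @export
group_mean_squared_fc <- function(matrices) {
  if (!is.list(matrices) || length(matrices) == 0L)
    stop("need a non-empty list of matrices")
  d <- dim(as.matrix(matrices[[1L]]))
  acc <- matrix(0, d[1L], d[2L])
  for (m in matrices) {
    m <- as.matrix(m)
    if (!identical(dim(m), d)) stop("matrix shape mismatch in group")
    acc <- acc + m^2
  }
  acc / length(matrices)
}

#' Time-averaged iPA matrix
#'
#' Mean over frames of the rebuilt per-frame iPA matrices.
#'
#' @param decomp an \code{ipa_decomposition}.
#' @return Symmetric N x N matrix with unit diagonal.
#' @export
mean_ipa <- function(decomp) {
  stopifnot(inherits(decomp, "ipa_decomposition"))
  tt <- length(decomp$lambda1)
  acc <- matrix(0, decomp$n_regions, decomp$n_regions)
  for (t in seq_len(tt))
    acc <- acc + ipa_rebuild(decomp$lambda1[t], decomp$lambda2[t],
                             decomp$v1[, t], decomp$v2[, t])
  acc <- acc / tt
  diag(acc) <- 1
  acc
}

#' Scalar metric report for a recording
#'
#' Convenience wrapper computing the full metric suite from phases and their
#' decomposition.
#'
#' @param phases a \code{\link{phase_series}}.
#' @param decomp optional precomputed \code{ipa_decomposition} of
#'   \code{phases}; computed on the fly when missing.
#' @param thresholds irreducibility threshold fractions, each in (0.5, 1).
#' @return List with \code{mean_lambda1}, \code{spectral_metastability},
#'   \code{kuramoto_metastability}, \code{irreducibility} (named by
#'   threshold), \code{fc_index_mean_ipa}.
#' @export
metrics_report <- function(phases, decomp = NULL,
                           thresholds = eida_default_thresholds) {
  stopifnot(inherits(phases, "phase_series"))
  if (is.null(decomp)) decomp <- ipa_decompose_series(phases)
  irr <- vapply(thresholds, function(f)
    irreducibility_index(decomp, f), numeric(1L))
  names(irr) <- format(thresholds)
  list(mean_lambda1 = mean(decomp$lambda1),
       spectral_metastability = spectral_metastability(decomp),
       kuramoto_metastability = kuramoto_metastability(phases),
       irreducibility = irr,
       fc_index_mean_ipa = fc_index(mean_ipa(decomp)))
}
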