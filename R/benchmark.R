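#' Paired timing of the closed-form decomposition vs the dense eigensolver
#'
#' Times \code{\link{ipa_decompose}} and \code{\link{ipa_eigen_oracle}} on
#' the same random-phase frames for each matrix size. Absolute times are
#' hardware-dependent; only the ratio column is meaningful, and it grows
#' with N because the closed form is O(N) per frame while the dense solver
#' is O(N^3).
#'
#' @param n_values integer vector of matrix sizes (>= 2 entries).
#' @param reps frames timed per size (default 20); each timing block runs
#'   all \code{reps} frames, so per-frame times are resolvable even when a
#'   single closed-form call is below clock resolution.
#' @param blocks timing blocks per method (default 5); mean and sd are taken
#'   over blocks.
#' @param seed integer RNG seed.
#' @return Data frame with columns \code{n}, \code{analytic_mean_s},
#'   \code{analytic_sd_s}, \code{oracle_mean_s}, \code{oracle_sd_s}
#'   (per-frame seconds), \code{ratio} (oracle / analytic); attributes
#'   \code{r_version} and \code{platform}.
#' @export
eida_benchmark <- function(n_values, reps = 20L, blocks = 5L, seed = 1L) {
  if (length(n_values) < 2L) stop("need at least 2 matrix sizes")
  rows <- lapply(n_values, function(n) {
    thetas <- with_preserved_seed(seed + n,
      lapply(seq_len(reps), function(i) stats::runif(n, -pi, pi)))
    mats <- lapply(thetas, ipa_matrix)
    ta <- vapply(seq_len(blocks), function(b) system.time(
      for (th in thetas) ipa_decompose(th))[["elapsed"]] / reps, numeric(1L))
    to <- vapply(seq_len(blocks), function(b) system.time(
      for (m in mats) ipa_eigen_oracle(m))[["elapsed"]] / reps, numeric(1L))
    data.frame(n = n, analytic_mean_s = mean(ta), analytic_sd_s = stats::sd(ta),
               oracle_mean_s = mean(to), oracle_sd_s = stats::sd(to),
               ratio = if (mean(ta) > 0) mean(to) / mean(ta) else Inf)
  })
  out <- do.call(rbind, rows)
  attr(out, "r_version") <- R.version.string
  attr(out, "platform") <- R.version$platform
  out
}
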