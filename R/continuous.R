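# 1 - |Pearson r| between rows of a matrix and the preceding row;
# zero-variance rows yield NA (degenerate marker), never an error mid-series
step_corr_distance <- function(m) {
  tt <- nrow(m)
  v <- apply(m, 1L, stats::var)
  out <- rep(NA_real_, tt - 1L)
  for (t in 2L:tt) {
    if (v[t] > 0 && v[t - 1L] > 0) {
      r <- stats::cor(m[t, ], m[t - 1L, ])
      out[t - 1L] <- min(max(1 - abs(r), 0), 1)
    }
  }
  out
}

#' Reconfiguration speed of the iPA matrix
#'
#' For each consecutive frame pair, 1 minus the absolute Pearson correlation
#' between the strictly-upper triangles of the rebuilt iPA matrices: 0 for a
#' frozen (or globally sign-flipped) pattern, approaching 1 for uncorrelated
#' reconfiguration. The series has length T-1, indexed to frames 2..T.
#' Frames whose upper triangle has zero variance yield NA at the adjacent
#' steps (degenerate marker).
#'
#' @param decomp an \code{ipa_decomposition} with T >= 2.
#' @return Numeric series of length T-1 with values in [0, 1] (NA at
#'   degenerate steps).
#' @export
reconfiguration_speed <- function(decomp) {
  stopifnot(inherits(decomp, "ipa_decomposition"))
  if (length(decomp$lambda1) < 2L) stop("need at least 2 frames")
  step_corr_distance(frames_upper_triangle(decomp))
}

#' Reconfiguration speed of a single eigenvector
#'
#' Same correlation distance as \code{\link{reconfiguration_speed}} but on
#' the eigenvector series itself: 1 - |Pearson(v(t), v(t-1))|. The absolute
#' value makes the measure invariant to the eigenvector sign ambiguity.
#'
#' @param decomp an \code{ipa_decomposition} with T >= 2.
#' @param which 1 or 2: which eigenvector series.
#' @return Numeric series of length T-1 in [0, 1] (NA at degenerate steps).
#' @export
eigvec_speed <- function(decomp, which = 1L) {
  stopifnot(inherits(decomp, "ipa_decomposition"))
  if (length(decomp$lambda1) < 2L) stop("need at least 2 frames")
  which <- match.arg(as.character(which), c("1", "2"))
  v <- if (which == "1") decomp$v1 else decomp$v2
  step_corr_distance(t(v))
}

#' Kinematic speed-displacement (KSD) trajectory
#'
#' Two-dimensional embedding of the continuous flow of phase alignment:
#' "position" is the eigenvalue (lambda1 for the full matrix and the first
#' eigenvector, lambda2 for the second eigenvector) and "speed" the matching
#' reconfiguration speed. The position series is aligned to the speed series
#' by dropping the first frame.
#'
#' @param decomp an \code{ipa_decomposition} with T >= 2.
#' @param variant one of \code{"full_matrix"}, \code{"eigvec1"},
#'   \code{"eigvec2"}.
#' @return A \code{ksd_trajectory}: data frame with columns \code{frame}
#'   (2..T), \code{position}, \code{speed}, plus attribute \code{variant}.
#' @export
ksd <- function(decomp, variant = c("full_matrix", "eigvec1", "eigvec2")) {
  stopifnot(inherits(decomp, "ipa_decomposition"))
  variant <- match.arg(variant)
  tt <- length(decomp$lambda1)
  if (tt < 2L) stop("need at least 2 frames")
  speed <- switch(variant,
    full_matrix = reconfiguration_speed(decomp),
    eigvec1 = eigvec_speed(decomp, 1L),
    eigvec2 = eigvec_speed(decomp, 2L))
  position <- switch(variant,
    full_matrix = decomp$lambda1,
    eigvec1 = decomp$lambda1,
    eigvec2 = decomp$lambda2)[-1L]
  out <- data.frame(frame = 2L:tt, position = position, speed = speed)
  attr(out, "variant") <- variant
  class(out) <- c("ksd_trajectory", "data.frame")
  out
}

#' Functional connectivity dynamics (FCD) matrix
#'
#' T x T matrix of pairwise distances between frames,
#' \code{1 - |Pearson(u_i, u_j)|} on strictly-upper triangles of the rebuilt
#' iPA matrices. Symmetric with zero diagonal; its superdiagonal equals the
#' reconfiguration speed by construction.
#'
#' @param decomp an \code{ipa_decomposition} with T >= 2.
#' @return T x T numeric matrix in [0, 1] (NA rows/columns at degenerate
#'   frames).
#' @export
fcd <- function(decomp) {
  stopifnot(inherits(decomp, "ipa_decomposition"))
  tt <- length(decomp$lambda1)
  if (tt < 2L) stop("need at least 2 frames")
  u <- frames_upper_triangle(decomp)
  v <- apply(u, 1L, stats::var)
  good <- v > 0
  f <- matrix(NA_real_, tt, tt)
  if (any(good)) {
    r <- stats::cor(t(u[good, , drop = FALSE]))
    f[good, good] <- pmin(pmax(1 - abs(r), 0), 1)
  }
  diag(f) <- 0
  f
}

#' Mean and variance of the FCD
#'
#' Summaries of dynamical fluidity over the strictly-upper-triangle entries
#' of the FCD matrix; the variance is also known as the switching index.
#' Population variance convention, consistent with the metastabilities.
#'
#' @param fcdm T x T FCD matrix (from \code{\link{fcd}}).
#' @return List with \code{mean} and \code{variance} (switching index).
#' @export
fcd_summary <- function(fcdm) {
  u <- fcdm[upper.tri(fcdm)]
  u <- u[!is.na(u)]
  if (length(u) == 0L) stop("no defined FCD entries")
  list(mean = mean(u), variance = mean((u - mean(u))^2))
}
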