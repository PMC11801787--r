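#' Instantaneous phase alignment matrix of one frame
#'
#' \code{iPA[i,j] = cos(theta_i - theta_j)}: 1 for perfectly in-phase pairs,
#' -1 for antiphase, 0 for quadrature. Equal to \code{c c' + s s'} with
#' \code{c = cos(theta)}, \code{s = sin(theta)}, hence symmetric, positive
#' semidefinite, unit diagonal and of rank at most 2.
#'
#' @param theta numeric vector of N >= 2 finite phases (radians).
#' @return Symmetric N x N matrix with entries in [-1, 1].
#' @export
ipa_matrix <- function(theta) {
  if (!all(is.finite(theta))) stop("non-finite phase in input")
  if (length(theta) < 2L) stop("need at least 2 phases")
  cv <- cos(theta); sv <- sin(theta)
  m <- tcrossprod(cv) + tcrossprod(sv)
  # clamp rounding excursions outside [-1, 1]
  m[m > 1] <- 1; m[m < -1] <- -1
  diag(m) <- 1
  m
}

# tolerance scale for degeneracy branches, relative to N
.eida_degeneracy_tol <- 1e-12

#' Closed-form eigendecomposition of one iPA frame
#'
#' Solves the rank-2 eigenproblem of \code{ipa_matrix(theta)} analytically.
#' With \code{gamma = ||c||^2}, \code{sigma = ||s||^2}, \code{xi = c.s} and
#' \code{Delta = (sigma-gamma)^2 + 4 xi^2}, the two non-null eigenvalues are
#' \code{lambda = (N +/- sqrt(Delta))/2} and the eigenvectors are unit-norm
#' combinations \code{c + B s}. The quadratic root for B is evaluated in the
#' cancellation-free form, and the second root uses \code{B1 B2 = -1}.
#'
#' Degenerate configurations never fail; they are resolved explicitly and
#' flagged:
#' \itemize{
#'   \item \code{xi ~ 0, sigma != gamma}: c and s are already orthogonal
#'     eigenvectors; returned normalised, ordered by eigenvalue (not flagged,
#'     the eigenpairs are unique).
#'   \item \code{xi ~ 0, sigma ~ gamma}: lambda1 = lambda2 = N/2, any rotation
#'     of \{c, s\} is an eigenbasis; the orthonormalised pair is returned and
#'     \code{degenerate = TRUE}.
#'   \item \code{||s||^2 ~ 0} (all phases ~ 0 or pi; rank 1): lambda1 = gamma,
#'     v1 = c/||c||, lambda2 = 0, v2 = 0 and \code{degenerate = TRUE}
#'     (symmetrically when \code{||c||^2} collapses).
#' }
#'
#' @param theta numeric vector of N >= 2 finite phases (radians).
#' @return List with \code{lambda1}, \code{lambda2}, \code{v1}, \code{v2}
#'   (unit vectors; v2 is the zero vector in the rank-1 branch) and the
#'   logical \code{degenerate}.
#' @export
ipa_decompose <- function(theta) {
  if (!all(is.finite(theta))) stop("non-finite phase in input")
  n <- length(theta)
  if (n < 2L) stop("need at least 2 phases")
  cv <- cos(theta); sv <- sin(theta)
  gam <- sum(cv * cv); sig <- sum(sv * sv); xi <- sum(cv * sv)
  tol <- .eida_degeneracy_tol * n

  if (sig < tol || gam < tol) {
    # rank-1 collapse: one of c, s vanishes (phases all ~0/pi or ~ +/- pi/2)
    if (sig < tol) { v1 <- cv / sqrt(gam); l1 <- gam }
    else           { v1 <- sv / sqrt(sig); l1 <- sig }
    return(list(lambda1 = l1, lambda2 = 0, v1 = canonical_sign(v1),
                v2 = numeric(n), degenerate = TRUE))
  }

  if (gam * sig - xi^2 < tol * n) {
    # rank-1 collapse with c parallel to s (both norms nonzero): the Gram
    # determinant vanishes, lambda2 = 0, and the single eigenvector is the
    # direction of the larger of c, s
    v1 <- if (gam >= sig) cv / sqrt(gam) else sv / sqrt(sig)
    return(list(lambda1 = n, lambda2 = 0, v1 = canonical_sign(v1),
                v2 = numeric(n), degenerate = TRUE))
  }

  if (abs(xi) < tol) {
    if (abs(sig - gam) < tol) {
      # lambda1 = lambda2 = N/2: eigenbasis only defined up to rotation
      v1 <- cv / sqrt(gam)
      v2 <- sv - sum(sv * v1) * v1
      v2 <- v2 / sqrt(sum(v2 * v2))
      return(list(lambda1 = n / 2, lambda2 = n / 2,
                  v1 = canonical_sign(v1), v2 = canonical_sign(v2),
                  degenerate = TRUE))
    }
    # c and s orthogonal with distinct norms: they are the eigenvectors
    if (gam >= sig) {
      return(list(lambda1 = gam, lambda2 = sig,
                  v1 = canonical_sign(cv / sqrt(gam)),
                  v2 = canonical_sign(sv / sqrt(sig)), degenerate = FALSE))
    }
    return(list(lambda1 = sig, lambda2 = gam,
                v1 = canonical_sign(sv / sqrt(sig)),
                v2 = canonical_sign(cv / sqrt(gam)), degenerate = FALSE))
  }

  delta <- (sig - gam)^2 + 4 * xi^2
  sq <- sqrt(delta)
  l1 <- (n + sq) / 2
  l2 <- (n - sq) / 2
  if (l2 < 0) l2 <- 0
  # stable quadratic root: avoid subtractive cancellation in B1
  b1 <- if (xi * (sig - gam) >= 0) ((sig - gam) + sq) / (2 * xi)
        else 2 * xi / ((gam - sig) + sq)
  b2 <- -1 / b1
  v1 <- cv + b1 * sv; v1 <- v1 / sqrt(sum(v1 * v1))
  v2 <- cv + b2 * sv; v2 <- v2 / sqrt(sum(v2 * v2))
  list(lambda1 = l1, lambda2 = l2,
       v1 = canonical_sign(v1), v2 = canonical_sign(v2), degenerate = FALSE)
}

# flip so the largest-magnitude component is positive (ties -> first index);
# rebuilt matrices are sign-invariant, this only stabilises serialised output
canonical_sign <- function(v) {
  i <- which.max(abs(v))
  if (length(i) && v[i] < 0) -v else v
}

#' Frame-by-frame closed-form decomposition of a phase series
#'
#' Applies \code{\link{ipa_decompose}} to every column of the phase matrix.
#'
#' @param phases a \code{\link{phase_series}}, or a plain N x T numeric matrix
#'   of phases (then \code{tr} must be given).
#' @param tr sampling interval in seconds (ignored if \code{phases} is a
#'   \code{phase_series}).
#' @return An \code{ipa_decomposition}: list with numeric series
#'   \code{lambda1}, \code{lambda2} (length T), matrices \code{v1}, \code{v2}
#'   (N x T, unit columns, canonical signs), logical \code{degenerate}
#'   (length T), \code{n_regions} and \code{tr}.
#' @export
ipa_decompose_series <- function(phases, tr = NULL) {
  if (inherits(phases, "phase_series")) {
    theta <- phases$theta; tr <- phases$tr
  } else {
    theta <- as.matrix(phases)
    if (is.null(tr)) stop("tr must be supplied when phases is a bare matrix")
  }
  n <- nrow(theta); tt <- ncol(theta)
  l1 <- numeric(tt); l2 <- numeric(tt); dg <- logical(tt)
  v1 <- matrix(0, n, tt); v2 <- matrix(0, n, tt)
  for (t in seq_len(tt)) {
    d <- tryCatch(ipa_decompose(theta[, t]),
                  error = function(e) stop("frame ", t, ": ",
                                           conditionMessage(e), call. = FALSE))
    l1[t] <- d$lambda1; l2[t] <- d$lambda2
    v1[, t] <- d$v1; v2[, t] <- d$v2; dg[t] <- d$degenerate
  }
  structure(list(lambda1 = l1, lambda2 = l2, v1 = v1, v2 = v2,
                 degenerate = dg, n_regions = n, tr = as.numeric(tr)),
            class = "ipa_decomposition")
}

#' @export
print.ipa_decomposition <- function(x, ...) {
  cat("<ipa_decomposition> N = ", x$n_regions, ", T = ", length(x$lambda1),
      ", TR = ", x$tr, " s\n", sep = "")
  cat("  lambda1: mean ", signif(mean(x$lambda1), 5), ", sd ",
      signif(stats::sd(x$lambda1), 5), ", degenerate frames: ",
      sum(x$degenerate), "\n", sep = "")
  invisible(x)
}

#' Rebuild an iPA matrix from its two weighted eigenvectors
#'
#' \code{lambda1 v1 v1' + lambda2 v2 v2'}; exact (to rounding) inverse of
#' \code{\link{ipa_decompose}}, and invariant under sign flips of either
#' eigenvector.
#'
#' @param lambda1,lambda2 non-negative eigenvalues.
#' @param v1,v2 eigenvectors of equal length (unit norm for a true iPA frame).
#' @return Symmetric matrix \code{lambda1 v1 v1' + lambda2 v2 v2'}.
#' @export
ipa_rebuild <- function(lambda1, lambda2, v1, v2) {
  if (length(v1) != length(v2)) stop("eigenvector length mismatch")
  lambda1 * tcrossprod(v1) + lambda2 * tcrossprod(v2)
}

#' Dense symmetric eigensolver oracle
#'
#' Full LAPACK eigendecomposition (eigenvalues descending), used as the
#' numerical cross-check for the closed-form path and as the timing baseline.
#'
#' @param m square numeric matrix, symmetric within \code{tol}.
#' @param tol symmetry tolerance on max |m - t(m)|.
#' @return List with \code{values} (descending) and \code{vectors} (columns).
#' @export
ipa_eigen_oracle <- function(m, tol = 1e-8) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  if (max(abs(m - t(m))) > tol) stop("matrix is not symmetric within ", tol)
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  list(values = e$values, vectors = e$vectors)
}

#' Strictly-upper-triangle vectorisation
#'
#' Fixed row-major order of the strictly-upper entries (diagonal excluded):
#' (1,2), (1,3), ..., (1,N), (2,3), ... This is the vector space in which
#' cosine distances, reconfiguration speeds and FCD correlations operate.
#'
#' @param m square matrix.
#' @return Numeric vector of length N(N-1)/2.
#' @seealso \code{\link{ut_to_matrix}}
#' @export
upper_triangle <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  t(m)[lower.tri(m)]  # row-major order of the upper triangle
}

#' Restore a symmetric matrix from its strictly-upper triangle
#'
#' @param u vector of length N(N-1)/2 in the order of
#'   \code{\link{upper_triangle}}.
#' @param diag_value value placed on the diagonal (1 for iPA matrices).
#' @return Symmetric N x N matrix.
#' @export
ut_to_matrix <- function(u, diag_value = 1) {
  p <- length(u)
  n <- (1 + sqrt(1 + 8 * p)) / 2
  if (n != round(n)) stop("length ", p, " is not N(N-1)/2 for integer N")
  n <- as.integer(round(n))
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- u   # fills column-major lower = row-major upper
  m <- t(m)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- diag_value
  m
}
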