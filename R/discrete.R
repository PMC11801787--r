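#' Strictly-upper triangles of the rebuilt iPA frames
#'
#' Rebuilds every frame from its stored two weighted eigenvectors and stacks
#' the strictly-upper-triangle vectors as rows. This is the (lossless) data
#' matrix that discrete and continuous analyses operate on.
#'
#' @param decomp an \code{ipa_decomposition}.
#' @return T x N(N-1)/2 numeric matrix.
#' @export
frames_upper_triangle <- function(decomp) {
  stopifnot(inherits(decomp, "ipa_decomposition"))
  tt <- length(decomp$lambda1)
  p <- decomp$n_regions * (decomp$n_regions - 1L) / 2L
  u <- matrix(0, tt, p)
  for (t in seq_len(tt))
    u[t, ] <- upper_triangle(ipa_rebuild(decomp$lambda1[t], decomp$lambda2[t],
                                         decomp$v1[, t], decomp$v2[, t]))
  u
}

#' Cosine distance between a decomposition frame and a centroid
#'
#' Rebuilds the frame's iPA matrix from its weighted eigenvectors, takes the
#' strictly-upper triangle u, and returns 1 - cos(u, centroid). Because the
#' rebuild is a sum of quadratic forms, the distance is invariant to sign
#' flips of either eigenvector and to v1/v2 swaps when lambda1 = lambda2.
#'
#' @param frame list with \code{lambda1}, \code{lambda2}, \code{v1},
#'   \code{v2} (one decomposition frame).
#' @param centroid numeric vector of length N(N-1)/2.
#' @return Distance in [0, 2].
#' @export
eida_distance <- function(frame, centroid) {
  u <- upper_triangle(ipa_rebuild(frame$lambda1, frame$lambda2,
                                  frame$v1, frame$v2))
  if (length(u) != length(centroid)) stop("centroid length mismatch")
  nu <- sqrt(sum(u^2)); nc <- sqrt(sum(centroid^2))
  if (nu == 0 || nc == 0) stop("zero-norm vector in cosine distance")
  1 - sum(u * centroid) / (nu * nc)
}

# cosine similarity of the rows of u against the rows of centroids
cos_sim <- function(u_unit, centroids) {
  cn <- sqrt(rowSums(centroids^2))
  if (any(cn == 0)) stop("zero-norm centroid")
  tcrossprod(u_unit, centroids / cn)
}

run_kmeans_once <- function(u, u_unit, k, init_idx, max_iter) {
  centroids <- u[init_idx, , drop = FALSE]
  labels <- integer(nrow(u))
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    sim <- cos_sim(u_unit, centroids)
    new_labels <- max.col(sim, ties.method = "first")
    # empty-cluster repair: promote the frame farthest from its centroid
    repeat {
      sizes <- tabulate(new_labels, nbins = k)
      empty <- which(sizes == 0L)
      if (length(empty) == 0L) break
      d_own <- 1 - sim[cbind(seq_len(nrow(u)), new_labels)]
      far <- which.max(d_own)
      centroids[empty[1L], ] <- u[far, ]
      sim <- cos_sim(u_unit, centroids)
      new_labels <- max.col(sim, ties.method = "first")
    }
    if (iter > 1L && all(new_labels == labels)) { converged <- TRUE; break }
    labels <- new_labels
    for (j in seq_len(k))
      centroids[j, ] <- colMeans(u[labels == j, , drop = FALSE])
    if (iter >= max_iter) break
  }
  sim <- cos_sim(u_unit, centroids)
  d <- 1 - sim[cbind(seq_len(nrow(u)), labels)]
  list(labels = labels, centroids = centroids, inertia = sum(d^2),
       n_iter = iter, converged = converged)
}

#' Discrete mode analysis: k-means over rebuilt iPA matrices
#'
#' Clusters the frames of a decomposition into k recurrent phase-alignment
#' modes. Each frame is represented losslessly by its two weighted
#' eigenvectors; distances are cosine distances between strictly-upper
#' triangles of the rebuilt matrices, so the clustering is mathematically
#' equivalent to k-means on the full iPA matrices and immune to the
#' eigenvector sign-flip and near-degenerate v1/v2-swap ambiguities.
#' Assignment uses the cosine distance; the centroid update is the
#' arithmetic mean of the assigned upper triangles (exactly this pair, even
#' though the mean is not the cosine-distance minimiser — convergence is by
#' zero reassignments, with \code{max_iter} as a guard and
#' \code{converged = FALSE} reported if the loop is cut off).
#'
#' Centroids are initialised from k distinct randomly chosen frames; the
#' best of \code{restarts} runs (lowest inertia) is returned. Deterministic
#' given \code{seed}.
#'
#' @param decomp an \code{ipa_decomposition} with T >= k frames.
#' @param k number of modes, >= 1.
#' @param seed integer RNG seed.
#' @param restarts independent initialisations (default 10).
#' @param max_iter iteration cap per run (default 300).
#' @return An \code{eida_clusters} object: \code{k}, \code{centroids}
#'   (k x N(N-1)/2), \code{labels} (1-based, length T), \code{inertia}
#'   (sum of squared cosine distances), \code{n_iter}, \code{converged},
#'   \code{seed}.
#' @export
discrete_eida <- function(decomp, k, seed = 1L, restarts = 10L,
                          max_iter = 300L) {
  stopifnot(inherits(decomp, "ipa_decomposition"))
  tt <- length(decomp$lambda1)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > tt) stop("k = ", k, " exceeds the number of frames T = ", tt)
  u <- frames_upper_triangle(decomp)
  un <- sqrt(rowSums(u^2))
  if (any(un == 0)) stop("zero-norm frame(s): ",
                         paste(which(un == 0), collapse = ", "))
  u_unit <- u / un
  init_sets <- with_preserved_seed(seed, lapply(seq_len(restarts),
                                                function(i) sample.int(tt, k)))
  best <- NULL
  for (init_idx in init_sets) {
    fit <- run_kmeans_once(u, u_unit, k, init_idx, max_iter)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  structure(c(best, list(k = k, seed = as.integer(seed),
                         n_regions = decomp$n_regions, tr = decomp$tr)),
            class = "eida_clusters")
}

#' @export
print.eida_clusters <- function(x, ...) {
  cat("<eida_clusters> k = ", x$k, ", T = ", length(x$labels),
      ", inertia = ", signif(x$inertia, 6),
      if (x$converged) ", converged" else ", NOT converged", "\n", sep = "")
  invisible(x)
}

#' Fractional occurrence of each mode
#'
#' Share of frames assigned to each cluster; sums to 1.
#'
#' @param labels integer labels in 1..k (or an \code{eida_clusters}).
#' @param k number of clusters.
#' @return Numeric vector of length k summing to 1.
#' @export
fractional_occurrence <- function(labels, k = NULL) {
  if (inherits(labels, "eida_clusters")) { k <- labels$k; labels <- labels$labels }
  if (is.null(k)) k <- max(labels)
  tabulate(labels, nbins = k) / length(labels)
}

#' Mean dwell time of each mode
#'
#' Average duration, in seconds, of the maximal contiguous runs of each
#' label. A cluster never visited is reported as NA (undefined), not 0.
#'
#' @param labels integer labels in 1..k (or an \code{eida_clusters}; then
#'   \code{tr} and \code{k} are taken from it).
#' @param tr sampling interval, seconds.
#' @param k number of clusters.
#' @return Numeric vector of length k (seconds; NA for unvisited clusters).
#' @export
dwell_time <- function(labels, tr = NULL, k = NULL) {
  if (inherits(labels, "eida_clusters")) {
    tr <- labels$tr; k <- labels$k; labels <- labels$labels
  }
  if (is.null(tr) || tr <= 0) stop("tr must be a positive number of seconds")
  if (is.null(k)) k <- max(labels)
  r <- rle(labels)
  vapply(seq_len(k), function(j) {
    len <- r$lengths[r$values == j]
    if (length(len) == 0L) NA_real_ else mean(len) * tr
  }, numeric(1L))
}

#' Spectral metastability within each mode
#'
#' Standard deviation (population convention) of lambda1 restricted to the
#' frames of each cluster; clusters with fewer than 2 frames are NA.
#'
#' @param labels integer labels in 1..k (or an \code{eida_clusters}).
#' @param lambda1 numeric lambda1 series aligned with the labels.
#' @param k number of clusters.
#' @return Numeric vector of length k.
#' @export
per_cluster_spectral_metastability <- function(labels, lambda1, k = NULL) {
  if (inherits(labels, "eida_clusters")) { k <- labels$k; labels <- labels$labels }
  if (is.null(k)) k <- max(labels)
  stopifnot(length(labels) == length(lambda1))
  vapply(seq_len(k), function(j) {
    x <- lambda1[labels == j]
    if (length(x) < 2L) NA_real_ else pop_sd(x)
  }, numeric(1L))
}

#' Elbow curve for choosing k
#'
#' Best-of-restarts inertia (sum of squared cosine distances) as a function
#' of k, for selecting the number of modes from the inertia knee.
#'
#' @param decomp an \code{ipa_decomposition}.
#' @param k_values integer vector of cluster counts to evaluate.
#' @param seed integer RNG seed (one independent stream per k).
#' @param restarts,max_iter passed to \code{\link{discrete_eida}}.
#' @return Data frame with columns \code{k} and \code{inertia}.
#' @export
elbow_curve <- function(decomp, k_values, seed = 1L, restarts = 10L,
                        max_iter = 300L) {
  inertia <- vapply(k_values, function(k)
    discrete_eida(decomp, k, seed = seed, restarts = restarts,
                  max_iter = max_iter)$inertia, numeric(1L))
  data.frame(k = as.integer(k_values), inertia = inertia)
}
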