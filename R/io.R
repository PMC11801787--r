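#' Read a parcellated time-series matrix from delimited text
#'
#' Comma- or tab-separated numeric matrix, "." decimal. A single header row
#' of region labels is auto-detected (any non-numeric cell in the first
#' line). Orientation is regions-in-rows by default; use
#' \code{orientation = "rows_time"} for timepoints-in-rows input, which is
#' transposed on load.
#'
#' @param path file path.
#' @param tr sampling interval, seconds (required; no silent default).
#' @param orientation \code{"rows_regions"} (default) or \code{"rows_time"}.
#' @param sep field separator; inferred from the file extension
#'   (".tsv" -> tab, else comma) when NULL.
#' @return A \code{\link{region_ts}}.
#' @export
read_region_ts <- function(path, tr, orientation = c("rows_regions",
                                                     "rows_time"),
                           sep = NULL) {
  orientation <- match.arg(orientation)
  if (missing(tr)) stop("tr (sampling interval, seconds) must be supplied")
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  has_header <- any(is.na(suppressWarnings(as.numeric(first))))
  raw <- utils::read.table(path, sep = sep, header = has_header,
                           check.names = FALSE)
  for (j in seq_along(raw)) {
    if (!is.numeric(raw[[j]]))
      stop("non-numeric value in column ", j, " of ", path)
  }
  m <- as.matrix(raw)
  labels <- NULL
  if (orientation == "rows_time") {
    labels <- if (has_header) colnames(raw) else NULL
    m <- t(m)
  }
  dimnames(m) <- NULL
  region_ts(m, tr, region_labels = labels)
}

#' Write a region time series as CSV
#'
#' One row per region; a header row of region labels is written when labels
#' are present.
#'
#' @param ts a \code{\link{region_ts}}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_region_ts <- function(ts, path) {
  stopifnot(inherits(ts, "region_ts"))
  utils::write.table(ts$data, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Serialise a decomposition series to CSV
#'
#' One row per frame: \code{t, lambda1, lambda2, degenerate,
#' v1_1..v1_N, v2_1..v2_N} — the 2N+2-number lossless representation (plus
#' bookkeeping) instead of the N(N-1)/2 matrix entries.
#'
#' @param decomp an \code{ipa_decomposition}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_decomposition_csv <- function(decomp, path) {
  stopifnot(inherits(decomp, "ipa_decomposition"))
  n <- decomp$n_regions
  df <- data.frame(t = seq_along(decomp$lambda1),
                   lambda1 = decomp$lambda1, lambda2 = decomp$lambda2,
                   degenerate = as.integer(decomp$degenerate))
  v1 <- t(decomp$v1); colnames(v1) <- paste0("v1_", seq_len(n))
  v2 <- t(decomp$v2); colnames(v2) <- paste0("v2_", seq_len(n))
  utils::write.csv(cbind(df, v1, v2), path, row.names = FALSE)
  invisible(path)
}

#' Read a decomposition series from CSV
#'
#' Inverse of \code{\link{write_decomposition_csv}}.
#'
#' @param path file path.
#' @param tr sampling interval, seconds.
#' @return An \code{ipa_decomposition}.
#' @export
read_decomposition_csv <- function(path, tr) {
  df <- utils::read.csv(path)
  n <- sum(grepl("^v1_", names(df)))
  structure(list(lambda1 = df$lambda1, lambda2 = df$lambda2,
                 v1 = t(as.matrix(df[paste0("v1_", seq_len(n))])),
                 v2 = t(as.matrix(df[paste0("v2_", seq_len(n))])),
                 degenerate = as.logical(df$degenerate),
                 n_regions = n, tr = as.numeric(tr)),
            class = "ipa_decomposition")
}

#' Write a square matrix as headerless CSV
#'
#' @param m numeric matrix.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
write_matrix_csv <- function(m, path) {
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a headerless CSV matrix
#'
#' @param path file path.
#' @return Numeric matrix.
#' @export
read_matrix_csv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(m) <- NULL
  m
}
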