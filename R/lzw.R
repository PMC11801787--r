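#' Lempel-Ziv-Welch encoding of an integer symbol stream
#'
#' Dictionary-based LZW with the dictionary initialised to the
#' \code{alphabet_size} single symbols (codes 1..alphabet_size). Longest
#' known prefixes are emitted as codes and each emitted-prefix-plus-next
#' symbol is added as a new dictionary entry.
#'
#' @param symbols integer vector with values in 0..alphabet_size-1.
#' @param alphabet_size number of distinct symbols in the initial dictionary
#'   (>= 2).
#' @return List with \code{codes} (integer vector of emitted codes),
#'   \code{dict_size} (final dictionary size) and \code{bits}
#'   (\code{length(codes) * ceiling(log2(dict_size))}).
#' @export
lzw_encode <- function(symbols, alphabet_size) {
  symbols <- as.integer(symbols)
  if (length(symbols) == 0L) stop("empty symbol stream")
  alphabet_size <- as.integer(alphabet_size)
  if (alphabet_size < 2L) stop("alphabet_size must be >= 2")
  if (any(symbols < 0L | symbols >= alphabet_size))
    stop("symbols out of alphabet range")
  dict <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(alphabet_size))
    assign(as.character(i - 1L), i, envir = dict)
  dict_size <- alphabet_size
  codes <- integer(0)
  w <- as.character(symbols[1L])
  if (length(symbols) > 1L) for (k in symbols[-1L]) {
    wk <- paste0(w, ",", k)
    if (!is.null(dict[[wk]])) {
      w <- wk
    } else {
      codes <- c(codes, dict[[w]])
      dict_size <- dict_size + 1L
      assign(wk, dict_size, envir = dict)
      w <- as.character(k)
    }
  }
  codes <- c(codes, dict[[w]])
  list(codes = codes, dict_size = dict_size,
       bits = length(codes) * as.integer(ceiling(log2(dict_size))))
}

# uniform quantisation of a numeric vector into n_levels bins over its
# global range; a constant vector maps to level 0
quantize_uniform <- function(x, n_levels) {
  rng <- range(x)
  if (rng[2L] == rng[1L]) return(integer(length(x)))
  q <- floor((x - rng[1L]) / (rng[2L] - rng[1L]) * n_levels)
  as.integer(pmin(q, n_levels - 1L))
}

#' LZW informational complexity of the eigenvector dynamics
#'
#' Compresses a quantised representation of the decomposition with LZW and
#' reports the number of bits needed: more bits means a more random,
#' unpredictable evolution; fewer bits a more ordered, repetitive one. The
#' default representation concatenates, frame by frame in time order, the
#' weighted eigenvectors sqrt(lambda1) v1 and sqrt(lambda2) v2, uniformly
#' binned into \code{n_levels} levels over the global min-max range.
#' The symbolisation choices are recorded as attributes of the result since
#' the absolute bit count is only comparable between identical settings.
#'
#' @param decomp an \code{ipa_decomposition}.
#' @param n_levels quantisation levels (alphabet size), >= 2; default 256.
#' @param mode \code{"weighted_eigvecs"} (default) or \code{"lambda_series"}
#'   (quantised lambda1 series only).
#' @return Integer bit count with attributes \code{n_levels}, \code{mode},
#'   \code{n_codes}, \code{dict_size}, \code{stream_length}.
#' @export
lzw_complexity <- function(decomp, n_levels = 256L,
                           mode = c("weighted_eigvecs", "lambda_series")) {
  stopifnot(inherits(decomp, "ipa_decomposition"))
  mode <- match.arg(mode)
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("n_levels must be >= 2")
  series <- switch(mode,
    weighted_eigvecs = as.numeric(rbind(
      sweep(decomp$v1, 2L, sqrt(decomp$lambda1), `*`),
      sweep(decomp$v2, 2L, sqrt(decomp$lambda2), `*`))),
    lambda_series = decomp$lambda1)
  enc <- lzw_encode(quantize_uniform(series, n_levels), n_levels)
  structure(enc$bits, n_levels = n_levels, mode = mode,
            n_codes = length(enc$codes), dict_size = enc$dict_size,
            stream_length = length(series))
}
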