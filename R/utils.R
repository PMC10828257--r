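`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

check_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_inf && !is.finite(x)) || x < min || x > max) {
    stop_input(sprintf("invalid value for '%s'", name))
  }
  invisible(x)
}

clip01 <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)

#' Derive a reproducible substream seed
#'
#' Derives an integer seed for an independent random substream from a root
#' seed and a vector of integer indices (for example plate, worm, and
#' purpose indices). The scheme is a polynomial hash: starting from the
#' root, each index is folded in as `s <- (s * 69069 + index + 1) mod
#' (2^31 - 1)`. Because each (plate, worm) pair owns its own substream,
#' adding plates or worms to a simulation never shifts the random numbers
#' used by existing ones.
#'
#' @param root Integer root seed.
#' @param indices Integer vector of stream coordinates.
#' @return A single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' substream_seed(1, c(2, 7))
#' @export
substream_seed <- function(root, indices) {
  m <- 2147483647 # 2^31 - 1; keeps products below 2^53 for exact doubles
  s <- as.numeric(root) %% m
  for (idx in as.numeric(indices)) {
    s <- (s * 69069 + idx + 1) %% m
  }
  as.integer(s)
}

# row-major ("raster") rank of pixel coordinates, used for stable object ids
raster_rank <- function(row, col, ncol) (row - 1) * ncol + col
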