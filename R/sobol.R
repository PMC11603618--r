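# Unscrambled Sobol' low-discrepancy sequence (direction numbers after
# Joe & Kuo), up to 16 dimensions -- ample for the parameter counts the
# multistart estimator samples. Gray-code construction; fully
# deterministic, so starting points can be appended later without
# reshuffling the earlier ones.

# Direction-number table: dimension d >= 2 rows of (s, a, m_1..m_s).
.sobol_table <- list(
  list(s = 1, a = 0,  m = c(1)),
  list(s = 2, a = 1,  m = c(1, 3)),
  list(s = 3, a = 1,  m = c(1, 3, 1)),
  list(s = 3, a = 2,  m = c(1, 1, 1)),
  list(s = 4, a = 1,  m = c(1, 1, 3, 3)),
  list(s = 4, a = 4,  m = c(1, 3, 5, 13)),
  list(s = 5, a = 2,  m = c(1, 1, 5, 5, 17)),
  list(s = 5, a = 4,  m = c(1, 1, 5, 5, 5)),
  list(s = 5, a = 7,  m = c(1, 1, 7, 11, 19)),
  list(s = 5, a = 11, m = c(1, 1, 5, 1, 1)),
  list(s = 5, a = 13, m = c(1, 1, 1, 3, 11)),
  list(s = 5, a = 14, m = c(1, 3, 5, 5, 31)),
  list(s = 6, a = 1,  m = c(1, 3, 3, 9, 7, 49)),
  list(s = 6, a = 13, m = c(1, 1, 1, 15, 21, 21)),
  list(s = 6, a = 16, m = c(1, 3, 1, 13, 27, 49)))

.sobol_nbits <- 31L

# Direction numbers V[k] (k = 1..nbits) for dimension d, as doubles
# scaled by 2^-nbits internally (returned as integers < 2^31).
sobol_directions <- function(d, nbits = .sobol_nbits) {
  if (d == 1) return(2^(nbits - seq_len(nbits)))
  tab <- .sobol_table[[d - 1]]
  s <- tab$s; a <- tab$a; m <- tab$m
  V <- numeric(nbits)
  V[seq_len(min(s, nbits))] <- m[seq_len(min(s, nbits))] *
    2^(nbits - seq_len(min(s, nbits)))
  if (nbits > s) {
    for (k in (s + 1):nbits) {
      v <- bitwXor2(V[k - s], floor(V[k - s] / 2^s))
      for (j in seq_len(s - 1)) {
        if (bitwAnd(floor(a / 2^(s - 1 - j)), 1) == 1)
          v <- bitwXor2(v, V[k - j])
      }
      V[k] <- v
    }
  }
  V
}

# XOR for doubles holding 31-bit integers.
bitwXor2 <- function(x, y) {
  as.numeric(bitwXor(as.integer(x), as.integer(y)))
}

#' Unscrambled Sobol' sequence points in the unit cube
#'
#' Deterministic low-discrepancy points; point index 0 is the origin.
#' Requesting the same `(n, dim, skip)` always returns the same matrix,
#' and increasing `n` extends the set without changing earlier points.
#'
#' @param n Number of points.
#' @param dim Dimension (1..16).
#' @param skip Number of initial points to skip.
#' @return `n x dim` matrix in `[0, 1)`.
#' @export
sobol_sequence <- function(n, dim, skip = 0) {
  stopifnot(n >= 1, dim >= 1, dim <= length(.sobol_table) + 1, skip >= 0)
  V <- lapply(seq_len(dim), sobol_directions)
  ntot <- n + skip
  X <- matrix(0, ntot, dim)
  state <- numeric(dim)
  # Gray-code: point i obtained from point i-1 by XOR with V[c], where
  # c is the position of the lowest zero bit of i-1.
  if (ntot > 1) {
    for (i in 2:ntot) {
      ii <- i - 2
      c <- 1L
      while (bitwAnd(ii, 1L) == 1L) { ii <- bitwShiftR(ii, 1L); c <- c + 1L }
      for (j in seq_len(dim)) state[j] <- bitwXor2(state[j], V[[j]][c])
      X[i, ] <- state
    }
  }
  X[(skip + 1):ntot, , drop = FALSE] / 2^.sobol_nbits
}

#' Sobol' multistart parameter vectors
#'
#' Maps the unscrambled Sobol' sequence into per-parameter sampling
#' bounds. Bounds must be finite; by convention they span the plausible
#' magnitude range of each parameter (the default used by the
#' estimator is two decades around the starting magnitudes).
#'
#' @param n Number of starting vectors.
#' @param lower,upper Finite bound vectors (length = number of free
#'   parameters).
#' @param skip Number of initial Sobol' points to skip (default 1,
#'   skipping the origin point which maps onto `lower`).
#' @param log_scale Sample uniformly in log-space (natural for
#'   magnitude-type parameters); requires positive bounds.
#' @return `n x length(lower)` matrix; rows are starting vectors.
#' @export
sobol_starts <- function(n, lower, upper, skip = 1, log_scale = TRUE) {
  stopifnot(length(lower) == length(upper))
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("Sobol' sampling requires finite bounds for every parameter",
         call. = FALSE)
  if (any(upper <= lower))
    stop("Sobol' sampling bounds must satisfy lower < upper", call. = FALSE)
  d <- length(lower)
  U <- sobol_sequence(n, d, skip)
  if (log_scale) {
    if (any(lower <= 0))
      stop("log-scale Sobol' sampling requires positive lower bounds",
           call. = FALSE)
    exp(sweep(sweep(U, 2, log(upper) - log(lower), "*"), 2, log(lower), "+"))
  } else {
    sweep(sweep(U, 2, upper - lower, "*"), 2, lower, "+")
  }
}
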