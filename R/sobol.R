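# Sobol' low-discrepancy sequences for quasi-Monte-Carlo integration over
# covariate distributions. Direction numbers are from the Joe & Kuo (2008)
# "new-joe-kuo-6" table (first 21 dimensions), which optimises 2D projections.
# Points are generated with 31 bits of precision via the Gray-code recursion.

# Each row: dimension (>= 2), degree s, coefficient integer a, then m_1..m_s.
.sobol_joe_kuo <- list(
  list(s = 1L, a = 0L,  m = c(1L)),
  list(s = 2L, a = 1L,  m = c(1L, 3L)),
  list(s = 3L, a = 1L,  m = c(1L, 3L, 1L)),
  list(s = 3L, a = 2L,  m = c(1L, 1L, 1L)),
  list(s = 4L, a = 1L,  m = c(1L, 1L, 3L, 3L)),
  list(s = 4L, a = 4L,  m = c(1L, 3L, 5L, 13L)),
  list(s = 5L, a = 2L,  m = c(1L, 1L, 5L, 5L, 17L)),
  list(s = 5L, a = 4L,  m = c(1L, 1L, 5L, 5L, 5L)),
  list(s = 5L, a = 7L,  m = c(1L, 1L, 7L, 11L, 19L)),
  list(s = 5L, a = 11L, m = c(1L, 1L, 5L, 1L, 1L)),
  list(s = 5L, a = 13L, m = c(1L, 1L, 1L, 3L, 11L)),
  list(s = 5L, a = 14L, m = c(1L, 3L, 5L, 5L, 31L)),
  list(s = 6L, a = 1L,  m = c(1L, 3L, 3L, 9L, 7L, 49L)),
  list(s = 6L, a = 13L, m = c(1L, 1L, 1L, 15L, 21L, 21L)),
  list(s = 6L, a = 16L, m = c(1L, 3L, 1L, 13L, 27L, 49L)),
  list(s = 6L, a = 19L, m = c(1L, 1L, 1L, 15L, 7L, 5L)),
  list(s = 6L, a = 22L, m = c(1L, 3L, 1L, 15L, 13L, 25L)),
  list(s = 6L, a = 25L, m = c(1L, 1L, 5L, 5L, 19L, 61L)),
  list(s = 7L, a = 1L,  m = c(1L, 3L, 7L, 11L, 23L, 15L, 103L)),
  list(s = 7L, a = 4L,  m = c(1L, 3L, 7L, 13L, 13L, 15L, 69L))
)

.SOBOL_BITS <- 31L
.SOBOL_MAX_DIM <- length(.sobol_joe_kuo) + 1L

# Direction integers V[b, j] (b = 1..31 bits, j = dimension), scaled so that
# point value = XOR-accumulated integer / 2^31.
.sobol_direction_matrix <- function(dim) {
  nb <- .SOBOL_BITS
  V <- matrix(0L, nrow = nb, ncol = dim)
  # dimension 1: van der Corput in base 2
  V[, 1L] <- bitwShiftL(1L, nb - seq_len(nb))
  if (dim == 1L) return(V)
  for (j in 2:dim) {
    dn <- .sobol_joe_kuo[[j - 1L]]
    s <- dn$s
    m <- integer(nb)
    m[seq_len(min(s, nb))] <- dn$m[seq_len(min(s, nb))]
    if (nb > s) {
      # coefficient bits a_1..a_{s-1} of the primitive polynomial
      acoef <- as.integer(bitwAnd(bitwShiftR(dn$a, (s - 2L):0L), 1L))
      for (k in (s + 1L):nb) {
        mk <- bitwXor(m[k - s], bitwShiftL(m[k - s], s))
        if (s > 1L) {
          for (i in seq_len(s - 1L)) {
            if (acoef[i] == 1L)
              mk <- bitwXor(mk, bitwShiftL(m[k - i], i))
          }
        }
        m[k] <- mk
      }
    }
    V[, j] <- bitwShiftL(m, nb - seq_len(nb))
  }
  V
}

#' Generate Sobol' points in the unit hypercube
#'
#' Produces a deterministic low-discrepancy point set in `[0, 1)^dim` used as
#' the backbone of the numerical integration over covariate distributions.
#' Points are scrambled by a seeded random digital shift (bitwise XOR with a
#' per-dimension random integer), which preserves the low-discrepancy
#' structure while avoiding the degenerate all-zeros first point (which maps
#' to \code{-Inf} under an inverse normal transform).
#'
#' @param n_points number of points (>= 1).
#' @param dim dimension, one per covariate (1 to 20 supported).
#' @param seed integer seed for the digital shift. The same seed, `n_points`
#'   and `dim` always give bit-identical output.
#' @param scramble logical; set `FALSE` for the raw unscrambled sequence
#'   (first point is the origin). Mainly for validation.
#' @return an `n_points` by `dim` numeric matrix with entries in `[0, 1)`.
#' @examples
#' u <- sobol_unit_points(64, 3, seed = 1)
#' colMeans(u)  # close to 0.5
#' @export
sobol_unit_points <- function(n_points, dim, seed = 1L, scramble = TRUE) {
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 1)
    stop("`n_points` must be a single integer >= 1")
  if (!is.numeric(dim) || length(dim) != 1L || dim < 1)
    stop("`dim` must be a single integer >= 1")
  n_points <- as.integer(n_points); dim <- as.integer(dim)
  if (dim > .SOBOL_MAX_DIM)
    stop("`dim` = ", dim, " exceeds the supported maximum of ", .SOBOL_MAX_DIM,
         " dimensions")
  if (n_points >= 2^25)
    stop("`n_points` must be below 2^25")
  V <- .sobol_direction_matrix(dim)
  X <- matrix(0L, nrow = n_points, ncol = dim)
  x <- integer(dim)  # running XOR state; point 1 is the origin
  X[1L, ] <- x
  if (n_points > 1L) {
    for (i in seq_len(n_points - 1L)) {
      # Gray code: flip the bit at the position of the lowest zero bit of i-1
      c <- 1L
      value <- i - 1L
      while (bitwAnd(value, 1L) == 1L) {
        value <- bitwShiftR(value, 1L)
        c <- c + 1L
      }
      x <- bitwXor(x, V[c, ])
      X[i + 1L, ] <- x
    }
  }
  if (scramble) {
    shift <- withr::with_seed(as.integer(seed), {
      as.integer(floor(stats::runif(dim) * 2^.SOBOL_BITS))
    })
    X <- matrix(bitwXor(rep(shift, each = n_points), X), nrow = n_points)
  }
  X / 2^.SOBOL_BITS
}
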