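# Sobol' (LP-tau) low-discrepancy sequence generator.
#
# Direction numbers are the published Joe & Kuo "new-joe-kuo-6" constants
# (search criterion D(6)), here for dimensions 2..50; dimension 1 is the
# van der Corput sequence in base 2. Points are generated in Gray-code
# order with 31-bit precision, which keeps all direction integers within
# R's integer range.

# primitive polynomial degree per dimension (dims 2..50)
.sobol_s <- c(1, 2, 3, 3, 4, 4, 5, 5, 5, 5, 5, 5, 6, 6, 6, 6, 6, 6, 7, 7,
              7, 7, 7, 7, 7, 7, 7, 7, 7, 7, 7, 7, 7, 7, 7, 7, 8, 8, 8, 8,
              8, 8, 8, 8, 8, 8, 8, 8, 8)
# polynomial coefficient encoding (binary digits a_1..a_{s-1})
.sobol_a <- c(0, 1, 1, 2, 1, 4, 2, 4, 7, 11, 13, 14, 1, 13, 16, 19, 22,
              25, 1, 4, 7, 8, 14, 19, 21, 28, 31, 32, 37, 41, 42, 50, 55,
              56, 59, 62, 14, 21, 22, 38, 47, 49, 50, 52, 56, 67, 70, 84,
              97)
# initial direction values m_1..m_s
.sobol_m <- list(
  c(1), c(1, 3), c(1, 3, 1), c(1, 1, 1), c(1, 1, 3, 3), c(1, 3, 5, 13),
  c(1, 1, 5, 5, 17), c(1, 1, 5, 5, 5), c(1, 1, 7, 11, 19),
  c(1, 1, 5, 1, 1), c(1, 1, 1, 3, 11), c(1, 3, 5, 5, 31),
  c(1, 3, 3, 9, 7, 49), c(1, 1, 1, 15, 21, 21), c(1, 3, 1, 13, 27, 49),
  c(1, 1, 1, 15, 7, 5), c(1, 3, 1, 15, 13, 25), c(1, 1, 5, 5, 19, 61),
  c(1, 3, 7, 11, 23, 15, 103), c(1, 3, 7, 13, 13, 15, 69),
  c(1, 1, 3, 13, 7, 35, 63), c(1, 3, 5, 9, 1, 25, 53),
  c(1, 3, 1, 13, 9, 35, 107), c(1, 3, 1, 5, 27, 61, 31),
  c(1, 1, 5, 11, 19, 41, 61), c(1, 3, 5, 3, 3, 13, 69),
  c(1, 1, 7, 13, 1, 19, 1), c(1, 3, 7, 5, 13, 19, 59),
  c(1, 1, 3, 9, 25, 29, 41), c(1, 3, 5, 13, 23, 1, 55),
  c(1, 3, 7, 3, 13, 59, 17), c(1, 3, 1, 3, 5, 53, 69),
  c(1, 1, 5, 5, 23, 33, 13), c(1, 1, 7, 7, 1, 61, 123),
  c(1, 1, 7, 9, 13, 61, 49), c(1, 3, 3, 5, 3, 55, 33),
  c(1, 3, 1, 15, 31, 13, 49, 245), c(1, 3, 5, 15, 31, 59, 63, 97),
  c(1, 3, 1, 11, 11, 11, 77, 249), c(1, 3, 1, 11, 27, 43, 71, 9),
  c(1, 1, 7, 15, 21, 11, 81, 45), c(1, 3, 7, 3, 25, 31, 65, 79),
  c(1, 3, 1, 1, 19, 11, 3, 205), c(1, 1, 5, 9, 19, 21, 29, 157),
  c(1, 3, 7, 11, 1, 33, 89, 185), c(1, 3, 3, 3, 15, 9, 79, 71),
  c(1, 3, 7, 11, 15, 39, 119, 27), c(1, 1, 3, 1, 11, 31, 97, 225),
  c(1, 1, 1, 3, 23, 43, 57, 177)
)

.sobol_max_dim <- length(.sobol_s) + 1

# direction integers V[j, bit] for one dimension, scaled to 31 bits
.sobol_directions <- function(dim, bits = 31L) {
  if (dim == 1) {
    m <- rep(1L, bits)
  } else {
    s <- .sobol_s[dim - 1]
    a <- .sobol_a[dim - 1]
    m <- integer(bits)
    m[seq_len(min(s, bits))] <- .sobol_m[[dim - 1]][seq_len(min(s, bits))]
    if (bits > s) {
      for (j in (s + 1):bits) {
        val <- bitwXor(m[j - s], m[j - s] * as.integer(2^s))
        if (s > 1) {
          for (k in 1:(s - 1)) {
            ak <- bitwAnd(bitwShiftR(a, s - 1 - k), 1L)
            if (ak == 1L) val <- bitwXor(val, m[j - k] * as.integer(2^k))
          }
        }
        m[j] <- val
      }
    }
  }
  as.integer(m * 2^(bits - seq_len(bits)))
}

#' Generate points of the Sobol' (LP-tau) sequence
#'
#' Returns `n` consecutive points of the unscrambled Sobol' sequence in
#' the unit hypercube, in Gray-code order. Under the default
#' `skip = 1` the initial all-zero point is dropped, so the first
#' returned point is the cube midpoint (0.5, ..., 0.5).
#'
#' @param n Number of points.
#' @param k Dimension (at most 50).
#' @param skip Number of leading sequence points to drop (default 1,
#'   the zero point).
#' @return An `n` by `k` matrix with entries in (0, 1).
#' @export
sobol_sequence <- function(n, k, skip = 1L) {
  stopifnot(n >= 1, k >= 1, skip >= 0)
  if (k > .sobol_max_dim) {
    stop("Sobol' direction numbers available for at most ", .sobol_max_dim,
         " dimensions (requested ", k, ")", call. = FALSE)
  }
  bits <- 31L
  v <- vapply(seq_len(k), .sobol_directions, integer(bits), bits = bits)
  x <- integer(k)
  out <- matrix(0, n, k)
  total <- n + skip
  row <- 0L
  for (i in seq_len(total)) {
    if (i > skip) {
      row <- row + 1L
      out[row, ] <- x / 2^bits
    }
    if (i == total) break
    # position of the lowest zero bit of (i - 1)
    c_ <- 1L
    val <- i - 1L
    while (bitwAnd(val, 1L) == 1L) {
      val <- bitwShiftR(val, 1L)
      c_ <- c_ + 1L
    }
    x <- bitwXor(x, v[c_, ])
  }
  out
}

#' Build an LP-tau parameter design
#'
#' Scales a Sobol'/LP-tau sequence onto the native ranges of a parameter
#' table, producing the space-filling design matrix run through the crop
#' model in a sensitivity analysis (e.g. the 400-combination designs used
#' for the millet and rice models).
#'
#' @param specs A `param_ranges` table ([parameter_ranges()]).
#' @param n Number of design points.
#' @param skip Leading Sobol' points to drop (default 1; the first design
#'   point is then every parameter at its range midpoint).
#' @return A list of class `sensitivity_design`: `specs`, `unit_points`
#'   (n x k in (0,1)), `scaled_points` (native units, columns named by
#'   parameter), `method = "lp_tau"`.
#' @export
lp_tau_design <- function(specs, n, skip = 1L) {
  stopifnot(inherits(specs, "param_ranges"), n >= 1)
  k <- nrow(specs)
  unit <- sobol_sequence(n, k, skip = skip)
  scaled <- sweep(unit, 2, specs$max - specs$min, `*`)
  scaled <- sweep(scaled, 2, specs$min, `+`)
  colnames(unit) <- colnames(scaled) <- specs$name
  structure(list(specs = specs, unit_points = unit, scaled_points = scaled,
                 method = "lp_tau"),
            class = "sensitivity_design")
}
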