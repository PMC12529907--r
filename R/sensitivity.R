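# Sobol-sequence parameter perturbation, outlier screening, coefficients of
# variation, and partial correlation coefficients.

# Joe & Kuo (2008) primitive polynomials (full binary encoding) and initial
# direction numbers for dimensions 2..23; dimension 1 is the van der Corput
# sequence in base 2. Sample (n-1) standard deviations are used throughout
# the module.
SOBOL_POLY <- c(3L, 7L, 11L, 13L, 19L, 25L, 37L, 41L, 47L, 55L, 59L, 61L,
                67L, 91L, 97L, 103L, 109L, 115L, 131L, 137L, 143L, 145L)
SOBOL_MINIT <- list(
  c(1L), c(1L, 3L), c(1L, 3L, 1L), c(1L, 1L, 1L), c(1L, 1L, 3L, 3L),
  c(1L, 3L, 5L, 13L), c(1L, 1L, 5L, 5L, 17L), c(1L, 1L, 5L, 5L, 5L),
  c(1L, 1L, 7L, 11L, 19L), c(1L, 1L, 5L, 1L, 1L), c(1L, 1L, 1L, 3L, 11L),
  c(1L, 3L, 5L, 5L, 31L), c(1L, 3L, 3L, 9L, 7L, 49L),
  c(1L, 1L, 1L, 15L, 21L, 21L), c(1L, 3L, 1L, 13L, 27L, 49L),
  c(1L, 1L, 1L, 15L, 7L, 5L), c(1L, 3L, 1L, 15L, 13L, 25L),
  c(1L, 1L, 5L, 5L, 19L, 61L), c(1L, 3L, 7L, 11L, 23L, 15L, 103L),
  c(1L, 3L, 7L, 13L, 13L, 15L, 69L), c(1L, 1L, 3L, 13L, 7L, 35L, 63L),
  c(1L, 3L, 5L, 9L, 1L, 25L, 53L)
)
SOBOL_BITS <- 30L

sobol_direction_numbers <- function(dim) {
  v <- integer(SOBOL_BITS)
  if (dim == 1) {
    for (j in seq_len(SOBOL_BITS)) v[j] <- bitwShiftL(1L, SOBOL_BITS - j)
    return(v)
  }
  poly <- SOBOL_POLY[dim - 1]
  m <- SOBOL_MINIT[[dim - 1]]
  s <- length(m)
  for (j in seq_len(s)) v[j] <- bitwShiftL(m[j], SOBOL_BITS - j)
  if (SOBOL_BITS > s) {
    # interior coefficient bits of the primitive polynomial
    a <- integer(max(s - 1, 0))
    for (k in seq_len(max(s - 1, 0))) a[k] <- bitwAnd(bitwShiftR(poly, s - k), 1L)
    for (j in (s + 1):SOBOL_BITS) {
      vj <- bitwXor(v[j - s], bitwShiftR(v[j - s], s))
      for (k in seq_len(max(s - 1, 0))) {
        if (a[k] == 1L) vj <- bitwXor(vj, v[j - k])
      }
      v[j] <- vj
    }
  }
  v
}

#' Sobol low-discrepancy sequence
#'
#' Gray-code Sobol points in the unit hypercube, first point (the origin)
#' included. An optional seed applies a per-dimension digital shift
#' (XOR scramble), preserving the low-discrepancy structure while
#' randomizing positions; the same seed always yields the same points.
#'
#' @param n Number of points.
#' @param dim Dimension (1..23).
#' @param seed `NULL` for the unscrambled sequence, otherwise an integer
#'   scramble seed.
#' @return An `n x dim` matrix in `[0, 1)`.
#' @export
sobol_sequence <- function(n, dim, seed = NULL) {
  if (n <= 0) abort("n must be positive", class = "cgm_invalid_parameter")
  if (dim < 1 || dim > length(SOBOL_POLY) + 1) {
    abort(paste0("dim must be in 1..", length(SOBOL_POLY) + 1),
          class = "cgm_invalid_parameter")
  }
  V <- vapply(seq_len(dim), sobol_direction_numbers, integer(SOBOL_BITS))
  shift <- integer(dim)
  if (!is.null(seed)) {
    set.seed(seed)
    shift <- as.integer(floor(runif(dim) * 2^SOBOL_BITS))
  }
  out <- matrix(0, n, dim)
  state <- integer(dim)
  out[1, ] <- bitwXor(state, shift) / 2^SOBOL_BITS
  if (n > 1) {
    for (i in 2:n) {
      # Gray-code construction: flip the direction of the lowest zero bit
      c_ <- 1L
      im1 <- i - 2L
      while (bitwAnd(im1, 1L) == 1L) {
        im1 <- bitwShiftR(im1, 1L)
        c_ <- c_ + 1L
      }
      state <- bitwXor(state, V[c_, ])
      out[i, ] <- bitwXor(state, shift) / 2^SOBOL_BITS
    }
  }
  out
}

#' Perturb a parameter vector with a Sobol design
#'
#' Maps Sobol points onto the box `[base (1 - fraction), base (1 + fraction)]`
#' per dimension — the quasi-random 5% perturbation design used for
#' sensitivity analysis.
#'
#' @param base Named numeric vector of (nonzero) base parameter values.
#' @param fraction Relative half-width of the perturbation box (default
#'   0.05).
#' @param n Number of parameter sets (default 5000).
#' @param seed Scramble seed (same seed, same sets).
#' @return Tibble of `n` parameter sets with `base`'s names.
#' @export
sobol_perturb <- function(base, fraction = 0.05, n = 5000, seed = 1) {
  if (n <= 0) abort("n must be positive", class = "cgm_invalid_parameter")
  if (any(base == 0)) abort("base values must be nonzero for relative bounds",
                            class = "cgm_invalid_parameter")
  u <- sobol_sequence(n, length(base), seed = seed)
  lo <- base * (1 - fraction); hi <- base * (1 + fraction)
  swap <- lo > hi   # negative base values flip the interval
  tmp <- lo[swap]; lo[swap] <- hi[swap]; hi[swap] <- tmp
  out <- sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
  colnames(out) <- names(base)
  as_tibble(out)
}

#' Screen outlier rows from a sensitivity table
#'
#' Single-pass screen: a row is dropped when any of the named property
#' columns deviates more than `k` standard deviations from that column's
#' mean (sample sd). `k = Inf` is the identity.
#'
#' @param table Tibble of parameter sets and resulting properties.
#' @param property_cols Columns to screen on (default: all numeric columns
#'   not matching parameter names passed via `param_cols`).
#' @param k Deviation threshold in sd units (default 3).
#' @param param_cols Optional parameter columns excluded from screening.
#' @return The filtered tibble, with attribute `n_retained`.
#' @export
screen_outliers <- function(table, property_cols = NULL, k = 3,
                            param_cols = NULL) {
  table <- as_tibble(table)
  if (nrow(table) < 2) abort("need at least 2 rows", class = "cgm_invalid_parameter")
  if (is.null(property_cols)) {
    property_cols <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                             param_cols)
  }
  keep <- rep(TRUE, nrow(table))
  if (is.finite(k)) {
    for (cl in property_cols) {
      v <- table[[cl]]
      s <- sd(v)
      if (s > 0) keep <- keep & abs(v - mean(v)) <= k * s
    }
  }
  out <- table[keep, ]
  attr(out, "n_retained") <- sum(keep)
  out
}

#' Coefficient of variation
#'
#' `100 * sd / mean` (sample sd), a scale-free dispersion measure.
#'
#' @param series Numeric vector with nonzero mean.
#' @return Percent CoV.
#' @export
cov_percent <- function(series) {
  m <- mean(series)
  if (m == 0) abort("zero mean", class = "cgm_division_error")
  100 * sd(series) / abs(m)
}

#' Partial correlation coefficients
#'
#' For each parameter column `x_j`: regress `x_j` on all other parameters,
#' regress the property `y` on all other parameters, and report the Pearson
#' correlation of the two residual vectors — the direct association between
#' `x_j` and `y` controlling for the remaining covariates.
#'
#' @param X Matrix or tibble of parameter columns (n rows > ncol + 2, full
#'   column rank).
#' @param y Property vector of length n.
#' @return Tibble with `parameter` and `pcc` in `[-1, 1]`.
#' @export
partial_corr <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n)
  if (n <= p + 2) abort("need more rows than columns + 2",
                        class = "cgm_invalid_parameter")
  qrX <- qr(cbind(1, X))
  if (qrX$rank < p + 1) {
    bad <- colnames(X)[qrX$pivot[seq_len(p + 1)] > 1][qrX$rank:p]
    abort(paste0("collinear parameter columns: ",
                 paste(stats::na.omit(bad), collapse = ", ")),
          class = "cgm_collinearity_error")
  }
  nm <- colnames(X) %||% paste0("x", seq_len(p))
  pcc <- vapply(seq_len(p), function(j) {
    Z <- cbind(1, X[, -j, drop = FALSE])
    rx <- stats::lm.fit(Z, X[, j])$residuals
    ry <- stats::lm.fit(Z, y)$residuals
    cor(rx, ry)
  }, 1.0)
  tibble(parameter = nm, pcc = pcc)
}

#' Sensitivity analysis of a property map
#'
#' Convenience wrapper chaining [sobol_perturb()], a property evaluation
#' function, [screen_outliers()], [cov_percent()] and [partial_corr()].
#'
#' @param base Named base parameter vector.
#' @param property_fun Function mapping a named parameter vector to a named
#'   numeric vector of properties.
#' @param fraction,n,seed Passed to [sobol_perturb()].
#' @param k Outlier threshold in sd units.
#' @return List with `table` (screened), `n_retained`, `cov` (per property),
#'   `pcc` (long tibble parameter x property).
#' @export
sensitivity_analysis <- function(base, property_fun, fraction = 0.05,
                                 n = 5000, seed = 1, k = 3) {
  params <- sobol_perturb(base, fraction, n, seed)
  props <- purrr::map_dfr(seq_len(n), function(i) {
    as_tibble(as.list(property_fun(unlist(params[i, ]))))
  })
  full <- dplyr::bind_cols(params, props)
  screened <- screen_outliers(full, property_cols = names(props), k = k)
  covs <- vapply(names(props), function(p) cov_percent(screened[[p]]), 1.0)
  pcc <- purrr::map_dfr(names(props), function(p) {
    dplyr::mutate(partial_corr(screened[, names(base)], screened[[p]]),
                  property = p)
  })
  list(table = screened, n_retained = attr(screened, "n_retained"),
       cov = covs, pcc = pcc)
}
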