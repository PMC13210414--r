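# Periodised discrete wavelet transform with Daubechies-4 (db4, 8-tap)
# filters. Implemented in-package; the forward transform agrees with the
# standard periodised DWT convention (coefficient-level), and the inverse is
# the adjoint of the orthonormal analysis operator.

DB4_DEC_LO <- c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
                -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
                0.7148465705529157, 0.2303778133088965)
DB4_DEC_HI <- c(-0.2303778133088965, 0.7148465705529157, -0.6308807679298589,
                -0.027983769416859854, 0.18703481171909309, 0.030841381835560764,
                -0.0328830116668852, -0.010597401785069032)

# one analysis step on an even-length series; periodic boundary
.dwt_step <- function(x) {
  n <- length(x)
  stopifnot(n %% 2 == 0)
  lo <- rev(DB4_DEC_LO)
  hi <- rev(DB4_DEC_HI)
  half <- n / 2
  a <- numeric(half)
  d <- numeric(half)
  base <- 2 * (0:(half - 1))
  for (m in 0:7) {
    idx <- ((base + m - 3) %% n) + 1
    a <- a + lo[m + 1] * x[idx]
    d <- d + hi[m + 1] * x[idx]
  }
  list(a = a, d = d)
}

# inverse of .dwt_step (adjoint of the orthonormal analysis operator)
.idwt_step <- function(a, d) {
  half <- length(a)
  n <- 2 * half
  lo <- rev(DB4_DEC_LO)
  hi <- rev(DB4_DEC_HI)
  x <- numeric(n)
  base <- 2 * (0:(half - 1))
  for (m in 0:7) {
    idx <- ((base + m - 3) %% n) + 1
    x[idx] <- x[idx] + lo[m + 1] * a + hi[m + 1] * d
  }
  x
}

#' Multilevel periodised db4 wavelet decomposition
#'
#' @param x numeric series; length must be divisible by `2^level`.
#' @param level decomposition depth.
#' @return list with approximation `a` and detail coefficients `d` (list,
#'   finest level first).
#' @export
dwt_db4 <- function(x, level = 4L) {
  if (length(x) %% 2^level != 0) {
    stop("series length must be divisible by 2^level")
  }
  details <- vector("list", level)
  a <- x
  for (l in seq_len(level)) {
    st <- .dwt_step(a)
    a <- st$a
    details[[l]] <- st$d
  }
  list(a = a, d = details)
}

#' Inverse of [dwt_db4()]
#'
#' @param w decomposition as returned by [dwt_db4()].
#' @return reconstructed numeric series.
#' @export
idwt_db4 <- function(w) {
  a <- w$a
  for (l in rev(seq_along(w$d))) {
    a <- .idwt_step(a, w$d[[l]])
  }
  a
}
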