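# Vectorized bilinear interpolation on uniform grids; points outside the
# hull are clamped to it.
#' @keywords internal
interp_bilinear <- function(M, gx, gy, x, y) {
  nx <- length(gx); ny <- length(gy)
  sx <- if (nx > 1) gx[2] - gx[1] else 1
  sy <- if (ny > 1) gy[2] - gy[1] else 1
  px <- (x - gx[1]) / sx
  py <- (y - gy[1]) / sy
  i0 <- pmin(pmax(floor(px), 0), nx - 2)
  j0 <- pmin(pmax(floor(py), 0), ny - 2)
  fx <- pmin(pmax(px - i0, 0), 1)
  fy <- pmin(pmax(py - j0, 0), 1)
  i0 <- as.integer(i0); j0 <- as.integer(j0)
  v00 <- M[i0 + 1L + j0 * nx]
  v10 <- M[i0 + 2L + j0 * nx]
  v01 <- M[i0 + 1L + (j0 + 1L) * nx]
  v11 <- M[i0 + 2L + (j0 + 1L) * nx]
  (1 - fy) * ((1 - fx) * v00 + fx * v10) + fy * ((1 - fx) * v01 + fx * v11)
}

#' @keywords internal
#' @useDynLib thiamalloc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats simulate
NULL
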