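#' @keywords internal
"_PACKAGE"

# Numerical tolerance used for arc-length / angle comparisons throughout.
.EPS <- 1e-9

stop_f <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_f("'%s' must be a single positive finite number (got %s)", name,
           paste(format(x), collapse = ","))
  invisible(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
    stop_f("'%s' must lie in [0, 1] (got %s)", name, format(x))
  invisible(x)
}

#' Convert between micrometre coordinates and fractional pixel indices
#'
#' The package uses 0-based pixel indexing for its coordinate convention: a
#' particle sitting exactly at the centre of pixel (i, j) (0-based row i,
#' column j) has micrometre position ((j + 0.5) * pixel_size,
#' (i + 0.5) * pixel_size), with x = column and y = row.  In R's 1-based
#' matrix indexing this means x maps to fractional column index
#' x / pixel_size + 0.5.
#'
#' @param x,y coordinates in micrometres
#' @param pixel_size pixel size in micrometres per pixel
#' @return `um_to_index` returns a list with fractional `row` and `col`
#'   (1-based, sub-pixel); `index_to_um` the inverse.
#' @keywords internal
um_to_index <- function(x, y, pixel_size) {
  list(row = y / pixel_size + 0.5, col = x / pixel_size + 0.5)
}

#' @rdname um_to_index
#' @param row,col 1-based (possibly fractional) matrix indices
#' @keywords internal
index_to_um <- function(row, col, pixel_size) {
  list(x = (col - 0.5) * pixel_size, y = (row - 0.5) * pixel_size)
}

#' Bilinear interpolation of a matrix at fractional indices
#'
#' Indices outside the matrix are clamped to the border.
#'
#' @param m numeric matrix
#' @param row,col equal-length vectors of fractional 1-based indices
#' @return numeric vector of interpolated values
#' @keywords internal
bilinear <- function(m, row, col) {
  nr <- nrow(m); nc <- ncol(m)
  row <- pmin(pmax(row, 1), nr)
  col <- pmin(pmax(col, 1), nc)
  r0 <- pmin(floor(row), nr - 1L); c0 <- pmin(floor(col), nc - 1L)
  if (nr == 1L) r0 <- rep(1L, length(row))
  if (nc == 1L) c0 <- rep(1L, length(col))
  fr <- row - r0; fc <- col - c0
  i00 <- cbind(r0, c0); i10 <- cbind(pmin(r0 + 1L, nr), c0)
  i01 <- cbind(r0, pmin(c0 + 1L, nc)); i11 <- cbind(pmin(r0 + 1L, nr), pmin(c0 + 1L, nc))
  m[i00] * (1 - fr) * (1 - fc) + m[i10] * fr * (1 - fc) +
    m[i01] * (1 - fr) * fc + m[i11] * fr * fc
}

# Robust background threshold: median + k * MAD (MAD scaled to sigma).
mad_threshold <- function(x, k) {
  stats::median(x) + k * stats::mad(x)
}
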