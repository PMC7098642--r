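# Grayscale images and edge maps.
#
# Images are plain numeric matrices indexed [row, col].  Whenever an (x, y)
# pair crosses an interface, x is the 0-based column index, y the 0-based row
# index, and pixel centers sit at integer coordinates, so the pixel at matrix
# position [r, c] has center (x, y) = (c - 1, r - 1).

#' Validate and normalize a grayscale image
#'
#' Coerces a numeric matrix to the internal grayscale convention: at least
#' 8x8, finite, and (optionally) min-max normalized to the unit interval by
#' `(I - min) / (max - min)` when the image is not constant.
#'
#' @param data Numeric matrix, at least 8x8.
#' @param normalize Rescale to `[0, 1]`? Default `TRUE`.
#' @return A numeric matrix with values in `[0, 1]` when `normalize = TRUE`.
#' @examples
#' img <- as_gray_image(matrix(runif(100), 10, 10))
#' range(img)
#' @export
as_gray_image <- function(data, normalize = TRUE) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix", call. = FALSE)
  if (nrow(data) < 8L || ncol(data) < 8L)
    stop("image must be at least 8x8 (got ", nrow(data), "x", ncol(data), ")",
         call. = FALSE)
  if (!all(is.finite(data)))
    stop("image contains non-finite values", call. = FALSE)
  if (normalize) {
    rng <- range(data)
    if (rng[2] > rng[1]) data <- (data - rng[1]) / (rng[2] - rng[1])
  }
  data
}

# Shift a matrix by (dr, dc) with replicate (Neumann) boundary handling:
# out[r, c] = m[clamp(r + dr), clamp(c + dc)].
shift_replicate <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(seq_len(H) + dr, 1L), H)
  ci <- pmin(pmax(seq_len(W) + dc, 1L), W)
  m[ri, ci, drop = FALSE]
}

# Shift a matrix by (dr, dc) with zero padding outside the domain.
shift_zero <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  rs <- max(1L, 1L + dr):min(H, H + dr)
  cs <- max(1L, 1L + dc):min(W, W + dc)
  if (length(rs) > 0L && length(cs) > 0L)
    out[rs - dr, cs - dc] <- m[rs, cs]
  out
}

#' Gaussian smoothing of an image
#'
#' Separable Gaussian convolution with replicate boundary handling.  The
#' discrete kernel is a normalized sampled Gaussian truncated at
#' `ceiling(3 * sigma)`.  `sigma = 0` returns the input unchanged.
#'
#' @param image Numeric matrix.
#' @param sigma Standard deviation in pixels, `>= 0`.
#' @return Smoothed matrix, same shape.
#' @export
gaussian_smooth <- function(image, sigma) {
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (sigma == 0) return(image)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  tmp <- matrix(0, nrow(image), ncol(image))
  for (i in seq_along(w)) tmp <- tmp + w[i] * shift_replicate(image, 0L, i - r - 1L)
  out <- matrix(0, nrow(image), ncol(image))
  for (i in seq_along(w)) out <- out + w[i] * shift_replicate(tmp, i - r - 1L, 0L)
  out
}

# Central-difference gradient with replicate boundaries; returns list(fx, fy)
# where fx differentiates along x (columns) and fy along y (rows).
image_gradient <- function(m) {
  fx <- (shift_replicate(m, 0L, 1L) - shift_replicate(m, 0L, -1L)) / 2
  fy <- (shift_replicate(m, 1L, 0L) - shift_replicate(m, -1L, 0L)) / 2
  list(fx = fx, fy = fy)
}

#' Compute an edge map
#'
#' The edge map `f` is the nonnegative scalar image whose values act as the
#' "charge" driving every force model.  The default is the gradient-of-
#' Gaussian magnitude `|grad(G_sigma * I)|` with central differences on the
#' smoothed image; `mode = "identity"` passes the image through unchanged,
#' which is appropriate for binary line drawings that are already edge-like.
#'
#' @param image Numeric matrix (a grayscale image).
#' @param sigma Gaussian scale in pixels, `>= 0`.  Default 1.
#' @param mode `"gradient"` (default) or `"identity"`.
#' @return Nonnegative numeric matrix of the same shape, with attribute
#'   `"sigma"` recording the scale used.
#' @examples
#' img <- as_gray_image(matrix(rep(c(0, 1), each = 50), 10, 10))
#' f <- compute_edge_map(img, sigma = 1)
#' @export
compute_edge_map <- function(image, sigma = 1, mode = c("gradient", "identity")) {
  mode <- match.arg(mode)
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (mode == "identity") {
    if (any(image < 0)) stop("identity mode requires a nonnegative image", call. = FALSE)
    f <- image
  } else {
    g <- image_gradient(gaussian_smooth(image, sigma))
    f <- sqrt(g$fx^2 + g$fy^2)
  }
  attr(f, "sigma") <- sigma
  f
}

## ---- plain-text raster / table I/O -------------------------------------

#' Read and write plain PGM images
#'
#' Minimal portable graymap support (ASCII `P2` and binary `P5`, 8- or
#' 16-bit).  `write_pgm` always writes ASCII `P2` so that artifacts stay
#' text-only; intensities in `[0, 1]` are scaled by `maxval` and rounded.
#'
#' @param path File path.
#' @param image Numeric matrix with values in `[0, 1]`.
#' @param maxval Maximum gray value written (default 255).
#' @return `read_pgm` returns a numeric matrix in `[0, 1]`;
#'   `write_pgm` returns `path` invisibly.
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path, call. = FALSE)
  head <- integer(0)
  buf <- character(0)
  # token scanner skipping whitespace and '#' comments
  while (length(head) < 3L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("truncated PGM header", call. = FALSE)
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
    } else if (grepl("[0-9]", ch)) {
      buf <- c(buf, ch)
    } else if (length(buf) > 0L) {
      head <- c(head, as.integer(paste(buf, collapse = "")))
      buf <- character(0)
    }
  }
  W <- head[1]; H <- head[2]; maxval <- head[3]
  n <- W * H
  if (magic == "P2") {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE, comment.char = "#")
  } else {
    bytes <- if (maxval < 256L) 1L else 2L
    vals <- readBin(con, "integer", n = n, size = bytes, signed = FALSE,
                    endian = "big")
  }
  matrix(vals / maxval, nrow = H, ncol = W, byrow = TRUE)
}

#' @rdname read_pgm
#' @export
write_pgm <- function(image, path, maxval = 255L) {
  vals <- round(pmin(pmax(image, 0), 1) * maxval)
  lines <- apply(matrix(as.integer(vals), nrow(image), ncol(image)), 1L,
                 paste, collapse = " ")
  writeLines(c("P2", paste(ncol(image), nrow(image)), as.character(maxval),
               lines), path)
  invisible(path)
}

#' Read and write contours as CSV
#'
#' Contours are ordered closed polylines of subpixel `(x, y)` points stored
#' as a two-column matrix; the closing edge (last point back to the first) is
#' implicit.  Files carry the header `x,y`.
#'
#' @param contour Two-column numeric matrix of `(x, y)` points.
#' @param path File path.
#' @return `read_contour_csv` returns the contour matrix; `write_contour_csv`
#'   returns `path` invisibly.
#' @export
write_contour_csv <- function(contour, path) {
  utils::write.csv(data.frame(x = contour[, 1], y = contour[, 2]), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_contour_csv
#' @export
read_contour_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(d)))
    stop("contour CSV must have columns `x` and `y`", call. = FALSE)
  cbind(x = d$x, y = d$y)
}

#' Serialize a vector field as CSV
#'
#' Long-format dump with columns `x`, `y`, `u`, `v` (0-based pixel-center
#' coordinates, row-major order).
#'
#' @param field A `vector_field`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(field, path) {
  H <- nrow(field$u); W <- ncol(field$u)
  d <- data.frame(x = rep(0:(W - 1L), each = H),
                  y = rep(0:(H - 1L), times = W),
                  u = as.vector(field$u), v = as.vector(field$v))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
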