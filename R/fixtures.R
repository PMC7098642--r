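# Synthetic benchmark fixtures with exact ground truth.
#
# Each generator returns a `snake_fixture`: the image, the exact binary
# ground-truth mask of the generating geometry, a documented initial
# contour, and a record of every geometry constant used.  The classic
# benchmark silhouettes (U-shape, E-shape, 3-shape) are integer-rectangle
# constructions so their pixel counts have closed forms; the motorbike- and
# person-like silhouettes are parametric stand-ins exercising the same
# failure mode (deep concavities).

new_fixture <- function(image, gt_mask, name, init_contour, params_used) {
  stopifnot(identical(dim(image), dim(gt_mask)))
  structure(list(image = image, gt_mask = gt_mask, name = name,
                 init_contour = init_contour, params_used = params_used),
            class = "snake_fixture")
}

#' @export
print.snake_fixture <- function(x, ...) {
  cat(sprintf("<snake_fixture '%s' %dx%d, |gt| = %d px, init %d pts>\n",
              x$name, nrow(x$image), ncol(x$image), sum(x$gt_mask),
              nrow(x$init_contour)))
  invisible(x)
}

# Pixel-center-in-circle mask (0-based center coordinates, radius inclusive).
disk_mask <- function(size, cx, cy, r) {
  X <- matrix(0:(size - 1L), size, size, byrow = TRUE)
  Y <- matrix(0:(size - 1L), size, size)
  (X - cx)^2 + (Y - cy)^2 <= r^2
}

# Inclusive integer pixel-range rectangle mask (0-based x0..x1, y0..y1).
rect_mask <- function(size, x0, x1, y0, y1) {
  m <- matrix(FALSE, size, size)
  m[(y0:y1) + 1L, (x0:x1) + 1L] <- TRUE
  m
}

# Default far circular initialization, centered on the image.
default_init <- function(size, radius_frac) {
  r <- radius_frac * size
  init_circle(c((size - 1) / 2, (size - 1) / 2), r,
              n_points = max(64L, as.integer(round(2 * pi * r))))
}

#' U-shape benchmark image
#'
#' A filled square with an axis-aligned rectangular notch cut from the top,
#' the classic deep-concavity test object.  Geometry (all 0-based inclusive
#' pixel ranges, derived from `size = N`): the square spans
#' `margin .. N - 1 - margin` with `margin = round(0.1 N)`, so the shape
#' nearly fills the frame as in the classic benchmark image; the notch is
#' `round(notch_fraction * N)` pixels wide, centered, and reaches down to
#' leave a bottom bar `round(0.5 N)` pixels tall (legs about `0.2 N` wide,
#' notch depth about `0.3 N`).  The notch depth is kept close to the default
#' kernel half-size `N/4`, so that everywhere inside the corridor the
#' convolution window still sees the notch bottom: kernels have finite
#' support, and a corridor much deeper than the kernel reach has a stall
#' band that no force of this family can cross.
#' The image is binary with values `{bg, fg}` and the ground truth is the U
#' region itself.
#'
#' The default initial contour is a centered circle of radius `0.45 N`: a
#' far initialization that clears the notch mouth and crosses the shape only
#' near its corners (snakes are insensitive to initializations crossing the
#' boundary).
#'
#' @param size Image side `N >= 32`.
#' @param notch_fraction Notch width as a fraction of `N` (0 gives a solid
#'   square).
#' @param fg,bg Foreground/background intensities in `[0, 1]`.
#' @return A `snake_fixture`.
#' @examples
#' fx <- make_ushape(64)
#' sum(fx$gt_mask)
#' @export
make_ushape <- function(size = 64L, notch_fraction = 0.4, fg = 1, bg = 0) {
  size <- as.integer(size)
  if (size < 32L) stop("`size` must be >= 32", call. = FALSE)
  margin <- as.integer(round(0.1 * size))
  lo <- margin; hi <- size - 1L - margin
  side <- hi - lo + 1L
  w <- as.integer(round(notch_fraction * size))
  bar <- as.integer(round(0.5 * size))
  if (w > side || (w > 0L && bar >= side))
    stop("notch larger than the square", call. = FALSE)
  mask <- rect_mask(size, lo, hi, lo, hi)
  if (w > 0L) {
    n0 <- as.integer(round((size - w) / 2))
    mask <- mask & !rect_mask(size, n0, n0 + w - 1L, lo, hi - bar)
  }
  img <- ifelse(mask, fg, bg)
  new_fixture(img, mask, "ushape", default_init(size, 0.45),
              list(size = size, notch_fraction = notch_fraction, fg = fg,
                   bg = bg, margin = margin, side = side, notch_width = w,
                   bar_height = bar, init_radius_frac = 0.45))
}

#' Deep-concavity silhouettes
#'
#' Binary silhouettes with deep concave bays.  `eshape` is a blocky letter E:
#' three horizontal bars joined by a full-height spine on the left, with two
#' bays opening right; `threeshape` is the mirrored blocky digit 3 (spine on
#' the right, bays opening left).  `motorbike_like` and `person_like` are
#' parametric primitive-union silhouettes with at least two concave inlets,
#' standing in for freehand shapes that are not reproducible exactly.
#'
#' Glyph geometry: the bounding box spans rows `0.1 N .. 0.9 N` and is
#' `round(0.45 N)` wide (centered); bars and spine are `round(0.16 N)`
#' thick, so each bay is about `0.17 N` tall and `0.28 N` deep -- deeper
#' than half the glyph width (a genuinely deep concavity) yet within the
#' reach of the default `N/4` convolution kernel, so a snake at the bay
#' mouth can see the bay's end wall.
#'
#' @param kind One of `"eshape"`, `"threeshape"`, `"motorbike_like"`,
#'   `"person_like"`.
#' @param size Image side `N >= 64`.
#' @param fg,bg Foreground/background intensities.
#' @return A `snake_fixture`.
#' @export
make_concave_shape <- function(kind = c("eshape", "threeshape",
                                        "motorbike_like", "person_like"),
                               size = 64L, fg = 1, bg = 0) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  if (size < 64L) stop("`size` must be >= 64", call. = FALSE)
  margin <- as.integer(round(0.1 * size))
  lo <- margin; hi <- size - 1L - margin
  side <- hi - lo + 1L
  th <- max(3L, as.integer(round(0.16 * size)))
  if (kind %in% c("eshape", "threeshape")) {
    gw <- as.integer(round(0.45 * size))             # glyph width
    c0 <- as.integer(round((size - gw) / 2)); c1 <- c0 + gw - 1L
    mid0 <- lo + (side - th) %/% 2L
    bars <- rect_mask(size, c0, c1, lo, lo + th - 1L) |
            rect_mask(size, c0, c1, mid0, mid0 + th - 1L) |
            rect_mask(size, c0, c1, hi - th + 1L, hi)
    spine <- if (kind == "eshape")
      rect_mask(size, c0, c0 + th - 1L, lo, hi)
    else
      rect_mask(size, c1 - th + 1L, c1, lo, hi)
    mask <- bars | spine
  } else if (kind == "motorbike_like") {
    wr <- 0.11 * size
    mask <- disk_mask(size, 0.30 * size, 0.66 * size, wr) |
            disk_mask(size, 0.70 * size, 0.66 * size, wr) |
            rect_mask(size, round(0.22 * size), round(0.78 * size),
                      round(0.48 * size), round(0.58 * size)) |
            rect_mask(size, round(0.28 * size), round(0.36 * size),
                      round(0.30 * size), round(0.48 * size)) |
            rect_mask(size, round(0.62 * size), round(0.70 * size),
                      round(0.30 * size), round(0.48 * size))
  } else {
    mask <- disk_mask(size, 0.50 * size, 0.26 * size, 0.08 * size) |
            rect_mask(size, round(0.42 * size), round(0.58 * size),
                      round(0.32 * size), round(0.58 * size)) |
            rect_mask(size, round(0.28 * size), round(0.72 * size),
                      round(0.34 * size), round(0.41 * size)) |
            rect_mask(size, round(0.42 * size), round(0.47 * size),
                      round(0.58 * size), round(0.82 * size)) |
            rect_mask(size, round(0.53 * size), round(0.58 * size),
                      round(0.58 * size), round(0.82 * size))
  }
  img <- ifelse(mask, fg, bg)
  new_fixture(img, mask, kind, default_init(size, 0.45),
              list(kind = kind, size = size, fg = fg, bg = bg,
                   margin = margin, thickness = th,
                   init_radius_frac = 0.45))
}

#' Weak-edge benchmark scenes
#'
#' Scenes whose target boundary is deliberately fainter than nearby
#' distractors:
#' \describe{
#'   \item{`disk_with_boxes`}{a gray disk (intensity `weak_contrast`,
#'     radius `0.3 N`) on black, with two white boxes (intensity
#'     `strong_contrast`, side `0.12 N`) on the upper diagonals just outside
#'     the disk.  The default initial contour is a circle in the gap between
#'     the disk rim and the boxes: the boxes' strong edges lie just outside
#'     the initial contour and out-gradient the weak rim, so linear forces
#'     pull the snake outward onto them while the edge-stopping force stays
#'     on the rim.}
#'   \item{`crescent_circle`}{a bright crescent (disk minus a copy shifted
#'     right by `0.12 N`) whose completing circular arc is drawn as a faint
#'     1-pixel-radius ring at `weak_contrast`.}
#'   \item{`blurred_disk`}{a disk whose rim is Gaussian-blurred
#'     (`sigma = 0.03 N`), a stand-in for photographic low-contrast rims.
#'     This is the one fixture that is not piecewise constant.}
#' }
#' The ground truth is always the analytic disk/circle region
#' (pixel-center-in-circle, exact).
#'
#' @param kind One of `"disk_with_boxes"`, `"crescent_circle"`,
#'   `"blurred_disk"`.
#' @param size Image side `N >= 32`.
#' @param weak_contrast Target intensity/contrast, in `(0, strong_contrast)`.
#' @param strong_contrast Distractor intensity, in `(weak_contrast, 1]`.
#' @return A `snake_fixture`.
#' @export
make_weak_edge_scene <- function(kind = c("disk_with_boxes", "crescent_circle",
                                          "blurred_disk"),
                                 size = 64L, weak_contrast = 0.4,
                                 strong_contrast = 1) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  if (size < 32L) stop("`size` must be >= 32", call. = FALSE)
  if (!(weak_contrast > 0 && weak_contrast < strong_contrast &&
        strong_contrast <= 1))
    stop("require 0 < weak_contrast < strong_contrast <= 1", call. = FALSE)
  cx <- (size - 1) / 2; cy <- cx
  r <- 0.3 * size
  disk <- disk_mask(size, cx, cy, r)
  if (kind == "disk_with_boxes") {
    b <- as.integer(round(0.06 * size))          # box half-size
    rb <- r + 0.15 * size                        # box-center distance, on diagonals
    off <- rb / sqrt(2)
    boxes <- rect_mask(size, round(cx - off - b), round(cx - off + b),
                       round(cy - off - b), round(cy - off + b)) |
             rect_mask(size, round(cx + off - b), round(cx + off + b),
                       round(cy - off - b), round(cy - off + b))
    if (any(disk & boxes))
      stop("geometry overlap: boxes intersect the disk", call. = FALSE)
    img <- weak_contrast * disk
    img[boxes] <- strong_contrast
    # initialize between the rim and the boxes' inner corners
    init_frac <- ((r + rb - b * sqrt(2)) / 2) / size
    extra <- list(box_half = b, box_offset = rb)
  } else if (kind == "crescent_circle") {
    shifted <- disk_mask(size, cx + 0.12 * size, cy, r)
    crescent <- disk & !shifted
    X <- matrix(0:(size - 1L), size, size, byrow = TRUE)
    Y <- matrix(0:(size - 1L), size, size)
    ring <- abs(sqrt((X - cx)^2 + (Y - cy)^2) - r) <= 1
    img <- strong_contrast * crescent
    img[ring & !crescent] <- weak_contrast
    init_frac <- 0.42
    extra <- list(shift = 0.12 * size, ring_halfwidth = 1)
  } else {
    blur_sigma <- 0.03 * size
    img <- gaussian_smooth(strong_contrast * disk, blur_sigma)
    init_frac <- 0.42
    extra <- list(blur_sigma = blur_sigma)
  }
  new_fixture(img, disk, kind, default_init(size, init_frac),
              c(list(kind = kind, size = size, weak_contrast = weak_contrast,
                     strong_contrast = strong_contrast, disk_radius = r,
                     init_radius_frac = init_frac), extra))
}

#' Salt-and-pepper corruption
#'
#' Sets an exact `round(density * H * W)`-pixel subset, sampled uniformly
#' without replacement, to 0 or 1 with equal probability.  Deterministic
#' given `seed`; the caller's RNG state is left untouched.
#'
#' @param image Numeric matrix with values in `[0, 1]`.
#' @param density Fraction of pixels corrupted, in `[0, 0.5]`.
#' @param seed Integer seed.
#' @return The corrupted image.
#' @export
add_salt_pepper <- function(image, density, seed = 1L) {
  if (density < 0 || density > 0.5)
    stop("`density` must be in [0, 0.5]", call. = FALSE)
  if (density == 0) return(image)
  n <- as.integer(round(density * length(image)))
  if (n == 0L) return(image)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  idx <- sample.int(length(image), n)
  image[idx] <- as.numeric(stats::runif(n) < 0.5)
  image
}
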