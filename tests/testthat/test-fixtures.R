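test_that("ushape geometry: binary values and closed-form pixel counts", {
  fx <- make_ushape(64)
  expect_equal(sort(unique(as.vector(fx$image))), c(0, 1))
  p <- fx$params_used
  expect_equal(sum(fx$gt_mask),
               p$side^2 - p$notch_width * (p$side - p$bar_height))

  solid <- make_ushape(64, notch_fraction = 0)
  expect_equal(sum(solid$gt_mask), solid$params_used$side^2)

  big <- make_ushape(128, fg = 0.8, bg = 0.1)
  expect_equal(sort(unique(as.vector(big$image))), c(0.1, 0.8))
  expect_error(make_ushape(24), "size")
  expect_error(make_ushape(64, notch_fraction = 0.95), "notch")
})

test_that("eshape and threeshape have exactly two bays inside the glyph box", {
  # count connected components (4-connectivity) of the background restricted
  # to the glyph bounding box; flood fill written independently here
  bays <- function(mask) {
    rows <- range(which(rowSums(mask) > 0)); cols <- range(which(colSums(mask) > 0))
    bg <- !mask[rows[1]:rows[2], cols[1]:cols[2]]
    lab <- matrix(0L, nrow(bg), ncol(bg)); nl <- 0L
    for (r in seq_len(nrow(bg))) for (c in seq_len(ncol(bg))) {
      if (bg[r, c] && lab[r, c] == 0L) {
        nl <- nl + 1L
        stack <- list(c(r, c))
        while (length(stack)) {
          p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
          if (p[1] < 1 || p[2] < 1 || p[1] > nrow(bg) || p[2] > ncol(bg)) next
          if (!bg[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
          lab[p[1], p[2]] <- nl
          stack <- c(stack, list(p + c(1, 0), p - c(1, 0),
                                 p + c(0, 1), p - c(0, 1)))
        }
      }
    }
    nl
  }
  for (kind in c("eshape", "threeshape")) {
    fx <- make_concave_shape(kind, 64)
    expect_equal(sort(unique(as.vector(fx$image))), c(0, 1))
    expect_equal(bays(fx$gt_mask), 2L, label = kind)
  }
  # bay depth exceeds half the glyph width by construction
  fx <- make_concave_shape("eshape", 64)
  glyph_w <- diff(range(which(colSums(fx$gt_mask) > 0))) + 1
  bay_depth <- glyph_w - fx$params_used$thickness
  expect_gte(bay_depth / glyph_w, 0.5)
  expect_error(make_concave_shape("eshape", 48), "size")
  expect_error(make_concave_shape("blob", 64), "arg")
})

test_that("freehand-style silhouettes are valid binary fixtures with concavity", {
  for (kind in c("motorbike_like", "person_like")) {
    fx <- make_concave_shape(kind, 64)
    expect_equal(sort(unique(as.vector(fx$image))), c(0, 1))
    bb <- sum(fx$gt_mask) /
      (diff(range(which(rowSums(fx$gt_mask) > 0))) + 1) /
      (diff(range(which(colSums(fx$gt_mask) > 0))) + 1)
    expect_lt(bb, 0.75)   # well below its bounding box: concave inlets exist
  }
})

test_that("disk_with_boxes: exact disk ground truth and dominant box edges", {
  fx <- make_weak_edge_scene("disk_with_boxes", 64)
  p <- fx$params_used
  cx <- (p$size - 1) / 2
  X <- matrix(0:(p$size - 1), p$size, p$size, byrow = TRUE)
  Y <- matrix(0:(p$size - 1), p$size, p$size)
  expect_identical(fx$gt_mask, (X - cx)^2 + (Y - cx)^2 <= p$disk_radius^2)

  f <- compute_edge_map(fx$image, 1)
  rad <- sqrt((X - cx)^2 + (Y - cx)^2)
  on_disk_rim <- abs(rad - p$disk_radius) <= 1.5
  near_boxes <- fx$image == p$strong_contrast
  box_border <- (snakefields:::shift_zero(near_boxes, 1, 0) |
                 snakefields:::shift_zero(near_boxes, -1, 0) |
                 snakefields:::shift_zero(near_boxes, 0, 1) |
                 snakefields:::shift_zero(near_boxes, 0, -1)) & !near_boxes
  expect_gt(max(f[box_border]), max(f[on_disk_rim]))

  expect_error(make_weak_edge_scene("disk_with_boxes", 64,
                                    weak_contrast = 0.5, strong_contrast = 0.5),
               "weak_contrast")
})

test_that("crescent and blurred disk scenes have the stated structure", {
  cr <- make_weak_edge_scene("crescent_circle", 64)
  expect_equal(sort(unique(as.vector(cr$image))), c(0, 0.4, 1))
  bl <- make_weak_edge_scene("blurred_disk", 64)
  expect_gt(length(unique(as.vector(bl$image))), 4)    # genuinely graded rim
  expect_identical(dim(bl$image), dim(bl$gt_mask))
})

test_that("clean piecewise-constant fixtures have at most 4 intensity values", {
  names <- list(list(name = "ushape"), list(name = "eshape"),
                list(name = "threeshape"), list(name = "motorbike_like"),
                list(name = "person_like"), list(name = "disk_with_boxes"),
                list(name = "crescent_circle"))
  for (spec in names) {
    fx <- make_fixture(spec)
    expect_lte(length(unique(as.vector(fx$image))), 4)
  }
})

test_that("fixtures are bit-exact reproducible from their parameters", {
  a <- make_ushape(96, notch_fraction = 0.3)
  b <- do.call(make_ushape, a$params_used[c("size", "notch_fraction", "fg", "bg")])
  expect_identical(a$gt_mask, b$gt_mask)
  expect_identical(a$image, b$image)
  expect_identical(a$init_contour, b$init_contour)
})

test_that("add_salt_pepper: identity, exact count, determinism", {
  img <- matrix(0.5, 100, 100)
  expect_identical(add_salt_pepper(img, 0, 1), img)

  out <- add_salt_pepper(img, 0.1, 5)
  changed <- sum(out != img)
  expect_equal(changed, round(0.1 * 1e4))    # mid-gray: every hit is visible
  expect_true(all(out %in% c(0, 0.5, 1)))
  # corrupted count lies inside the binomial(1e4, 0.1) 99.9% interval
  expect_gt(changed, qbinom(5e-4, 1e4, 0.1) - 1)
  expect_lt(changed, qbinom(1 - 5e-4, 1e4, 0.1) + 1)

  expect_identical(add_salt_pepper(img, 0.2, 9), add_salt_pepper(img, 0.2, 9))
  expect_false(identical(add_salt_pepper(img, 0.2, 9),
                         add_salt_pepper(img, 0.2, 10)))
  expect_error(add_salt_pepper(img, 0.6, 1), "density")

  # caller RNG state is preserved
  set.seed(123); before <- .Random.seed
  invisible(add_salt_pepper(img, 0.1, 42))
  expect_identical(.Random.seed, before)
})
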