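test_that("vef: single charge attracts, zero map gives zero field", {
  f <- matrix(0, 16, 16)
  f[8, 8] <- 1                       # charge at (x, y) = (7, 7)
  E <- vef(f, t = 4)
  expect_equal(E$u[8, 9], -1)        # one pixel to the right: pulled left
  expect_equal(E$u[8, 7], 1)
  expect_equal(E$v[9, 8], -1)
  expect_equal(E$u[8, 8], 0)         # no self-force

  Z <- vef(matrix(0, 16, 16), t = 4)
  expect_equal(Z$u, matrix(0, 16, 16))
  expect_equal(Z$v, matrix(0, 16, 16))
})

test_that("vef: two-charge field equals the hand-summed kernel contributions", {
  f <- matrix(0, 9, 9)
  charges <- list(c(3, 4, 0.8), c(7, 6, 0.5))  # (x, y, strength), 0-based
  for (ch in charges) f[ch[2] + 1, ch[1] + 1] <- ch[3]
  E <- vef(f, t = 4)
  # hand sum at a probe pixel: F = sum_charges strength * (dx, dy) / d^3
  probe <- c(4, 2)
  eu <- ev <- 0
  for (ch in charges) {
    dx <- ch[1] - probe[1]; dy <- ch[2] - probe[2]
    if (abs(dx) <= 4 && abs(dy) <= 4) {
      d3 <- (dx^2 + dy^2)^1.5
      eu <- eu + ch[3] * dx / d3
      ev <- ev + ch[3] * dy / d3
    }
  }
  expect_equal(E$u[probe[2] + 1, probe[1] + 1], eu, tolerance = 1e-12)
  expect_equal(E$v[probe[2] + 1, probe[1] + 1], ev, tolerance = 1e-12)
})

test_that("vef is linear; mconvef is not", {
  f1 <- rand_map(12, 12, 4); f2 <- rand_map(12, 12, 5)
  a <- 1.7; b <- -0.6
  lin <- vef(a * f1 + b * f2, t = 3)
  sup <- vef(f1, t = 3)
  sup2 <- vef(f2, t = 3)
  expect_equal(lin$u, a * sup$u + b * sup2$u, tolerance = 1e-10)
  expect_equal(lin$v, a * sup$v + b * sup2$v, tolerance = 1e-10)

  m12 <- mconvef_direct(f1 + f2, t = 3, h = 0.5, k = 0.3)
  m1 <- mconvef_direct(f1, t = 3, h = 0.5, k = 0.3)
  m2 <- mconvef_direct(f2, t = 3, h = 0.5, k = 0.3)
  expect_gt(max_abs_diff(m12, list(u = m1$u + m2$u, v = m1$v + m2$v)), 1e-3)
})

test_that("convef: parameter reduction, softened delta case, monotone decay", {
  f <- rand_map(16, 16, 6)
  expect_identical(convef(f, t = 4, h = 0, n = 1), vef(f, t = 4))

  fd <- matrix(0, 16, 16); fd[8, 8] <- 1
  Eh <- convef(fd, t = 4, h = 1, n = 1)
  expect_equal(Eh$u[8, 9], -1 / 2^1.5, tolerance = 1e-12)  # d_h^2 = 1 + 1

  # increasing n strictly weakens the pull at offsets with x^2+y^2+h > 1
  mags <- sapply(1:4, function(n) abs(convef(fd, t = 4, h = 0, n = n)$u[8, 11]))
  expect_true(all(diff(mags) < 0))
})

test_that("edge_stop matches its closed form", {
  expect_equal(edge_stop(0, 5), 1)
  expect_equal(edge_stop(0.5, 0.5), 0.5)
  expect_equal(edge_stop(-0.5, 0.5), 0.5)          # even
  expect_equal(edge_stop(0.3, 100), 1 / (1 + 9e-6))
  expect_error(edge_stop(1, 0), "contrast")
})

test_that("interpolation_weight is a hat function and partitions unity", {
  expect_equal(interpolation_weight(0.4, 0.4, 0.2), 1)
  expect_equal(interpolation_weight(0.4, 0.1, 0.2), 0)
  expect_equal(interpolation_weight(0.5, 0.4, 0.2), 0.5)
  expect_error(interpolation_weight(0.5, 0.4, 0), "deltaf")

  set.seed(8)
  levels <- seq(0, 1, length.out = 6)
  deltaf <- levels[2] - levels[1]
  for (v in runif(25)) {
    expect_equal(sum(interpolation_weight(v, levels, deltaf)), 1,
                 tolerance = 1e-12)
  }
})

test_that("mconvef_direct agrees with an independent triple-loop oracle", {
  f <- leveled_map(8, 8, 2, 9) * 0.6
  d <- mconvef_direct(f, t = 3, h = 0.4, k = 0.25)
  o <- mconvef_loop_oracle(f, t = 3, h = 0.4, k = 0.25)
  expect_equal(d$u, o$u, tolerance = 1e-12)
  expect_equal(d$v, o$v, tolerance = 1e-12)
})

test_that("mconvef_direct collapses to convef when g is constant", {
  # constant edge map: all differences are zero, g = 1 exactly
  fc <- matrix(0.5, 12, 12)
  expect_equal(max_abs_diff(mconvef_direct(fc, t = 3, h = 0.8, k = 0.1),
                            convef(fc, t = 3, h = 0.8, n = 1)), 0,
               tolerance = 1e-12)
  # enormous contrast: g -> 1 within 1e-6
  f <- rand_map(12, 12, 10)
  expect_lt(max_abs_diff(mconvef_direct(f, t = 3, h = 0.8, k = 1e6),
                         convef(f, t = 3, h = 0.8, n = 1)), 1e-6)
})

test_that("mconvef matches the exact sum on level-resolved maps", {
  fb <- leveled_map(16, 16, 2, 11) * 0.7     # binary map, L = 2
  expect_lt(max_abs_diff(mconvef(fb, t = 4, h = 0.5, k = 0.3, L = 2),
                         mconvef_direct(fb, t = 4, h = 0.5, k = 0.3)), 1e-8)

  f8 <- leveled_map(16, 16, 8, 12)           # 8 equispaced values, L = 8
  expect_lt(max_abs_diff(mconvef(f8, t = 4, h = 0, k = 0.4, L = 8),
                         mconvef_direct(f8, t = 4, h = 0, k = 0.4)), 1e-8)
})

test_that("mconvef approximation error is monotone non-increasing in L", {
  f <- leveled_map(16, 16, 6, 13)
  exact <- mconvef_direct(f, t = 4, h = 0.3, k = 0.35)
  errs <- sapply(2:6, function(L)
    max_abs_diff(mconvef(f, t = 4, h = 0.3, k = 0.35, L = L), exact))
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[length(errs)], 1e-8)        # L = number of distinct values
})

test_that("mconvef limits and degenerate input", {
  f <- rand_map(16, 16, 14)
  for (L in c(2, 5)) {
    expect_lt(max_abs_diff(mconvef(f, t = 4, h = 0.9, k = 1e6, L = L),
                           convef(f, t = 4, h = 0.9, n = 1)), 1e-6)
  }
  fc <- matrix(0.4, 12, 12)
  expect_warning(mc <- mconvef(fc, t = 3, h = 0.2, k = 0.5, L = 2),
                 "constant edge map")
  expect_equal(mc, convef(fc, t = 3, h = 0.2, n = 1))
  expect_error(mconvef(f, t = 4, L = 1), "L")
  expect_error(mconvef(f, t = 4, k = 0), "contrast")
})

test_that("left-right mirroring negates and mirrors u, mirrors v (all models)", {
  f <- rand_map(16, 16, 15)
  mir <- function(m) m[, rev(seq_len(ncol(m)))]
  fields <- list(
    vef = function(x) vef(x, t = 4),
    convef = function(x) convef(x, t = 4, h = 0.8, n = 2),
    mconvef = function(x) mconvef(x, t = 4, h = 0.3, k = 0.4, L = 4),
    gvf = function(x) gvf(x, mu = 0.2, n_iter = 30)
  )
  for (nm in names(fields)) {
    E <- fields[[nm]](f)
    Em <- fields[[nm]](mir(f))
    expect_equal(Em$u, -mir(E$u), tolerance = 1e-10, label = nm)
    expect_equal(Em$v, mir(E$v), tolerance = 1e-10, label = nm)
  }
})

test_that("normalize_field produces unit-capped vectors and keeps zeros", {
  u <- matrix(3, 2, 2); u[2, 2] <- 0
  v <- matrix(4, 2, 2); v[2, 2] <- 0
  N <- normalize_field(vector_field(u, v))
  expect_equal(N$u[1, 1], 0.6)
  expect_equal(N$v[1, 1], 0.8)
  expect_equal(N$u[2, 2], 0)
  expect_true(N$normalized)

  E <- normalize_field(vef(rand_map(12, 12, 16), t = 3))
  expect_true(all(sqrt(E$u^2 + E$v^2) <= 1 + 1e-9))
  expect_error(normalize_field(E, eps = 0), "eps")
})
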