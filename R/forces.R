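# External force fields for parametric snakes.
#
# All fields follow the attractive convolution orientation: the field sampled
# at (x0, y0) from a charge at (x, y) points from (x0, y0) toward (x, y), so
# a snake outside an object is pulled in toward its edges.

#' Construct a vector field
#'
#' A vector field is a pair of equally shaped matrices `u` (x-component) and
#' `v` (y-component) sampled on the pixel grid, plus a flag recording whether
#' it has been normalized to unit vectors.
#'
#' @param u,v Numeric matrices of identical shape.
#' @param normalized Logical flag.
#' @return List of class `vector_field`.
#' @export
vector_field <- function(u, v, normalized = FALSE) {
  if (!identical(dim(u), dim(v)))
    stop("`u` and `v` must share one shape", call. = FALSE)
  structure(list(u = u, v = v, normalized = normalized),
            class = "vector_field")
}

#' @export
print.vector_field <- function(x, ...) {
  mag <- sqrt(x$u^2 + x$v^2)
  cat(sprintf("<vector_field %dx%d%s, max |F| = %.4g>\n",
              nrow(x$u), ncol(x$u),
              if (isTRUE(x$normalized)) " (normalized)" else "", max(mag)))
  invisible(x)
}

#' Edge-stopping weight
#'
#' The Perona-Malik style rational edge-stopping function
#' \deqn{g_k(\delta) = \frac{1}{1 + (\delta / k)^2},}
#' even in `delta`, equal to 1 at `delta = 0` and decaying toward 0 for
#' differences much larger than the contrast `k`.  In the MCONVEF field it
#' down-weights charges whose edge-map value differs strongly from the value
#' at the evaluation pixel, so strong edges do not drown out weak ones.
#'
#' @param delta Intensity difference(s); any numeric array.
#' @param k Contrast parameter, `> 0`.
#' @return Weights in `(0, 1]`, same shape as `delta`.
#' @examples
#' edge_stop(0, 1)       # 1
#' edge_stop(0.5, 0.5)   # 0.5
#' @export
edge_stop <- function(delta, k) {
  if (k <= 0) stop("contrast `k` must be > 0", call. = FALSE)
  1 / (1 + (delta / k)^2)
}

#' Hat-function interpolation weight across intensity levels
#'
#' Linear (tent) weight `max(0, 1 - |f_value - level_j| / deltaf)` used to
#' blend the per-level fields of the piecewise-constant MCONVEF algorithm.
#' For equispaced levels with spacing `deltaf`, the weights of any value
#' inside the level range sum to exactly 1 (partition of unity), which is
#' what makes the blend a linear interpolation between the two bracketing
#' levels.
#'
#' @param f_value Intensity value(s).
#' @param level_j Sampled level.
#' @param deltaf Level spacing, `> 0`.
#' @return Weight(s) in `[0, 1]`.
#' @export
interpolation_weight <- function(f_value, level_j, deltaf) {
  if (deltaf <= 0) stop("`deltaf` must be > 0", call. = FALSE)
  pmax(0, 1 - abs(f_value - level_j) / deltaf)
}

#' Virtual electric field family (VEF / CONVEF)
#'
#' `convef` computes the convolutional virtual electric field
#' \eqn{(k_x \otimes f, k_y \otimes f)} with the kernel of [build_kernel()]:
#' every pixel acts as a charge proportional to the edge map `f`, the kernel
#' encodes the (softened, exponent-`n`) attraction law, and the two linear
#' convolutions are evaluated by FFT.  `vef` is the special case `h = 0,
#' n = 1` (inverse-square law) and runs on the identical code path.
#'
#' @param f Edge map (nonnegative numeric matrix).
#' @param t Kernel half-size in pixels; default `floor(N/4)` for an
#'   `N = min(H, W)` image, giving a kernel of about half the image size.
#' @param h Softening scale, `>= 0`; larger values smooth the field and
#'   improve noise robustness.
#' @param n Decay exponent, `>= 1`.
#' @return A `vector_field`.
#' @examples
#' f <- matrix(0, 16, 16); f[8, 8] <- 1
#' E <- vef(f, t = 4)
#' @export
convef <- function(f, t = default_half_size(f), h = 0, n = 1) {
  kern <- build_kernel(t, h, n)
  plan <- conv_plan(kern, nrow(f), ncol(f))
  Fhat <- stats::fft(pad_to(f, plan$P, plan$Q))
  vector_field(conv_apply(plan$Kx, Fhat, plan, nrow(f), ncol(f)),
               conv_apply(plan$Ky, Fhat, plan, nrow(f), ncol(f)))
}

#' @rdname convef
#' @export
vef <- function(f, t = default_half_size(f)) convef(f, t = t, h = 0, n = 1)

#' Default kernel half-size for an image
#'
#' `floor(min(H, W) / 4)`, so the kernel spans about half the image in each
#' direction.
#'
#' @param f Matrix whose shape sets the size.
#' @return Integer half-size, at least 1.
#' @export
default_half_size <- function(f) max(1L, min(nrow(f), ncol(f)) %/% 4L)

#' Modified CONVEF field, exact double-sum evaluation
#'
#' The MCONVEF field weights each charge by the edge-stopping function of
#' the *nonlocal* difference between the charge's edge-map value and the
#' value at the evaluation pixel:
#' \deqn{E(x_0, y_0) = \sum_{(x,y) \in D}
#'   \frac{(x - x_0, \; y - y_0)}{d_h^3} \;
#'   g_k\big(f(x, y) - f(x_0, y_0)\big) \, f(x, y),}
#' over the `(2t+1) x (2t+1)` window `D`, with
#' \eqn{d_h = \sqrt{(x-x_0)^2 + (y-y_0)^2 + h}}.  This routine evaluates the
#' sum exactly (no intensity-level sampling) and serves as the oracle for
#' the fast approximation in [mconvef()]; cost is `O(H W t^2)`.
#'
#' Charges outside the image contribute zero, consistent with the
#' zero-padded convolutions of the fast path.
#'
#' @inheritParams convef
#' @param k Edge-stopping contrast, `> 0`.
#' @return A `vector_field`.
#' @export
mconvef_direct <- function(f, t = default_half_size(f), h = 0, k = 1) {
  if (t < 1) stop("kernel half-size `t` must be >= 1", call. = FALSE)
  if (h < 0) stop("softening `h` must be >= 0", call. = FALSE)
  if (k <= 0) stop("contrast `k` must be > 0", call. = FALSE)
  u <- v <- matrix(0, nrow(f), ncol(f))
  for (dy in -t:t) {
    for (dx in -t:t) {
      if (dx == 0L && dy == 0L) next  # a pixel exerts no force on itself
      dh3 <- (dx^2 + dy^2 + h)^1.5
      fs <- shift_zero(f, dy, dx)     # charge value at (x0 + dx, y0 + dy)
      contrib <- edge_stop(fs - f, k) * fs / dh3
      u <- u + dx * contrib
      v <- v + dy * contrib
    }
  }
  vector_field(u, v)
}

#' Modified CONVEF field via piecewise-constant approximation
#'
#' Fast evaluation of the nonlinear field of [mconvef_direct()].  The edge
#' map's intensity range is sampled at `L` equispaced levels
#' `f_j = minf + j (maxf - minf) / (L - 1)`, `j = 0, ..., L - 1`.  At each
#' level the edge-stopping weight is frozen at `g_k(f - f_j)`, which makes
#' the per-level field a pair of *linear* FFT convolutions of
#' `H_j = g_k(f - f_j) * f`; the final field blends the per-level fields
#' pixelwise with the hat weights of [interpolation_weight()], i.e. linear
#' interpolation between the two levels bracketing each pixel's value.
#'
#' When `f` takes at most `L` distinct values that all lie exactly on the
#' sampled levels (e.g. a binary map with `L = 2`) the approximation is
#' exact up to FFT round-off.  Cost is `L` FFT convolutions, so roughly `L`
#' times the cost of [vef()].
#'
#' For `k` much larger than the intensity range, `g_k` is essentially 1 and
#' the field reduces to [convef()] with `n = 1`.
#'
#' @inheritParams mconvef_direct
#' @param L Number of intensity levels, integer `>= 2`.
#' @return A `vector_field`.
#' @examples
#' f <- matrix(0, 32, 32); f[8:24, 8:24] <- 1
#' E  <- mconvef(f, t = 8, h = 0, k = 0.5, L = 2)
#' E0 <- mconvef_direct(f, t = 8, h = 0, k = 0.5)
#' max(abs(E$u - E0$u))  # ~1e-14: exact on a binary map
#' @export
mconvef <- function(f, t = default_half_size(f), h = 0, k = 1, L = 2) {
  if (k <= 0) stop("contrast `k` must be > 0", call. = FALSE)
  if (L < 2) stop("`L` must be an integer >= 2", call. = FALSE)
  minf <- min(f); maxf <- max(f)
  if (maxf == minf) {
    warning("constant edge map: intensity levels collapse; returning CONVEF",
            call. = FALSE)
    return(convef(f, t = t, h = h, n = 1))
  }
  L <- as.integer(L)
  deltaf <- (maxf - minf) / (L - 1)
  kern <- build_kernel(t, h, 1)
  plan <- conv_plan(kern, nrow(f), ncol(f))
  u <- v <- matrix(0, nrow(f), ncol(f))
  for (j in 0:(L - 1L)) {
    fj <- minf + j * deltaf
    Hj <- edge_stop(f - fj, k) * f
    Fhat <- stats::fft(pad_to(Hj, plan$P, plan$Q))
    w <- interpolation_weight(f, fj, deltaf)
    u <- u + conv_apply(plan$Kx, Fhat, plan, nrow(f), ncol(f)) * w
    v <- v + conv_apply(plan$Ky, Fhat, plan, nrow(f), ncol(f)) * w
  }
  vector_field(u, v)
}

#' Gradient vector flow field
#'
#' Diffuses the edge-map gradient over the whole image by explicit Euler
#' iteration of the decoupled reaction-diffusion equations
#' \deqn{u_t = \mu \nabla^2 u - |\nabla f|^2 (u - f_x), \qquad
#'       v_t = \mu \nabla^2 v - |\nabla f|^2 (v - f_y),}
#' initialized at `(u, v) = grad(f)`, with a 5-point Laplacian and replicate
#' (Neumann) boundaries.  Near strong edges the data term pins the field to
#' `grad(f)`; elsewhere diffusion extends the capture range.
#'
#' @param f Edge map (nonnegative numeric matrix).
#' @param mu Regularization weight, `> 0`; larger values smooth more.
#' @param n_iter Number of explicit steps; default `min(H, W)`.
#' @param dt Time step.  The pure-diffusion bound is `dt <= 1/(4 mu)`, and
#'   steps beyond it are rejected; the reaction (data) term tightens the
#'   true von Neumann / energy-descent bound to
#'   `dt <= 2 / (8 mu + max |grad f|^2)`, which is what the default uses --
#'   at the looser diffusion-only bound the discrete energy grows slowly
#'   through the Nyquist mode wherever `|grad f|` is large.
#' @return A `vector_field`.
#' @export
gvf <- function(f, mu = 0.2, n_iter = min(dim(f)), dt = NULL) {
  if (mu <= 0) stop("`mu` must be > 0", call. = FALSE)
  g <- image_gradient(f)
  b <- g$fx^2 + g$fy^2
  if (is.null(dt)) dt <- 2 / (8 * mu + max(b))
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  if (dt > 1 / (4 * mu) + 1e-12)
    stop("unstable time step: require dt <= 1/(4*mu) = ", 1 / (4 * mu),
         call. = FALSE)
  u <- g$fx
  v <- g$fy
  lap <- function(m)
    shift_replicate(m, 1L, 0L) + shift_replicate(m, -1L, 0L) +
    shift_replicate(m, 0L, 1L) + shift_replicate(m, 0L, -1L) - 4 * m
  for (i in seq_len(n_iter)) {
    u <- u + dt * (mu * lap(u) - b * (u - g$fx))
    v <- v + dt * (mu * lap(v) - b * (v - g$fy))
  }
  vector_field(u, v)
}

#' Normalize a vector field to unit vectors
#'
#' Divides each vector by `max(|F|, eps)`, so true zero vectors stay zero
#' and every magnitude is at most 1.  Normalization is the customary
#' preprocessing before snake evolution when comparing force models under
#' one snake parameterization; field-level comparisons should use the raw
#' fields.
#'
#' @param field A `vector_field`.
#' @param eps Magnitude floor, `> 0`; default `1e-10`.
#' @return A `vector_field` with the `normalized` flag set.
#' @export
normalize_field <- function(field, eps = 1e-10) {
  if (eps <= 0) stop("`eps` must be > 0", call. = FALSE)
  mag <- sqrt(field$u^2 + field$v^2)
  s <- 1 / pmax(mag, eps)
  vector_field(field$u * s, field$v * s, normalized = TRUE)
}
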