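# Convolution kernels for the virtual-electric-field family and the linear
# (zero-padded) "same" convolution used to apply them.

#' Build a virtual-electric-field convolution kernel
#'
#' Constructs the pair of kernel components on the grid
#' `x, y in [-t, t]`:
#' \deqn{k_x(x, y) = -x / d_h^{n+2}, \quad k_y(x, y) = -y / d_h^{n+2},}
#' with softened distance \eqn{d_h = \sqrt{x^2 + y^2 + h}}.  `h = 0, n = 1`
#' gives the classic inverse-square electric-field kernel.  The center is set
#' to `(0, 0)`: a pixel exerts no force on itself (and the `h = 0` center is
#' singular).
#'
#' Matrices are indexed `[y + t + 1, x + t + 1]`, i.e. rows are y, columns x.
#'
#' @param t Kernel half-size in pixels, integer `>= 1`.
#' @param h Softening scale added inside the squared distance, `>= 0`.
#' @param n Decay exponent, `>= 1`; larger `n` decays faster with distance.
#' @return List of class `conv_kernel` with components `kx`, `ky`
#'   (`(2t+1) x (2t+1)` matrices) and the parameters `t`, `h`, `n`.
#' @examples
#' k <- build_kernel(t = 3, h = 0, n = 1)
#' k$kx[3 + 1 + 0, 3 + 1 + 1]  # kx at (x = 1, y = 0) is -1
#' @export
build_kernel <- function(t, h = 0, n = 1) {
  if (t < 1) stop("kernel half-size `t` must be >= 1", call. = FALSE)
  if (h < 0) stop("softening `h` must be >= 0", call. = FALSE)
  if (n < 1) stop("decay exponent `n` must be >= 1", call. = FALSE)
  t <- as.integer(t)
  off <- -t:t
  X <- matrix(off, 2L * t + 1L, 2L * t + 1L, byrow = TRUE)  # x varies by column
  Y <- matrix(off, 2L * t + 1L, 2L * t + 1L)                # y varies by row
  dh_pow <- (X^2 + Y^2 + h)^((n + 2) / 2)
  ctr <- t + 1L
  dh_pow[ctr, ctr] <- 1  # avoid 0/0 at the (zeroed) center when h = 0
  kx <- -X / dh_pow
  ky <- -Y / dh_pow
  kx[ctr, ctr] <- 0
  ky[ctr, ctr] <- 0
  structure(list(kx = kx, ky = ky, t = t, h = h, n = n),
            class = "conv_kernel")
}

# Zero-pad a matrix into the top-left corner of a P x Q matrix.
pad_to <- function(m, P, Q) {
  out <- matrix(0, P, Q)
  out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  out
}

# FFT-friendly size (factors 2, 3, 5) at least n.
fast_len <- function(n) stats::nextn(n, factors = c(2L, 3L, 5L))

# Precompute the FFT plan for convolving kernels of size kh x kw with fields
# of size H x W: padded sizes and the transformed kernel components.
conv_plan <- function(kernel, H, W) {
  kh <- nrow(kernel$kx); kw <- ncol(kernel$kx)
  P <- fast_len(H + kh - 1L)
  Q <- fast_len(W + kw - 1L)
  list(P = P, Q = Q, t = kernel$t,
       Kx = stats::fft(pad_to(kernel$kx, P, Q)),
       Ky = stats::fft(pad_to(kernel$ky, P, Q)))
}

# Apply one precomputed transformed kernel to the FFT of a padded field and
# crop to "same" (kernel center aligned with each output pixel).
conv_apply <- function(Khat, Fhat, plan, H, W) {
  full <- Re(stats::fft(Khat * Fhat, inverse = TRUE)) / (plan$P * plan$Q)
  full[plan$t + seq_len(H), plan$t + seq_len(W), drop = FALSE]
}

#' Linear "same" convolution of a kernel component with a field
#'
#' Computes the linear (zero-padded, non-circular) 2-D convolution of
#' `kernel_component` with `field`, cropped to the shape of `field` with the
#' kernel center aligned to each output pixel.  Implemented by FFT with
#' padding to fast composite lengths, so opposite image borders never
#' interact (no circular wrap-around).
#'
#' @param kernel_component Odd-sized numeric matrix (e.g. `kx` or `ky` from
#'   [build_kernel()]).
#' @param field Numeric matrix at least as large as the kernel.
#' @return Numeric matrix, same shape as `field`.
#' @seealso [convolve_same_direct()] for the brute-force reference.
#' @export
convolve_same <- function(kernel_component, field) {
  kh <- nrow(kernel_component); kw <- ncol(kernel_component)
  if (kh %% 2L == 0L || kw %% 2L == 0L)
    stop("kernel must have odd dimensions", call. = FALSE)
  if (kh > nrow(field) + (kh - 1L) || kw > ncol(field) + (kw - 1L))
    stop("kernel larger than the padded field", call. = FALSE)
  H <- nrow(field); W <- ncol(field)
  P <- fast_len(H + kh - 1L)
  Q <- fast_len(W + kw - 1L)
  Khat <- stats::fft(pad_to(kernel_component, P, Q))
  Fhat <- stats::fft(pad_to(field, P, Q))
  full <- Re(stats::fft(Khat * Fhat, inverse = TRUE)) / (P * Q)
  th <- (kh - 1L) %/% 2L
  tw <- (kw - 1L) %/% 2L
  full[th + seq_len(H), tw + seq_len(W), drop = FALSE]
}

#' @rdname convolve_same
#' @details `convolve_same_direct` evaluates the same quantity by an explicit
#'   sliding-window double sum; it exists as an independent oracle for the
#'   FFT path and for small problems only.
#' @export
convolve_same_direct <- function(kernel_component, field) {
  kh <- nrow(kernel_component); kw <- ncol(kernel_component)
  th <- (kh - 1L) %/% 2L
  tw <- (kw - 1L) %/% 2L
  out <- matrix(0, nrow(field), ncol(field))
  for (dy in -th:th) {
    for (dx in -tw:tw) {
      k <- kernel_component[dy + th + 1L, dx + tw + 1L]
      if (k != 0) out <- out + k * shift_zero(field, -dy, -dx)
    }
  }
  out
}
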