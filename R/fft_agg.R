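# Frequency-domain attention aggregation.
#
# The server combines the clients' shared weight tensors per tensor:
# reshape to a 2D matrix, centered 2D FFT, split the spectrum into low and
# high frequencies by a threshold fraction r, pool the low parts across
# clients with a reciprocal-Gram softmax attention (upweighting clients
# whose low-frequency components are dissimilar from the rest, i.e. the
# slow-converging ones), keep each client's own high part, and invert.

# 2D fftshift/ifftshift: roll each axis so the DC term sits at
# (floor(n/2)+1), the grid "center". pracma's fftshift is vector-only.
.roll_idx <- function(n, s) ((seq_len(n) - 1L + s) %% n) + 1L

fftshift2 <- function(z) {
  d <- dim(z)
  # left-rotate each axis by ceil(n/2): DC lands at floor(n/2)+1
  z[.roll_idx(d[1L], d[1L] - d[1L] %/% 2L),
    .roll_idx(d[2L], d[2L] - d[2L] %/% 2L), drop = FALSE]
}

ifftshift2 <- function(z) {
  d <- dim(z)
  z[.roll_idx(d[1L], d[1L] %/% 2L),
    .roll_idx(d[2L], d[2L] %/% 2L), drop = FALSE]
}

# Centered integer frequency coordinates along one axis of length n:
# positions 1..n carry frequencies -floor(n/2) .. ceil(n/2)-1.
centered_coords <- function(n) seq_len(n) - (n %/% 2L + 1L)

#' Reshape a convolution weight tensor to a 2D matrix (and back)
#'
#' A 4D kernel in the common \code{(out, in, kH, kW)} layout is permuted to
#' \code{(in, kH, kW, out)} and flattened row-major into an
#' \code{(in*kH) x (kW*out)} matrix, the canonical form the spectral
#' aggregation operates on. The returned record makes the reshape exactly
#' invertible. 2D inputs pass through unchanged.
#'
#' @param w a 4D array (out, in, kH, kW) or a 2D matrix.
#' @return list with \code{matrix} and \code{record} (a \code{shape_record}).
#' @export
reshape_to_2d <- function(w) {
  d <- dim(w)
  if (length(d) == 2L) {
    return(list(matrix = w,
                record = structure(list(shape = d, is2d = TRUE),
                                   class = "shape_record")))
  }
  if (length(d) != 4L) {
    stop("reshape_to_2d expects a 4D (out, in, kH, kW) tensor or a matrix")
  }
  m <- aperm(w, c(3L, 2L, 1L, 4L))     # (kH, cin, cout, kW)
  dim(m) <- c(d[3L] * d[2L], d[1L] * d[4L])
  list(matrix = m,
       record = structure(list(shape = d, is2d = FALSE),
                          class = "shape_record"))
}

#' @param m matrix produced by \code{reshape_to_2d}.
#' @param record the matching \code{shape_record}.
#' @rdname reshape_to_2d
#' @export
invert_reshape <- function(m, record) {
  if (record$is2d) {
    dim(m) <- record$shape
    return(m)
  }
  d <- record$shape
  dim(m) <- c(d[3L], d[2L], d[1L], d[4L])
  aperm(m, c(3L, 2L, 1L, 4L))
}

#' Centered 2D FFT and its inverse
#'
#' \code{fft2_centered} computes the 2D discrete Fourier transform of a real
#' matrix with the zero-frequency (DC) coefficient shifted to the grid
#' center, coordinate (0, 0). \code{ifft2_centered} inverts it.
#'
#' @param m real matrix.
#' @return complex matrix of the same dimensions (the centered spectrum);
#'   for the inverse, the complex spatial-domain matrix.
#' @export
fft2_centered <- function(m) {
  if (!all(is.finite(m))) stop("non-finite entries in FFT input")
  if (is.null(dim(m))) m <- matrix(m, 1L)
  fftshift2(stats::fft(m))
}

#' @param z complex centered spectrum.
#' @rdname fft2_centered
#' @export
ifft2_centered <- function(z) {
  stats::fft(ifftshift2(z), inverse = TRUE) / length(z)
}

#' Low-frequency mask for a centered spectrum
#'
#' A coefficient at centered coordinates (u, v) is low-frequency iff
#' \code{|u| <= r*H/2} and \code{|v| <= r*W/2}. The mask is symmetric under
#' coordinate negation for r < 1, monotone in r, and always contains the DC
#' coefficient.
#'
#' @param H,W spectrum dimensions.
#' @param r threshold fraction in [0, 1]; r = 0 keeps only DC, r = 1 keeps
#'   everything.
#' @return logical H x W matrix with attribute \code{r}.
#' @export
make_mask <- function(H, W, r) {
  if (!is.finite(r) || r < 0 || r > 1) {
    stop("low-frequency threshold r must lie in [0, 1]")
  }
  u <- centered_coords(H)
  v <- centered_coords(W)
  mask <- outer(abs(u) <= r * H / 2, abs(v) <= r * W / 2, `&`)
  attr(mask, "r") <- r
  mask
}

#' Split a spectrum into low- and high-frequency parts
#'
#' @param z complex centered spectrum.
#' @param mask logical mask from \code{\link{make_mask}}.
#' @return list with \code{low} (\code{z} on the mask, zero elsewhere) and
#'   \code{high} (the complement); \code{low + high} reproduces \code{z}
#'   exactly.
#' @export
decompose <- function(z, mask) {
  if (!identical(dim(z), dim(mask))) {
    stop("mask dimensions do not match spectrum")
  }
  low <- z
  low[!mask] <- 0
  high <- z
  high[mask] <- 0
  list(low = low, high = high)
}

# Real embedding of the masked low-frequency coefficients: concatenated
# real and imaginary parts, in the mask's column-major order.
embed_low <- function(z, mask) {
  zl <- z[mask]
  c(Re(zl), Im(zl))
}

unembed_low <- function(v, mask) {
  m2 <- length(v) / 2L
  complex(real = v[seq_len(m2)], imaginary = v[m2 + seq_len(m2)])
}

#' Reciprocal-Gram self-attention weights across clients
#'
#' Given the K clients' low-frequency coefficient vectors (real-embedded)
#' as rows of \code{Z_l}, forms the Gram matrix \code{G = Z_l Z_l^T},
#' guards entries of magnitude below \code{eps} (replaced by
#' \code{eps * sign}, with sign(0) = +1), takes the elementwise reciprocal
#' and row-wise softmax. Clients whose components align strongly with a
#' peer produce a small reciprocal and hence a small weight: dissimilar
#' (slow-converging) clients are upweighted.
#'
#' @param Z_l K x m real matrix (one row per client) or a single vector.
#' @param eps reciprocal guard against division blow-up.
#' @return K x K row-stochastic attention matrix with entries in (0, 1).
#' @export
attention_weights <- function(Z_l, eps = 1e-8) {
  if (is.null(dim(Z_l))) Z_l <- matrix(Z_l, 1L)
  G <- tcrossprod(Z_l)
  sgn <- ifelse(G >= 0, 1, -1)
  small <- abs(G) < eps
  G[small] <- eps * sgn[small]
  R <- 1 / G
  e <- exp(R - apply(R, 1L, max))
  e / rowSums(e)
}

#' Pool the clients' low-frequency components
#'
#' Applies the attention matrix to the stacked low-frequency rows and
#' averages the attended rows over clients, yielding the single aggregated
#' low-frequency vector shared by every client. Invariant under a
#' consistent permutation of the clients.
#'
#' @param Z_l K x m real matrix of embedded low coefficients.
#' @param A K x K row-stochastic attention matrix.
#' @return length-m aggregated low-frequency vector.
#' @export
aggregate_low <- function(Z_l, A) {
  if (is.null(dim(Z_l))) Z_l <- matrix(Z_l, 1L)
  if (!is.matrix(A) || nrow(A) != nrow(Z_l) || ncol(A) != nrow(Z_l)) {
    stop("attention matrix must be K x K matching the rows of Z_l")
  }
  colMeans(A %*% Z_l)
}

#' Recombine aggregated low and client high frequencies and invert
#'
#' Re-embeds the aggregated low-frequency vector on the mask support, adds
#' the client's own high-frequency part, inverts the centered FFT, checks
#' that the imaginary residue is negligible (a real result is guaranteed by
#' the Hermitian symmetry of real-sourced spectra under a symmetric mask),
#' and reshapes back to the original tensor layout.
#'
#' @param z_high complex spectrum holding the client's high-frequency part
#'   (zero on the mask support).
#' @param zbar_low real-embedded aggregated low-frequency vector.
#' @param mask the low-frequency mask used for the split.
#' @param record \code{shape_record} from \code{\link{reshape_to_2d}}.
#' @param imag_tol maximum tolerated absolute imaginary residue.
#' @return the aggregated weight tensor in its original shape.
#' @export
recombine_and_invert <- function(z_high, zbar_low, mask, record,
                                 imag_tol = 1e-8) {
  spec <- z_high
  spec[mask] <- unembed_low(zbar_low, mask)
  x <- ifft2_centered(spec)
  resid <- max(abs(Im(x)))
  if (resid > imag_tol) {
    stop(sprintf(
      "imaginary residue %.3g exceeds %.3g: broken spectrum symmetry",
      resid, imag_tol))
  }
  invert_reshape(Re(x), record)
}

#' Aggregate one server round of shared tensors across clients
#'
#' Each 4D convolution kernel (and any 2D matrix) is processed through the
#' spectral pipeline: reshape, centered FFT, low/high split at threshold
#' \code{r}, attention-weighted pooling of the low parts, inversion with the
#' client's own high part. Tensors with fewer than two axes (biases, BN
#' affine vectors) carry no meaningful spatial frequency structure and are
#' pooled by a plain element-wise mean.
#'
#' @param client_WRs list of K named-tensor maps (the clients' shared
#'   parts), identical names and shapes across clients.
#' @param r low-frequency threshold in [0, 1].
#' @param attention_mode \code{"reciprocal"} for the reciprocal-Gram softmax
#'   weighting, \code{"uniform"} for constant 1/K weights (in which case the
#'   pooled low part is the plain mean).
#' @return list of K named-tensor maps, one per client, in input order.
#' @export
aggregate_round <- function(client_WRs, r,
                            attention_mode = c("reciprocal", "uniform")) {
  attention_mode <- match.arg(attention_mode)
  K <- length(client_WRs)
  if (K < 1L) stop("need at least one client")
  nms <- names(client_WRs[[1L]])
  for (k in seq_len(K)) {
    if (!identical(sort(names(client_WRs[[k]])), sort(nms))) {
      stop("client ", k, " has a mismatching shared tensor name set")
    }
  }
  out <- replicate(K, list(), simplify = FALSE)
  for (nm in nms) {
    ws <- lapply(client_WRs, `[[`, nm)
    nd <- length(dim(ws[[1L]]))
    if (nd >= 2L) {
      rs <- lapply(ws, reshape_to_2d)
      record <- rs[[1L]]$record
      specs <- lapply(rs, function(x) fft2_centered(x$matrix))
      dm <- dim(specs[[1L]])
      mask <- make_mask(dm[1L], dm[2L], r)
      Z_l <- do.call(rbind, lapply(specs, embed_low, mask = mask))
      A <- if (attention_mode == "uniform") {
        matrix(1 / K, K, K)
      } else {
        attention_weights(Z_l)
      }
      zbar <- aggregate_low(Z_l, A)
      for (k in seq_len(K)) {
        zh <- specs[[k]]
        zh[mask] <- 0
        out[[k]][[nm]] <- recombine_and_invert(zh, zbar, mask, record)
      }
    } else {
      avg <- Reduce(`+`, ws) / K
      for (k in seq_len(K)) out[[k]][[nm]] <- avg
    }
  }
  out
}

#' Low-frequency threshold schedule across communication rounds
#'
#' In fixed mode the threshold is constant; in adaptive mode it grows
#' linearly from \code{r0} at round 0 to \code{r1} at round T, so early
#' rounds share only the coarsest structure and later rounds share more.
#'
#' @param t round index, 0 <= t <= T.
#' @param T total number of communication rounds (>= 1).
#' @param mode \code{"fixed"} or \code{"adaptive"}.
#' @param r_fixed threshold used in fixed mode.
#' @param r0,r1 initial and terminal thresholds for the adaptive schedule.
#' @return the threshold r for round t.
#' @export
r_schedule <- function(t, T, mode = c("adaptive", "fixed"),
                       r_fixed = 0.25, r0 = 0, r1 = 0.5) {
  mode <- match.arg(mode)
  if (T < 1L) stop("T must be >= 1")
  if (t < 0L || t > T) stop("round index t must satisfy 0 <= t <= T")
  if (mode == "fixed") r_fixed else r0 + (r1 - r0) * t / T
}
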