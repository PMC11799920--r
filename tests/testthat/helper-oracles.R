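# Independent oracles and small fixture builders used across the suite.

# Direct O(N^4) double-sum DFT with the DC term moved to the grid center;
# deliberately naive and independent of the package's FFT path.
dft2_centered_ref <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0i, H, W)
  us <- seq_len(H) - (H %/% 2 + 1)      # centered row frequencies
  vs <- seq_len(W) - (W %/% 2 + 1)
  for (a in seq_len(H)) {
    for (b in seq_len(W)) {
      u <- us[a]; v <- vs[b]
      acc <- 0i
      for (i in seq_len(H)) {
        for (j in seq_len(W)) {
          ph <- -2 * pi * (u * (i - 1) / H + v * (j - 1) / W)
          acc <- acc + m[i, j] * complex(argument = ph)
        }
      }
      out[a, b] <- acc
    }
  }
  out
}

# Reference ASSD: boundary extraction by an explicit per-pixel loop
# (4-neighbour, border outside), distances via EBImage's exact Euclidean
# distance transform. Unit spacing.
assd_ref_ebimage <- function(pred, gt, cls) {
  boundary_loop <- function(mask) {
    H <- nrow(mask); W <- ncol(mask)
    out <- NULL
    for (i in seq_len(H)) {
      for (j in seq_len(W)) {
        if (!mask[i, j]) next
        nb <- c(if (i > 1) mask[i - 1, j] else FALSE,
                if (i < H) mask[i + 1, j] else FALSE,
                if (j > 1) mask[i, j - 1] else FALSE,
                if (j < W) mask[i, j + 1] else FALSE)
        if (!all(nb)) out <- rbind(out, c(i, j))
      }
    }
    out
  }
  b1 <- boundary_loop(pred == cls)
  b2 <- boundary_loop(gt == cls)
  if (is.null(b1) || is.null(b2)) return(NA_real_)
  dist_to <- function(bpts) {
    ind <- matrix(1, nrow(pred), ncol(pred))
    ind[bpts] <- 0
    EBImage::distmap(ind, metric = "euclidean")
  }
  d1 <- dist_to(b2)   # distance of every pixel to gt boundary
  d2 <- dist_to(b1)
  (sum(d1[b1]) + sum(d2[b2])) / (nrow(b1) + nrow(b2))
}

# Tiny U-Net and a perturbed family of K clients' shared tensors.
tiny_unet <- function(seed = 1L, n_classes = 3L) {
  build_unet(1L, n_classes, depth = 2L, base_width = 4L, seed = seed)
}

perturbed_shared <- function(model, preset, K, sd = 0.01, seed = 99L) {
  spec <- classify_parameters(model, preset)
  WR <- split_weights(model, spec)$W_R
  withr::with_seed(seed, lapply(seq_len(K), function(k) {
    lapply(WR, function(w) {
      out <- w + stats::rnorm(length(w), sd = sd)
      dim(out) <- dim(w)
      out
    })
  }))
}

# Small deterministic two-client federation fixture.
small_federation_data <- function(K = 2L, n = 20L, het = 0.8, seed = 3L) {
  profs <- make_profiles(K, het, seed = seed)
  lapply(seq_len(K), function(k) {
    generate_dataset(profs[[k]], n, size = c(32L, 32L), seed = 100L + k)
  })
}
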