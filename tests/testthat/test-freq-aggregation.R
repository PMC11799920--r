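test_that("weight reshape follows the canonical index bookkeeping and inverts", {
  # (out=8, in=4, 3, 3) -> 12 x 24 via permutation to (in, kH, kW, out)
  w <- array(stats::rnorm(8 * 4 * 3 * 3), c(8, 4, 3, 3))
  rr <- reshape_to_2d(w)
  expect_identical(dim(rr$matrix), c(12L, 24L))
  # index oracle: element (a=cin, b=kH, c=kW, o=cout) lands at
  # row (a-1)*kH + b, column (c-1)*cout + o
  for (probe in 1:20) {
    a <- sample(4, 1); b <- sample(3, 1); cc <- sample(3, 1); o <- sample(8, 1)
    expect_identical(rr$matrix[(a - 1) * 3 + b, (cc - 1) * 8 + o],
                     w[o, a, b, cc])
  }
  expect_identical(invert_reshape(rr$matrix, rr$record), w)

  # degenerate 1x1 kernels: (out=5, in=2, 1, 1) -> 2 x 5
  w1 <- array(stats::rnorm(10), c(5, 2, 1, 1))
  r1 <- reshape_to_2d(w1)
  expect_identical(dim(r1$matrix), c(2L, 5L))
  expect_identical(invert_reshape(r1$matrix, r1$record), w1)

  # 2D matrices pass through unchanged
  m2 <- matrix(stats::rnorm(12), 3, 4)
  r2 <- reshape_to_2d(m2)
  expect_identical(r2$matrix, m2)
  expect_identical(invert_reshape(r2$matrix, r2$record), m2)
})

test_that("centered FFT matches DC placement, a 1x1 identity and the brute-force DFT", {
  z <- fft2_centered(matrix(3, 4, 4))
  expect_equal(Mod(z[3, 3]), 48, tolerance = 1e-10)   # 16 * c at center
  expect_lt(sum(Mod(z)) - Mod(z[3, 3]), 1e-10)

  expect_equal(fft2_centered(matrix(2.5, 1, 1))[1, 1], 2.5 + 0i)

  set.seed(42)
  for (dims in list(c(3, 3), c(4, 4), c(5, 7), c(8, 8), c(2, 5))) {
    m <- matrix(stats::rnorm(prod(dims)), dims[1], dims[2])
    expect_lt(max(Mod(fft2_centered(m) - dft2_centered_ref(m))), 1e-10)
  }
  expect_error(fft2_centered(matrix(c(1, NA, 3, 4), 2)), "non-finite")
})

test_that("FFT/IFFT round trip is exact to 1e-10 on random matrices", {
  set.seed(7)
  for (i in 1:40) {
    H <- sample(1:64, 1); W <- sample(1:64, 1)
    m <- matrix(stats::rnorm(H * W), H, W)
    back <- Re(ifft2_centered(fft2_centered(m)))
    expect_lt(max(abs(back - m)) / max(1, max(abs(m))), 1e-10)
  }
})

test_that("the low-frequency mask has the right combinatorics and symmetry", {
  expect_identical(sum(make_mask(8, 8, 0)), 1L)
  ctr <- make_mask(8, 8, 0)
  expect_true(ctr[5, 5])                      # DC at floor(n/2)+1
  expect_true(all(make_mask(8, 8, 1)))
  expect_identical(sum(make_mask(8, 8, 0.5)), 25L)

  # monotone nesting in r
  rs <- c(0, 0.25, 0.5, 1)
  for (dims in list(c(8, 8), c(5, 9), c(12, 3))) {
    prev <- NULL
    for (r in rs) {
      mk <- make_mask(dims[1], dims[2], r)
      if (!is.null(prev)) expect_true(all(mk[prev]))
      prev <- mk
    }
  }

  # symmetry under coordinate negation for r < 1 (odd and even sizes)
  for (dims in list(c(8, 8), c(7, 7), c(6, 9))) {
    mk <- make_mask(dims[1], dims[2], 0.5)
    u <- seq_len(dims[1]) - (dims[1] %/% 2 + 1)
    v <- seq_len(dims[2]) - (dims[2] %/% 2 + 1)
    for (a in seq_len(dims[1])) {
      for (b in seq_len(dims[2])) {
        na_ <- which(u == -u[a]); nb <- which(v == -v[b])
        if (length(na_) && length(nb)) {
          expect_identical(mk[a, b], mk[na_, nb])
        }
      }
    }
  }
  expect_error(make_mask(4, 4, 1.2), "\\[0, 1\\]")
})

test_that("decomposition is exactly complementary", {
  set.seed(11)
  z <- fft2_centered(matrix(stats::rnorm(48), 6, 8))
  mk <- make_mask(6, 8, 0.4)
  dec <- decompose(z, mk)
  expect_identical(dec$low + dec$high, z)
  expect_true(all(dec$high[mk] == 0))
  expect_true(all(dec$low[!mk] == 0))

  all_true <- matrix(TRUE, 6, 8)
  expect_true(all(decompose(z, all_true)$high == 0))
  expect_true(all(decompose(z, !all_true)$low == 0))
  expect_error(decompose(z, matrix(TRUE, 3, 3)), "dimensions")
})

test_that("reciprocal-Gram attention matches a brute-force oracle and is row-stochastic", {
  expect_equal(attention_weights(matrix(stats::rnorm(5), 1)), matrix(1, 1, 1))

  Z2 <- matrix(rep(c(1, 2, 3), 2), 2, byrow = TRUE)
  expect_equal(attention_weights(Z2), matrix(0.5, 2, 2), tolerance = 1e-12)

  set.seed(5)
  for (i in 1:5) {
    Z <- matrix(stats::rnorm(3 * 7), 3, 7)
    # explicit oracle: Gram, guarded reciprocal, row softmax
    G <- Z %*% t(Z)
    G[abs(G) < 1e-8] <- 1e-8 * ifelse(G[abs(G) < 1e-8] >= 0, 1, -1)
    R <- 1 / G
    A_ref <- t(apply(R, 1, function(row) exp(row) / sum(exp(row))))
    A <- attention_weights(Z)
    expect_equal(A, A_ref, tolerance = 1e-12)
    expect_equal(rowSums(A), rep(1, 3), tolerance = 1e-12)
    expect_true(all(A > 0 & A < 1))
  }
})

test_that("low-frequency pooling is shared, symmetric and reduces to the mean", {
  set.seed(9)
  z <- stats::rnorm(10)
  expect_equal(aggregate_low(matrix(z, 1), matrix(1, 1, 1)), z)

  Zs <- matrix(rep(z, 3), 3, byrow = TRUE)
  expect_equal(aggregate_low(Zs, attention_weights(Zs)), z, tolerance = 1e-12)

  Z <- matrix(stats::rnorm(4 * 10), 4, 10)
  expect_equal(aggregate_low(Z, matrix(0.25, 4, 4)), colMeans(Z),
               tolerance = 1e-12)

  # permutation invariance of the pooled vector
  p <- c(3, 1, 4, 2)
  expect_equal(aggregate_low(Z[p, ], attention_weights(Z[p, ])),
               aggregate_low(Z, attention_weights(Z)), tolerance = 1e-12)
})

test_that("recombination inverts exactly when a client keeps its own low part", {
  set.seed(13)
  w <- array(stats::rnorm(6 * 2 * 3 * 3), c(6, 2, 3, 3))
  rr <- reshape_to_2d(w)
  z <- fft2_centered(rr$matrix)
  mk <- make_mask(nrow(z), ncol(z), 0.5)
  zh <- z; zh[mk] <- 0
  back <- recombine_and_invert(zh, freqfed:::embed_low(z, mk), mk, rr$record)
  expect_lt(max(abs(back - w)), 1e-10)
})

test_that("aggregation limits: identity at K=1/identical clients, FedAvg at r=1 uniform", {
  m <- tiny_unet(seed = 21)
  WRs1 <- perturbed_shared(m, "paf_fed", 1)
  out1 <- aggregate_round(WRs1, r = 0.5, attention_mode = "reciprocal")
  for (nm in names(WRs1[[1]])) {
    expect_lt(max(abs(out1[[1]][[nm]] - WRs1[[1]][[nm]])), 1e-8)
  }

  WR <- perturbed_shared(m, "paf_fed", 1)[[1]]
  same <- replicate(3, WR, simplify = FALSE)
  out_same <- aggregate_round(same, r = 0.3, attention_mode = "reciprocal")
  for (k in 1:3) {
    for (nm in names(WR)) {
      expect_lt(max(abs(out_same[[k]][[nm]] - WR[[nm]])), 1e-8)
    }
  }

  WRs <- perturbed_shared(m, "fedavg", 3)
  out <- aggregate_round(WRs, r = 1, attention_mode = "uniform")
  for (nm in names(WRs[[1]])) {
    ref <- Reduce(`+`, lapply(WRs, `[[`, nm)) / 3
    for (k in 1:3) expect_lt(max(abs(out[[k]][[nm]] - ref)), 1e-8)
  }

  bad <- WRs
  names(bad[[2]])[1] <- "renamed"
  expect_error(aggregate_round(bad, r = 1), "name set")
})

test_that("aggregation is equivariant under client permutation", {
  m <- tiny_unet(seed = 31)
  WRs <- perturbed_shared(m, "paf_fed", 4, sd = 0.05)
  p <- c(3, 1, 4, 2)
  out <- aggregate_round(WRs, r = 0.5, attention_mode = "reciprocal")
  out_p <- aggregate_round(WRs[p], r = 0.5, attention_mode = "reciprocal")
  for (k in 1:4) {
    for (nm in names(WRs[[1]])) {
      expect_equal(out_p[[k]][[nm]], out[[p[k]]][[nm]], tolerance = 1e-10)
    }
  }
})

test_that("the r schedule interpolates linearly and validates its domain", {
  expect_identical(r_schedule(0, 10, "adaptive", r0 = 0, r1 = 0.5), 0)
  expect_identical(r_schedule(10, 10, "adaptive", r0 = 0, r1 = 0.5), 0.5)
  expect_equal(r_schedule(5, 10, "adaptive", r0 = 0, r1 = 0.5), 0.25)
  expect_identical(r_schedule(3, 10, "fixed", r_fixed = 0.25), 0.25)
  expect_error(r_schedule(11, 10, "adaptive"), "0 <= t <= T")
  expect_error(r_schedule(-1, 10, "adaptive"), "0 <= t <= T")
})
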