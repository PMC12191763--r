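test_that("linear downsampling matches the hand-computed block means", {
  a <- matrix(c(1, 1, 3, 3, 5, 5, 7, 7), 4, 2, byrow = TRUE)
  W_mean <- rbind(c(0.5, 0), c(0, 0.5), c(0.5, 0), c(0, 0.5))
  expect_equal(linear_downsample(a, 2, W_mean),
               matrix(c(2, 2, 6, 6), 2, 2, byrow = TRUE))
  # S = 1 with identity weights is the identity
  expect_equal(linear_downsample(a, 1, diag(2)), a)
  expect_error(linear_downsample(a[1:3, ], 2, W_mean), class = "cheap_bad_shape")
})

test_that("shortened length is ceiling(L / S) after padding, for any L", {
  withr::with_seed(1, {
    for (L in sample(4:40, 8)) {
      S <- sample(c(1, 2, 4), 1)
      x <- matrix(rnorm(L * 6), L, 6)
      pd <- pad_to_multiple(x, S = S)
      W <- matrix(rnorm(S * 6 * 6), S * 6, 6)
      expect_equal(nrow(linear_downsample(pd$x, S, W)), ceiling(L / S))
    }
  })
})

test_that("upsampling inverts downsampling shapes, and exactly with a pseudo-inverse", {
  a <- matrix(rnorm(12), 6, 2)
  S <- 2
  W_down <- matrix(rnorm(8), S * 2, 2)
  W_up <- MASS::ginv(W_down)  # 2 x 4
  short <- linear_downsample(a, S, W_down)
  back <- linear_upsample(short, S, W_up)
  expect_equal(dim(back), dim(a))
  expect_equal(linear_upsample(short, 1, diag(2)), short)
  # rank-complete input: rows of the flattened blocks lie in the row space
  # of ginv(W_down), so down-then-up is exact
  c0 <- matrix(rnorm(6), 3, 2)
  Z <- c0 %*% W_up                       # 3 x 4 flattened blocks
  a_rc <- matrix(as.vector(t(Z)), ncol = 2, byrow = TRUE)
  short_rc <- linear_downsample(a_rc, S, W_down)
  expect_equal(short_rc, c0, tolerance = 1e-10)
  expect_equal(linear_upsample(short_rc, S, W_up), a_rc, tolerance = 1e-10)
})

test_that("mask reduction follows the any-valid rule and expansion repeats", {
  expect_equal(reduce_mask(c(1, 1, 1, 0), 2), c(1, 1))
  expect_equal(reduce_mask(c(0, 0), 2), c(0))
  expect_equal(reduce_mask(c(1, 0, 0, 0), 4), c(1))
  expect_equal(expand_mask(c(1, 0), 2), c(1, 1, 0, 0))
  # expanded mask equals the original when L is divisible by S and blocks
  # are homogeneous
  m <- c(1, 1, 1, 1, 0, 0)
  expect_equal(expand_mask(reduce_mask(m, 2), 2), m)
})

test_that("attention resampling obeys softmax semantics and the key mask", {
  q <- matrix(rnorm(8), 4, 2)
  kv1 <- matrix(c(3, -1), 1, 2)
  out1 <- attention_resample(q, kv1, mask = 1)
  expect_equal(out1, matrix(rep(c(3, -1), each = 4), 4, 2))
  # duplicate keys with identical values: same output as the single key
  kv3 <- kv1[c(1, 1, 1), , drop = FALSE]
  expect_equal(attention_resample(q, kv3, mask = c(1, 1, 1)), out1)
  # perturbing a masked-out key changes nothing, to tolerance 0
  kv <- matrix(rnorm(10), 5, 2)
  m <- c(1, 1, 0, 1, 1)
  base <- attention_resample(q, kv, m)
  kv_pert <- kv; kv_pert[3, ] <- c(1e6, -1e6)
  expect_identical(attention_resample(q, kv_pert, m), base)
  expect_error(attention_resample(q, kv, rep(0, 5)), class = "cheap_all_masked")
})

test_that("encode produces the contracted shapes deterministically", {
  cfg <- tiny_hcfg()
  model <- init_hourglass(cfg)
  d <- gen_embeddings(tiny_scfg(seed = 17))
  x <- d$embeddings[[1]]
  lat1 <- hpct_encode(model, x)
  expect_s3_class(lat1, "compressed_latent")
  expect_equal(nrow(lat1$values), ceiling(nrow(x) / cfg$shorten_factor))
  expect_equal(ncol(lat1$values), cfg$d_c)
  expect_identical(lat1$values, hpct_encode(model, x)$values)
  # tanh bottleneck bounds the latent
  expect_true(all(abs(lat1$values) <= 1))
})

test_that("decode restores the input shape and enforces config compatibility", {
  cfg <- tiny_hcfg()
  model <- init_hourglass(cfg)
  for (L in c(11, 16)) {
    x <- matrix(rnorm(L * 32), L, 32)
    lat <- hpct_encode(model, x)
    rec <- hpct_decode(model, lat)
    expect_equal(dim(rec), dim(x))
  }
  other <- init_hourglass(tiny_hcfg(K = 16))
  x <- matrix(rnorm(12 * 32), 12, 32)
  expect_error(hpct_decode(other, hpct_encode(model, x)),
               class = "cheap_config_mismatch")
})

test_that("valid-position outputs are invariant to padded-row content", {
  cfg <- tiny_hcfg()
  model <- init_hourglass(cfg)
  L <- 9
  x <- matrix(rnorm(L * 32), L, 32)
  m <- c(rep(1, 7), 0, 0)
  lat1 <- hpct_encode(model, x, m)
  rec1 <- hpct_decode(model, lat1)
  x2 <- x; x2[8:9, ] <- 1e6
  lat2 <- hpct_encode(model, x2, m)
  rec2 <- hpct_decode(model, lat2)
  valid_red <- lat1$mask > 0
  expect_lt(max(abs(lat1$values[valid_red, ] - lat2$values[valid_red, ])), 1e-6)
  expect_lt(max(abs(rec1[1:7, ] - rec2[1:7, ])), 1e-6)
})

test_that("all input dependence flows through the bottleneck (no skips)", {
  cfg <- tiny_hcfg()
  model <- init_hourglass(cfg)
  zero_latent <- function(x) {
    lat <- hpct_encode(model, x)
    lat$values <- lat$values * 0
    hpct_decode(model, lat)
  }
  x1 <- matrix(rnorm(12 * 32), 12, 32)
  x2 <- matrix(rnorm(12 * 32), 12, 32)
  expect_equal(zero_latent(x1), zero_latent(x2), tolerance = 1e-12)
})

test_that("compression ratio follows ceiling(L/S) * d_c for random lengths", {
  cfg <- hourglass_config(d_model = 1024, downproject_factor = 128,
                          shorten_factor = 2)
  withr::with_seed(4, {
    for (L in sample(20:600, 10)) {
      expect_equal(compression_ratio(cfg, L),
                   (L * 1024) / (ceiling(L / 2) * 8))
    }
  })
  expect_equal(compression_ratio(cfg, 512), 256)
})

test_that("invalid hourglass configurations are rejected", {
  expect_error(hourglass_config(d_model = 30, n_heads = 4),
               class = "cheap_bad_config")
  expect_error(hourglass_config(d_model = 32, downproject_factor = 5),
               class = "cheap_bad_config")
  expect_error(hourglass_config(d_model = 32, bottleneck = "fsq",
                                downproject_factor = 8,
                                fsq_levels = c(5, 5)),
               class = "cheap_bad_config")
})
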