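test_that("channel statistics are elementwise extrema over valid positions", {
  x <- matrix(c(0, 1, 0, 1), 2, 2)
  st <- estimate_channel_stats(x)
  expect_equal(st$x_min, c(0, 0))
  expect_equal(st$x_max, c(1, 1))
  # padded positions containing enormous values leave stats untouched
  x2 <- rbind(x, c(1e9, -1e9))
  st2 <- estimate_channel_stats(list(x2), masks = list(c(1, 1, 0)))
  expect_equal(st2$x_min, st$x_min)
  expect_equal(st2$x_max, st$x_max)
  expect_error(estimate_channel_stats(list(x), masks = list(c(0, 0))),
               class = "cheap_empty_input")
})

test_that("outlier channels show up in the estimated extrema", {
  d <- gen_embeddings(tiny_scfg(seed = 5, outlier_scale = 500))
  st <- estimate_channel_stats(d)
  out_ch <- d$config$outlier_channels
  pos_out <- out_ch[d$generator$offsets[out_ch] > 0][1]
  expect_gt(st$x_max[pos_out] - median(st$x_max[-out_ch]), 400)
})

test_that("normalization maps calibration extrema to the target bounds", {
  x <- matrix(c(-5, 5, 0, 10), 2, 2)
  st <- estimate_channel_stats(x)
  xn <- normalize_embedding(matrix(c(0, 5, -5, 5, 10, 0), 3, 2), st)
  expect_equal(xn[1, 1], 0)    # midpoint symmetry
  expect_equal(xn[2, 1], 1)    # calibration max -> c_max
  expect_equal(xn[3, 1], -1)   # calibration min -> c_min
  # whole calibration set stays inside [c_min, c_max]
  d <- gen_embeddings(tiny_scfg(seed = 2))
  std <- estimate_channel_stats(d)
  for (e in d$embeddings) {
    en <- normalize_embedding(e, std)
    expect_true(all(en >= -1 - 1e-12 & en <= 1 + 1e-12))
  }
})

test_that("denormalization is the exact inverse away from constant channels", {
  d <- gen_embeddings(tiny_scfg(seed = 13))
  st <- estimate_channel_stats(d)
  x <- d$embeddings[[1]]
  rt <- denormalize_embedding(normalize_embedding(x, st), st)
  rel <- max(abs(rt - x)) / max(st$x_max - st$x_min)
  expect_lt(rel, 1e-5)
  # normalized midpoint maps back to (x_min + x_max) / 2
  mid <- denormalize_embedding(matrix(0, 1, length(st$x_min)), st)
  expect_equal(as.vector(mid), (st$x_min + st$x_max) / 2, tolerance = 1e-10)
})

test_that("constant channels are flagged, guarded and non-invertible", {
  x <- cbind(rep(2, 4), rnorm(4))
  st <- estimate_channel_stats(x)
  expect_true(st$constant[1])
  expect_false(st$constant[2])
  xn <- normalize_embedding(x, st)
  expect_true(all(xn[, 1] == -1))  # divide guard maps to c_min
  expect_error(denormalize_embedding(xn, st), class = "cheap_constant_channel")
})

test_that("activation reports expose outlier channels and magnitude ratios", {
  ones <- matrix(1, 5, 8)
  rep1 <- activation_report(ones, k = 3)
  expect_equal(rep1$top_k$value / rep1$median_magnitude, rep(1, 3))
  d <- gen_embeddings(tiny_scfg(seed = 21, outlier_scale = 3000))
  rep2 <- activation_report(d, k = 3)
  expect_setequal(rep2$top_k$channel, d$config$outlier_channels)
  expect_gte(min(rep2$top_k$value) / rep2$median_magnitude, 1000)
})

test_that("zero_channels is a pure surgical ablation", {
  x <- matrix(rnorm(20), 4, 5)
  expect_identical(zero_channels(x, integer()), x)
  z <- zero_channels(x, c(1, 3))
  expect_true(all(z[, c(1, 3)] == 0))
  expect_identical(z[, c(2, 4, 5)], x[, c(2, 4, 5)])
  # Pythagorean check: removed energy equals the norm of the zeroed columns
  expect_equal(sum((x - z)^2), sum(x[, c(1, 3)]^2))
  expect_error(zero_channels(x, 9), class = "cheap_bad_input")
})

test_that("statistics are stable across disjoint halves of a larger sample", {
  d <- gen_embeddings(tiny_scfg(seed = 31, n_samples = 40))
  st1 <- estimate_channel_stats(d$embeddings[1:20])
  st2 <- estimate_channel_stats(d$embeddings[21:40])
  rng <- pmax(st1$x_max - st1$x_min, 1e-9)
  expect_lt(max(abs(st1$x_max - st2$x_max) / rng), 0.5)
  expect_lt(max(abs(st1$x_min - st2$x_min) / rng), 0.5)
  expect_gt(stats::cor(st1$x_max, st2$x_max), 0.99)
})
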