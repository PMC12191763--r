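test_that("tanh bottleneck saturates and matches high-precision values", {
  expect_equal(tanh_bottleneck(0), 0)
  expect_lt(abs(tanh_bottleneck(1e6) - 1), 1e-9)
  expect_equal(tanh_bottleneck(0.5), 0.46211715726000974, tolerance = 1e-12)
  c <- matrix(rnorm(20, sd = 5), 4, 5)
  expect_true(all(abs(tanh_bottleneck(c)) < 1))
})

test_that("VQ assigns nearest codes with deterministic tie-breaking", {
  cb <- rbind(c(0, 0), c(1, 1))
  r <- vq_quantize(matrix(c(0.9, 0.8), 1, 2), cb)
  expect_equal(r$tokens$indices, 1L)
  expect_equal(r$quantized, matrix(c(1, 1), 1, 2))
  # exact match: both auxiliary losses vanish
  r2 <- vq_quantize(matrix(c(1, 1), 1, 2), cb)
  expect_equal(r2$tokens$indices, 1L)
  expect_equal(r2$codebook_loss, 0)
  expect_equal(r2$commitment_loss, 0)
  # equidistant input goes to the lowest index
  r3 <- vq_quantize(matrix(c(0.5, 0.5), 1, 2), cb)
  expect_equal(r3$tokens$indices, 0L)
  expect_error(vq_quantize(matrix(0, 1, 3), cb), class = "cheap_bad_shape")
})

test_that("masked VQ rows carry no index and no loss", {
  cb <- new_codebook(4, 2, seed = 1)
  c <- matrix(rnorm(8), 4, 2)
  r <- vq_quantize(c, cb, mask = c(1, 1, 0, 1))
  expect_true(is.na(r$tokens$indices[3]))
  expect_equal(r$quantized[3, ], c(0, 0))
  # loss unaffected by the masked row's content
  c2 <- c; c2[3, ] <- 1e4
  r2 <- vq_quantize(c2, cb, mask = c(1, 1, 0, 1))
  expect_equal(r$codebook_loss, r2$codebook_loss)
})

test_that("VQ perplexity is the exponential entropy of code usage", {
  expect_equal(vq_perplexity(rep(5, 16)), 16)
  expect_equal(vq_perplexity(c(0, 100, 0)), 1)
  expect_equal(vq_perplexity(c(3, 1)), 1.7547654, tolerance = 1e-6)
  expect_error(vq_perplexity(c(0, 0)), class = "cheap_empty_input")
})

test_that("FSQ rounds bounded values onto the expected integer grid", {
  expect_equal(fsq_quantize(matrix(0), 5)$ints[1, 1], 0)
  expect_equal(fsq_quantize(matrix(10), 5)$ints[1, 1], 2)   # saturated top bin
  expect_equal(fsq_quantize(matrix(0.3), 5)$ints[1, 1], 1)  # round(2 tanh 0.3)
  # every quantized value lies on the per-channel grid
  lv <- c(5, 4, 3)
  z <- matrix(rnorm(30, sd = 2), 10, 3)
  q <- fsq_quantize(z, lv)
  for (j in 1:3) {
    expect_true(all(q$quantized[, j] %in% fsq_grid(lv, j)))
  }
  # re-quantizing grid values (already bounded) is the identity
  q2 <- fsq_quantize(q$quantized, lv, bound = FALSE)
  expect_equal(q2$quantized, q$quantized)
  expect_equal(q2$tokens$indices, q$tokens$indices)
})

test_that("FSQ index encoding is a bijection over the implicit codebook", {
  for (lv in list(c(3, 3), c(5, 4))) {
    geo_n <- prod(lv)
    all_codes <- fsq_decode_index(0:(geo_n - 1), lv)
    idx <- fsq_encode_index(all_codes, lv)
    expect_equal(idx, 0:(geo_n - 1))
    expect_equal(length(unique(idx)), geo_n)
  }
  # degenerate single-level channel admits only index 0
  expect_equal(fsq_encode_index(matrix(0), 1), 0L)
  # eight binary channels give an implicit codebook of 256
  expect_equal(prod(fsq_geometry_levels <- rep(2L, 8)), 256)
  expect_error(fsq_encode_index(matrix(5, 1, 1), 3), class = "cheap_bad_input")
  expect_error(fsq_decode_index(9, c(3, 3)), class = "cheap_bad_input")
})

test_that("wide inputs force full FSQ codebook utilization", {
  lv <- c(3, 3)
  withr::with_seed(8, z <- matrix(runif(2000 * 2, -3, 3), 2000, 2))
  q <- fsq_quantize(z, lv)
  expect_equal(codebook_utilization(q$tokens, prod(lv)), 1)
})

test_that("codebook utilization counts distinct observed codes", {
  expect_equal(codebook_utilization(0:15, 16), 1)
  expect_equal(codebook_utilization(rep(3L, 100), 16), 1 / 16)
  withr::with_seed(2, toks <- sample(0:15, 10000, replace = TRUE))
  expect_equal(codebook_utilization(toks, 16), 1)  # coupon-collector bound
})
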