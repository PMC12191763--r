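test_that("interpolation reproduces endpoints exactly and is affine", {
  withr::with_seed(3, {
    x1 <- matrix(rnorm(12), 3, 4)
    x2 <- matrix(rnorm(12), 3, 4)
  })
  tr <- interpolate_latents(x1, x2, ts = c(0, 0.25, 0.5, 1))
  expect_identical(tr$latents[[1]], x2)   # t = 0
  expect_identical(tr$latents[[4]], x1)   # t = 1
  expect_equal(interpolate_latents(matrix(0), matrix(2), 0.5)$latents[[1]],
               matrix(1))
  # swapping arguments at 1 - t gives identical latents
  tr_swap <- interpolate_latents(x2, x1, ts = 0.75)
  expect_equal(tr$latents[[2]], tr_swap$latents[[1]], tolerance = 1e-12)
  expect_error(interpolate_latents(x1, x2[, 1:2], 0.5), class = "cheap_bad_shape")
  expect_error(interpolate_latents(x1, x2, 1.5), class = "cheap_bad_input")
})

test_that("token corruption respects rate, mask and degenerate codebooks", {
  toks <- cheap:::new_tokenized_latent(rep(0L, 50), rep(1, 50), 4)
  expect_identical(corrupt_tokens(toks, 0, seed = 1)$indices, toks$indices)
  one <- cheap:::new_tokenized_latent(rep(0L, 50), rep(1, 50), 1)
  expect_identical(corrupt_tokens(one, 1, seed = 1)$indices, one$indices)
  # masked positions are never touched
  m <- rep(c(1, 0), 25)
  tm <- cheap:::new_tokenized_latent(rep(2L, 50), m, 8)
  out <- corrupt_tokens(tm, 1, seed = 4)
  expect_identical(out$indices[m == 0], tm$indices[m == 0])
  expect_identical(out$mask, tm$mask)
  expect_error(corrupt_tokens(toks, 1.2), class = "cheap_bad_input")
})

test_that("corrupted fraction matches rate * (1 - 1/C) and draws uniformly", {
  n <- 10000; C <- 16; rate <- 0.5
  toks <- cheap:::new_tokenized_latent(rep(3L, n), rep(1, n), C)
  out <- corrupt_tokens(toks, rate, seed = 11)
  frac <- mean(out$indices != toks$indices)
  p <- rate * (1 - 1 / C)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / n))
  # replacement distribution is uniform over codes (chi-square)
  out2 <- corrupt_tokens(cheap:::new_tokenized_latent(rep(0L, 20000),
                                                      rep(1, 20000), 8),
                         1, seed = 12)
  pval <- suppressWarnings(stats::chisq.test(tabulate(out2$indices + 1L, 8))$p.value)
  expect_gt(pval, 0.01)
})

test_that("smoothness curves are linear for latent distance and monotone", {
  x1 <- matrix(seq(0, 1, length.out = 8), 4, 2)
  x2 <- -x1
  tr <- interpolate_latents(x1, x2, ts = seq(0, 1, by = 0.1))
  neg_dist <- function(a, b) -sqrt(sum((a - b)^2))
  sc <- smoothness_curve(tr, neg_dist)
  # similarity to either endpoint is exactly linear in t on a segment
  expect_lt(max(abs(diff(diff(sc$sim_to_x1)))), 1e-9)
  expect_lt(max(abs(diff(diff(sc$sim_to_x2)))), 1e-9)
  mono <- attr(sc, "monotone_fraction")
  expect_equal(unname(mono["toward_x1"]), 1)
  expect_equal(unname(mono["toward_x2"]), 1)
  # a normalized similarity scores 1 for an endpoint against itself
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  sc2 <- smoothness_curve(tr, cosine)
  expect_equal(sc2$sim_to_x1[sc2$t == 1], 1)
  expect_equal(sc2$sim_to_x2[sc2$t == 0], 1)
})

test_that("decoded smoothness through the model head is mostly monotone", {
  fx <- fixture_trained_model()
  d <- fx$data
  L <- min(nrow(d$embeddings[[1]]), nrow(d$embeddings[[2]]))
  m <- rep(1, L)
  lat1 <- hpct_encode(fx$model, d$embeddings[[1]][1:L, , drop = FALSE], m)
  lat2 <- hpct_encode(fx$model, d$embeddings[[2]][1:L, , drop = FALSE], m)
  tr <- interpolate_latents(lat1$values, lat2$values, seq(0, 1, by = 0.25))
  sim <- function(a, b) -sqrt(mean((a - b)^2))
  sc <- smoothness_curve(tr, sim)
  expect_gt(attr(sc, "monotone_fraction")[["toward_x1"]], 0.5)
})
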