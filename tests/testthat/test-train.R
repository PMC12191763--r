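test_that("masked MSE ignores padding and matches closed forms", {
  x <- matrix(rnorm(20), 4, 5)
  m <- c(1, 1, 1, 0)
  expect_equal(masked_mse(x, x, m), 0)
  expect_equal(masked_mse(x, x + 0.3, m), 0.09, tolerance = 1e-12)
  xg <- x; xg[4, ] <- 1e9  # garbage confined to the padded row
  expect_equal(masked_mse(x, xg, m), 0)
  expect_error(masked_mse(x, x, rep(0, 4)), class = "cheap_empty_input")
  expect_error(masked_mse(x, x[1:3, ], m), class = "cheap_bad_shape")
})

test_that("the learning-rate trace follows linear warmup then constant", {
  fx <- fixture_trained_model()
  tr <- fx$model$trace
  expect_equal(tr$lr, 2e-3 * pmin(1, tr$step / 30), tolerance = 1e-12)
})

test_that("zero training steps return the initialization with stats attached", {
  d <- gen_embeddings(tiny_scfg(seed = 19))
  hcfg <- tiny_hcfg()
  m0 <- train_compression(d, hcfg, train_config(max_steps = 0, seed = 1))
  expect_identical(m0$params, init_hourglass(hcfg)$params)
  expect_s3_class(m0$stats, "channel_stats")
})

test_that("training is reproducible from the root seed", {
  d <- gen_embeddings(tiny_scfg(seed = 23, n_samples = 8))
  hcfg <- tiny_hcfg(seed = 2)
  tcfg <- train_config(learning_rate = 2e-3, warmup_steps = 10, max_steps = 15,
                       batch_size = 4, seed = 9)
  m1 <- train_compression(d, hcfg, tcfg)
  m2 <- train_compression(d, hcfg, tcfg)
  expect_identical(m1$trace$loss, m2$trace$loss)
  expect_identical(m1$params, m2$params)
})

test_that("checkpoints round-trip losslessly", {
  fx <- fixture_trained_model()
  path <- tempfile(fileext = ".rds")
  save_checkpoint(fx$model, path)
  restored <- read_checkpoint(path)
  e1 <- eval_masked_mse(fx$model, fx$data)
  e2 <- eval_masked_mse(restored, fx$data)
  expect_equal(e1, e2, tolerance = 1e-6)
  expect_error(read_checkpoint(tempfile()), class = "cheap_io_error")
})

test_that("the sequence decoder emits 21-way scores and rejects bad labels", {
  d <- gen_embeddings(tiny_scfg(seed = 29, noise_sd = 0))
  dec <- train_sequence_decoder(d, hidden = 64, epochs = 8, batch_size = 128,
                                learning_rate = 3e-3, seed = 1)
  x <- d$embeddings[[1]]
  logits <- predict(dec, x, type = "logits")
  expect_equal(dim(logits), c(nrow(x), 21))
  # the labels are linearly recoverable, so even a short run is accurate
  expect_gt(dec$holdout_accuracy, 0.9)
  bad <- d$labels
  bad[[1]][1] <- 25L
  expect_error(train_sequence_decoder(d, labels = bad),
               class = "cheap_bad_label")
})

test_that("the linear probe recovers a realizable pooled-signal target", {
  d <- gen_embeddings(tiny_scfg(seed = 37, n_samples = 200, noise_sd = 0.02))
  pooled <- do.call(rbind, lapply(d$embeddings, colMeans))
  withr::with_seed(5, w <- rnorm(ncol(pooled)))
  y <- as.vector(pooled %*% w)
  pr <- linear_probe(lapply(d$embeddings, identity), y, task = "regression",
                     epochs = 600, seed = 2)
  expect_gt(pr$metric[["r_squared"]], 0.99)
  # shuffled targets are unlearnable
  withr::with_seed(6, ysh <- sample(y))
  pr2 <- linear_probe(lapply(d$embeddings, identity), ysh, task = "regression",
                      epochs = 600, seed = 2)
  expect_lt(pr2$metric[["r_squared"]], 0.5)
  expect_error(linear_probe(lapply(d$embeddings, identity), y[1:10]),
               class = "cheap_bad_input")
})

test_that("probe performance does not increase as the latent width shrinks", {
  d <- gen_embeddings(synthetic_config(
    n_samples = 150, length_range = c(10, 18), n_channels = 64,
    intrinsic_rank = 8, outlier_channels = c(7, 33), outlier_scale = 500,
    noise_sd = 0.3, seed = 53))
  rows <- do.call(rbind, d$embeddings)
  pca <- prcomp(rows, center = TRUE, scale. = FALSE)
  pooled <- do.call(rbind, lapply(d$embeddings, colMeans))
  withr::with_seed(8, w <- rnorm(64))
  y <- as.vector(pooled %*% w)
  r2_at <- function(d_c, seed) {
    proj <- pca$rotation[, seq_len(d_c), drop = FALSE]
    lat <- lapply(d$embeddings, function(e) e %*% proj)
    linear_probe(lat, y, task = "regression", epochs = 300,
                 seed = seed)$metric[["r_squared"]]
  }
  med <- vapply(c(64, 8, 4), function(d_c) {
    median(vapply(1:3, function(s) r2_at(d_c, s), numeric(1)))
  }, numeric(1))
  expect_gte(med[1], med[2])   # d_c = 64 >= d_c = 8
  expect_gte(med[2], med[3])   # d_c = 8  >= d_c = 4
})
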