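# shared fixtures, all generated in code at test time

# small-but-realistic synthetic dataset: low-rank signal, outlier channels,
# token labels; sized so whole-stack tests stay fast
tiny_scfg <- function(seed = 11, n_samples = 16, n_channels = 32,
                      noise_sd = 0.05, outlier_scale = 500) {
  synthetic_config(
    n_samples = n_samples, length_range = c(10, 18), n_channels = n_channels,
    intrinsic_rank = 4, outlier_channels = c(5, 20, 28),
    outlier_scale = outlier_scale, noise_sd = noise_sd, seed = seed
  )
}

tiny_hcfg <- function(bottleneck = "tanh", seed = 5, K = 8, S = 2, ...) {
  hourglass_config(d_model = 32, n_layers_enc = 1, n_layers_dec = 1,
                   n_heads = 2, shorten_factor = S, downproject_factor = K,
                   bottleneck = bottleneck, rel_window = 4, ffn_mult = 2,
                   codebook_size = 32, seed = seed, ...)
}

# lazily trained tanh fixture model shared within a test file run
.fixture_env <- new.env(parent = emptyenv())
fixture_trained_model <- function() {
  if (is.null(.fixture_env$model)) {
    d <- gen_embeddings(tiny_scfg())
    tcfg <- train_config(learning_rate = 2e-3, warmup_steps = 30,
                         max_steps = 80, batch_size = 4, seed = 3)
    .fixture_env$model <- train_compression(d, tiny_hcfg(), tcfg)
    .fixture_env$data <- d
  }
  list(model = .fixture_env$model, data = .fixture_env$data)
}

# independent oracle: minimize RMSD over rotations (Euler angles) and
# translations by general-purpose optimization, multi-start
brute_force_min_rmsd <- function(a, b, n_starts = 8, seed = 1) {
  euler_R <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cx <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(par) {
    R <- euler_R(par[1:3])
    moved <- sweep(a %*% t(R), 2, par[4:6], "+")
    sqrt(mean(rowSums((moved - b)^2)))
  }
  best <- Inf
  withr::with_seed(seed, {
    for (s in seq_len(n_starts)) {
      par0 <- c(runif(3, -pi, pi), colMeans(b) - colMeans(a))
      fit <- optim(par0, obj, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-14))
      if (fit$value < best) best <- fit$value
    }
  })
  best
}
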