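#' Hourglass protein compression transformer configuration
#'
#' The HPCT is an autoencoder over per-residue embeddings. The encoder runs
#' transformer blocks at full length, shortens the sequence by a factor `S`
#' via linear downsampling (equivalent to a stride-`S`, width-`S`
#' convolution), lets the shortened positions cross-attend back over the
#' full-length sequence (attention resampling), and projects channels down
#' by a factor `K` (`d_c = d_model / K`). A bottleneck then constrains the
#' code: elementwise `tanh` (continuous), a learned VQ-VAE codebook, or
#' finite scalar quantization (FSQ). The decoder mirrors the encoder; there
#' are deliberately no skip connections across the bottleneck, so all input
#' dependence must flow through the code.
#'
#' Transformer block details are not dictated by the architecture and are
#' configurable: pre-norm blocks, learned relative-position bias (clipped at
#' `rel_window`), GELU feedforward with expansion `ffn_mult`.
#'
#' @param d_model Embedding width `D` (divisible by `n_heads` and by
#'   `downproject_factor`).
#' @param n_layers_enc,n_layers_dec Transformer blocks in encoder/decoder.
#' @param n_heads Attention heads.
#' @param shorten_factor Lengthwise compression `S >= 1`; the latent has
#'   `ceiling(L / S)` positions (inputs are zero-padded to a multiple of `S`,
#'   with the mask extended by zeros).
#' @param downproject_factor Channelwise compression `K`; bottleneck width is
#'   `d_c = d_model / K`.
#' @param bottleneck One of `"tanh"`, `"vq"`, `"fsq"`.
#' @param codebook_size VQ codebook size `C` (ignored otherwise).
#' @param beta VQ commitment-loss weight (default 0.25).
#' @param fsq_levels Integer vector of per-channel level counts for FSQ, one
#'   per bottleneck channel; defaults to 5 levels per channel.
#' @param rel_window Relative-position bias clip distance.
#' @param ffn_mult Feedforward expansion factor.
#' @param seed Seed used by [init_hourglass()] for weight initialization.
#' @return An object of class `hourglass_config`.
#' @export
hourglass_config <- function(d_model = 1024, n_layers_enc = 2, n_layers_dec = 2,
                             n_heads = 4, shorten_factor = 2,
                             downproject_factor = 8,
                             bottleneck = c("tanh", "vq", "fsq"),
                             codebook_size = 512, beta = 0.25,
                             fsq_levels = NULL, rel_window = 32, ffn_mult = 4,
                             seed = 1) {
  bottleneck <- match.arg(bottleneck)
  if (!is_count(d_model) || !is_count(n_heads) || !is_count(shorten_factor) ||
      !is_count(downproject_factor) || !is_count(n_layers_enc) ||
      !is_count(n_layers_dec)) {
    cheap_abort("counts in the hourglass config must be positive integers.",
                "cheap_bad_config")
  }
  if (d_model %% n_heads != 0) {
    cheap_abort("`d_model` must be divisible by `n_heads`.", "cheap_bad_config")
  }
  if (d_model %% downproject_factor != 0) {
    cheap_abort("`d_model` must be divisible by `downproject_factor`.",
                "cheap_bad_config")
  }
  d_c <- d_model %/% downproject_factor
  if (bottleneck == "fsq") {
    if (is.null(fsq_levels)) fsq_levels <- rep(5L, d_c)
    fsq_levels <- as.integer(fsq_levels)
    if (length(fsq_levels) != d_c || any(fsq_levels < 1L)) {
      cheap_abort("`fsq_levels` must have one entry >= 1 per bottleneck channel.",
                  "cheap_bad_config")
    }
  }
  structure(
    list(d_model = as.integer(d_model), n_layers_enc = as.integer(n_layers_enc),
         n_layers_dec = as.integer(n_layers_dec), n_heads = as.integer(n_heads),
         shorten_factor = as.integer(shorten_factor),
         downproject_factor = as.integer(downproject_factor), d_c = d_c,
         bottleneck = bottleneck, codebook_size = as.integer(codebook_size),
         beta = beta, fsq_levels = fsq_levels,
         rel_window = as.integer(rel_window), ffn_mult = as.integer(ffn_mult),
         seed = as.integer(seed)),
    class = "hourglass_config"
  )
}

#' Initialize an untrained hourglass model
#'
#' Weights are drawn deterministically from `cfg$seed`: attention and FFN
#' matrices `N(0, 0.02)`, layer-norm gains 1, relative biases 0, and the
#' down/up channel projections and the lengthwise resampling matrices
#' scaled-orthogonal (no biases on the projections).
#'
#' @param cfg An [hourglass_config()].
#' @return An object of class `hpct_model` (weights + config; channel
#'   statistics and a training trace are attached by [train_compression()]).
#' @export
init_hourglass <- function(cfg) {
  if (!inherits(cfg, "hourglass_config")) {
    cheap_abort("`cfg` must be an `hourglass_config`.", "cheap_bad_config")
  }
  D <- cfg$d_model; S <- cfg$shorten_factor
  withr::with_seed(cfg$seed, {
    p <- list()
    put <- function(pre, lst) {
      for (nm in names(lst)) p[[paste0(pre, nm)]] <<- lst[[nm]]
    }
    for (i in seq_len(cfg$n_layers_enc)) {
      put(sprintf("enc%d_", i), init_block(D, cfg$n_heads, cfg$ffn_mult, cfg$rel_window))
    }
    p$down_W <- ortho_init(S * D, D)
    put("res_enc_", init_resample(D, cfg$n_heads))
    p$proj_Wd <- ortho_init(D, cfg$d_c)
    if (cfg$bottleneck == "vq") {
      p$vq_codebook <- rmat(cfg$codebook_size, cfg$d_c, sd = 1 / sqrt(cfg$d_c))
    }
    p$proj_Wu <- ortho_init(cfg$d_c, D)
    p$up_W <- ortho_init(D, S * D)
    put("res_dec_", init_resample(D, cfg$n_heads))
    for (i in seq_len(cfg$n_layers_dec)) {
      put(sprintf("dec%d_", i), init_block(D, cfg$n_heads, cfg$ffn_mult, cfg$rel_window))
    }
    structure(list(params = p, cfg = cfg, stats = NULL, trace = NULL),
              class = "hpct_model")
  })
}

#' @export
print.hpct_model <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf(
    "<hpct_model> D=%d, S=%d, K=%d (d_c=%d), bottleneck=%s, %d+%d layers%s\n",
    cfg$d_model, cfg$shorten_factor, cfg$downproject_factor, cfg$d_c,
    cfg$bottleneck, cfg$n_layers_enc, cfg$n_layers_dec,
    if (is.null(x$trace)) " (untrained)" else sprintf(", trained %d steps", nrow(x$trace))))
  invisible(x)
}

## ---- exported shortening primitives ----

#' Lengthwise linear downsampling
#'
#' Shortens `a` from `L x D` to `(L/S) x D`: groups of `S` consecutive rows
#' are flattened to a length-`S*D` vector and multiplied by `W`
#' (`(S*D) x D`). Equivalent to a 1-D convolution with filter size and
#' stride both equal to `S`. `L` must already be padded to a multiple of `S`
#' (see [pad_to_multiple()]).
#'
#' @param a Numeric `L x D` matrix.
#' @param S Integer shortening factor.
#' @param W `(S*D) x D` weight matrix.
#' @return `(L/S) x D` matrix.
#' @export
linear_downsample <- function(a, S, W) {
  check_matrix(a, "a")
  if (nrow(a) %% S != 0) {
    cheap_abort("`a` must have a multiple of `S` rows; pad first.", "cheap_bad_shape")
  }
  if (!is.matrix(W) || nrow(W) != S * ncol(a)) {
    cheap_abort(sprintf("`W` must be (%d x D); got %d rows.", S * ncol(a), nrow(W)),
                "cheap_bad_shape")
  }
  X2 <- matrix(as.vector(t(a)), ncol = S * ncol(a), byrow = TRUE)
  X2 %*% W
}

#' Lengthwise linear upsampling
#'
#' Inverse-shaped counterpart of [linear_downsample()]: multiplies the
#' shortened `(L/S) x D` matrix by `W` (`D x (S*D)`) and reshapes each row
#' into `S` consecutive rows, returning `L x D`.
#'
#' @param a Numeric `(L/S) x D` matrix.
#' @param S Integer shortening factor.
#' @param W `D x (S*D)` weight matrix.
#' @return `(L) x D` matrix with `L = S * nrow(a)`.
#' @export
linear_upsample <- function(a, S, W) {
  check_matrix(a, "a")
  if (!is.matrix(W) || nrow(W) != ncol(a) || ncol(W) != S * ncol(a)) {
    cheap_abort(sprintf("`W` must be %d x %d.", ncol(a), S * ncol(a)), "cheap_bad_shape")
  }
  Y2 <- a %*% W
  matrix(as.vector(t(Y2)), ncol = ncol(a), byrow = TRUE)
}

#' Reduce a validity mask across shortening blocks
#'
#' Block `b` of the shortened mask is valid iff any of its `S` source
#' positions is valid (sum-then-threshold rule).
#'
#' @param m 0/1 mask of length `L` (a multiple of `S`).
#' @param S Integer shortening factor.
#' @return 0/1 mask of length `L/S`.
#' @examples
#' reduce_mask(c(1, 1, 1, 0), 2)  # c(1, 1)
#' @export
reduce_mask <- function(m, S) {
  m <- check_mask(m)
  if (length(m) %% S != 0) {
    cheap_abort("mask length must be a multiple of `S`.", "cheap_bad_shape")
  }
  as.numeric(colSums(matrix(m, nrow = S)) > 0)
}

#' Expand a shortened mask back to full length
#'
#' Repeat-then-threshold: each shortened position contributes `S`
#' consecutive full-length positions.
#'
#' @param m 0/1 mask of length `L/S`.
#' @param S Integer shortening factor.
#' @return 0/1 mask of length `L`.
#' @export
expand_mask <- function(m, S) {
  m <- check_mask(m)
  as.numeric(rep(m, each = S) > 0)
}

#' Zero-pad an embedding to a multiple of the shortening factor
#'
#' @param x `L x D` matrix.
#' @param mask Length-`L` 0/1 mask (default all ones).
#' @param S Shortening factor.
#' @return List with `x` (`Lp x D`), `mask` (length `Lp`), and the original
#'   `L`; padding rows are zero and masked out.
#' @export
pad_to_multiple <- function(x, mask = NULL, S = 1) {
  check_matrix(x)
  L <- nrow(x)
  if (is.null(mask)) mask <- rep(1, L)
  mask <- check_mask(mask, L)
  pad <- (S - L %% S) %% S
  if (pad > 0) {
    x <- rbind(x, matrix(0, pad, ncol(x)))
    mask <- c(mask, rep(0, pad))
  }
  list(x = x, mask = mask, L = L)
}

#' Cross-attention resampling primitive
#'
#' One row of output per query, computed by scaled-dot-product attention of
#' the queries over the keys/values; masked-out key positions receive
#' exactly zero attention weight. With the default identity projections this
#' is the bare resampling operator (a single valid key returns its value row
#' for every query); the model-internal layer wraps it with learned
#' projections, layer norms and a residual connection.
#'
#' @param queries `Lq x D` matrix.
#' @param keys_values `Lk x D` matrix used for both keys and values.
#' @param mask Length-`Lk` 0/1 key mask; must have at least one valid key.
#' @param n_heads Number of attention heads (default 1).
#' @return `Lq x D` matrix.
#' @export
attention_resample <- function(queries, keys_values, mask, n_heads = 1) {
  check_matrix(queries, "queries"); check_matrix(keys_values, "keys_values")
  if (ncol(queries) != ncol(keys_values)) {
    cheap_abort("queries and keys/values must share the channel dimension.",
                "cheap_bad_shape")
  }
  mask <- check_mask(mask, nrow(keys_values))
  if (!any(mask > 0)) cheap_abort("all key positions are masked out.",
                                  "cheap_all_masked")
  D <- ncol(queries)
  dh <- D %/% n_heads
  out <- matrix(0, nrow(queries), D)
  for (h in seq_len(n_heads)) {
    idx <- ((h - 1) * dh + 1):(h * dh)
    S <- tcrossprod(queries[, idx, drop = FALSE],
                    keys_values[, idx, drop = FALSE]) / sqrt(dh)
    S[, mask == 0] <- MASK_NEG
    S <- S - apply(S, 1, max)
    E <- exp(S)
    out[, idx] <- (E / rowSums(E)) %*% keys_values[, idx, drop = FALSE]
  }
  out
}

## ---- full forward / backward ----

# forward through the whole autoencoder on one padded sample.
# x: Lp x D (already normalized, pad rows arbitrary), m: length-Lp mask.
# Returns reconstruction (padded), latent pieces and caches for backward.
hpct_fwd <- function(p, cfg, x, m, keep_cache = FALSE) {
  S <- cfg$shorten_factor
  nh <- cfg$n_heads; R <- cfg$rel_window
  x0 <- x * m
  h <- x0
  enc_caches <- vector("list", cfg$n_layers_enc)
  for (i in seq_len(cfg$n_layers_enc)) {
    bf <- block_fwd(p, sprintf("enc%d_", i), h, m, nh, R)
    enc_caches[[i]] <- bf$cache
    h <- bf$y
  }
  a_full <- h
  X2 <- matrix(as.vector(t(a_full)), ncol = S * cfg$d_model, byrow = TRUE)
  xd <- X2 %*% p$down_W
  m_red <- reduce_mask(m, S)
  rs <- resample_fwd(p, "res_enc_", xd, a_full, key_mask = m, q_mask = m_red, n_heads = nh)
  a_short <- rs$y
  c_pre <- a_short %*% p$proj_Wd        # L' x d_c, pad rows exactly zero
  bt <- bottleneck_fwd(c_pre, cfg, p, m_red)
  c_q <- bt$values
  b1 <- (c_q * m_red) %*% p$proj_Wu     # L' x D
  Y2 <- b1 %*% p$up_W
  a_up <- matrix(as.vector(t(Y2)), ncol = cfg$d_model, byrow = TRUE)
  a_up <- a_up * m
  rs2 <- resample_fwd(p, "res_dec_", a_up, b1, key_mask = m_red, q_mask = m, n_heads = nh)
  h2 <- rs2$y
  dec_caches <- vector("list", cfg$n_layers_dec)
  for (i in seq_len(cfg$n_layers_dec)) {
    bf <- block_fwd(p, sprintf("dec%d_", i), h2, m, nh, R)
    dec_caches[[i]] <- bf$cache
    h2 <- bf$y
  }
  out <- list(recon = h2, pre = a_short, c_pre = c_pre, latent = c_q,
              codes = bt$codes, mask_red = m_red, aux = bt$aux)
  if (keep_cache) {
    out$cache <- list(enc = enc_caches, X2 = X2, xd = xd, rs = rs$cache,
                      a_short = a_short, bt = bt$cache, c_q = c_q, b1 = b1,
                      rs2 = rs2$cache, dec = dec_caches, m = m, m_red = m_red,
                      a_full = a_full)
  }
  out
}

# backward: d_recon is the gradient of the loss wrt the padded reconstruction.
# Returns flat gradient list (same names as params). VQ auxiliary-loss
# gradients (codebook + commitment + straight-through) are injected at the
# bottleneck.
hpct_bwd <- function(p, cfg, fw, d_recon) {
  ca <- fw$cache
  if (is.null(ca)) cheap_abort("forward pass was run without keep_cache.", "cheap_internal")
  S <- cfg$shorten_factor; D <- cfg$d_model
  grads <- list()
  dh2 <- d_recon
  for (i in rev(seq_len(cfg$n_layers_dec))) {
    bb <- block_bwd(p, dh2, ca$dec[[i]], grads)
    dh2 <- bb$dx; grads <- bb$grads
  }
  rb2 <- resample_bwd(p, dh2, ca$rs2, grads)
  grads <- rb2$grads
  da_up <- rb2$dq * ca$m
  dY2 <- matrix(as.vector(t(da_up)), ncol = S * D, byrow = TRUE)
  grads$up_W <- crossprod(ca$b1, dY2)
  db1 <- tcrossprod(dY2, p$up_W) + rb2$dkv
  grads$proj_Wu <- crossprod(ca$c_q * ca$m_red, db1)
  dc_q <- tcrossprod(db1, p$proj_Wu) * ca$m_red
  dc_pre <- bottleneck_bwd(dc_q, ca$bt, cfg, grads)
  grads <- dc_pre$grads
  da_short <- tcrossprod(dc_pre$dc, p$proj_Wd)
  grads$proj_Wd <- crossprod(ca$a_short, dc_pre$dc)
  rb1 <- resample_bwd(p, da_short, ca$rs, grads)
  grads <- rb1$grads
  dxd <- rb1$dq
  grads$down_W <- crossprod(ca$X2, dxd)
  dX2 <- tcrossprod(dxd, p$down_W)
  da_full <- matrix(as.vector(t(dX2)), ncol = D, byrow = TRUE) + rb1$dkv
  dh <- da_full
  for (i in rev(seq_len(cfg$n_layers_enc))) {
    bb <- block_bwd(p, dh, ca$enc[[i]], grads)
    dh <- bb$dx; grads <- bb$grads
  }
  grads
}

## ---- user-facing encode / decode ----

#' Encode an embedding into the compressed latent
#'
#' Applies the model's stored per-channel normalization (when present and
#' `normalized = FALSE`), zero-pads to a multiple of `S`, and runs the
#' encoder half of the hourglass: transformer blocks, linear downsampling,
#' mask reduction, attention resampling over the full-length sequence,
#' channel downprojection and the configured bottleneck.
#'
#' @param model An `hpct_model`.
#' @param x `L x D` embedding matrix.
#' @param mask Optional length-`L` 0/1 mask (default all valid).
#' @param normalized Set `TRUE` if `x` is already normalized.
#' @return An object of class `compressed_latent`: `values`
#'   (`ceiling(L/S) x d_c`), integer `codes` (0-based; discrete bottlenecks
#'   only), `mask`, the original `length`, and the compression settings.
#' @export
hpct_encode <- function(model, x, mask = NULL, normalized = FALSE) {
  stopifnot(inherits(model, "hpct_model"))
  check_matrix(x)
  cfg <- model$cfg
  if (ncol(x) != cfg$d_model) {
    cheap_abort(sprintf("embedding has %d channels; model expects %d.",
                        ncol(x), cfg$d_model), "cheap_channel_mismatch")
  }
  if (!normalized && !is.null(model$stats)) x <- normalize_embedding(x, model$stats)
  pd <- pad_to_multiple(x, mask, cfg$shorten_factor)
  fw <- hpct_fwd(model$params, cfg, pd$x, pd$mask)
  structure(
    list(values = fw$latent, codes = fw$codes, mask = fw$mask_red,
         mask_full = pd$mask, pre = fw$pre, length = pd$L,
         S = cfg$shorten_factor, K = cfg$downproject_factor,
         bottleneck = cfg$bottleneck),
    class = "compressed_latent"
  )
}

#' @export
print.compressed_latent <- function(x, ...) {
  cat(sprintf("<compressed_latent> %d x %d (%s), from length %d (S=%d, K=%d)\n",
              nrow(x$values), ncol(x$values), x$bottleneck, x$length, x$S, x$K))
  invisible(x)
}

#' Decode a compressed latent back to an embedding
#'
#' Runs the decoder half: channel upprojection, lengthwise linear
#' upsampling, mask expansion, attention resampling of the full-length
#' queries over the shortened keys, transformer blocks, and (when the model
#' carries channel statistics and `denormalized = TRUE`) inversion of the
#' per-channel normalization. The output is cropped to the original length.
#'
#' @param model The `hpct_model` whose encoder produced `latent`.
#' @param latent A `compressed_latent`.
#' @param denormalized Return embeddings on the original (denormalized)
#'   scale when channel statistics are available.
#' @return `L x D` embedding matrix.
#' @export
hpct_decode <- function(model, latent, denormalized = FALSE) {
  stopifnot(inherits(model, "hpct_model"))
  if (!inherits(latent, "compressed_latent")) {
    cheap_abort("`latent` must be a `compressed_latent`.", "cheap_bad_input")
  }
  cfg <- model$cfg
  if (ncol(latent$values) != cfg$d_c || latent$S != cfg$shorten_factor ||
      latent$bottleneck != cfg$bottleneck) {
    cheap_abort("latent was produced under a different configuration.",
                "cheap_config_mismatch")
  }
  p <- model$params
  m_red <- latent$mask
  c_q <- latent$values * m_red
  b1 <- c_q %*% p$proj_Wu
  Y2 <- b1 %*% p$up_W
  a_up <- matrix(as.vector(t(Y2)), ncol = cfg$d_model, byrow = TRUE)
  # reuse the encoder's full-length mask when recorded (keeps decode
  # identical to the training forward for L not divisible by S); fall back
  # to repeat-then-threshold expansion
  m_full <- if (!is.null(latent$mask_full)) latent$mask_full
            else expand_mask(m_red, cfg$shorten_factor)
  a_up <- a_up * m_full
  rs2 <- resample_fwd(p, "res_dec_", a_up, b1, key_mask = m_red, q_mask = m_full,
                      n_heads = cfg$n_heads)
  h2 <- rs2$y
  for (i in seq_len(cfg$n_layers_dec)) {
    h2 <- block_fwd(p, sprintf("dec%d_", i), h2, m_full, cfg$n_heads,
                    cfg$rel_window)$y
  }
  out <- h2[seq_len(latent$length), , drop = FALSE]
  if (denormalized && !is.null(model$stats)) {
    out <- denormalize_embedding(out, model$stats)
  }
  out
}

#' Compression ratio of a configuration
#'
#' Stored scalars per protein are `ceiling(L/S) * d_c`; the ratio is
#' `(L * D) / (ceiling(L/S) * d_c)`.
#'
#' @param cfg An `hourglass_config`.
#' @param L Protein length(s).
#' @return Numeric vector of reduction factors.
#' @export
compression_ratio <- function(cfg, L) {
  (L * cfg$d_model) / (ceiling(L / cfg$shorten_factor) * cfg$d_c)
}

#' @describeIn init_hourglass parameter inventory, one row per tensor.
#' @param x An `hpct_model`.
#' @param ... Unused.
#' @method tidy hpct_model
#' @export
tidy.hpct_model <- function(x, ...) {
  tibble::tibble(
    parameter = names(x$params),
    n_values = vapply(x$params, length, integer(1)),
    component = dplyr::case_when(
      grepl("^enc", names(x$params)) ~ "encoder",
      grepl("^dec", names(x$params)) ~ "decoder",
      grepl("^res_enc", names(x$params)) ~ "resample_enc",
      grepl("^res_dec", names(x$params)) ~ "resample_dec",
      grepl("^vq", names(x$params)) ~ "bottleneck",
      TRUE ~ "projection"
    )
  )
}

#' @describeIn init_hourglass one-row model summary (sizes, bottleneck,
#'   final training loss when trained).
#' @param x An `hpct_model`.
#' @method glance hpct_model
#' @export
glance.hpct_model <- function(x, ...) {
  tibble::tibble(
    d_model = x$cfg$d_model, S = x$cfg$shorten_factor,
    K = x$cfg$downproject_factor, d_c = x$cfg$d_c,
    bottleneck = x$cfg$bottleneck,
    n_parameters = sum(vapply(x$params, length, integer(1))),
    trained_steps = if (is.null(x$trace)) 0L else nrow(x$trace),
    final_loss = if (is.null(x$trace)) NA_real_ else tail(x$trace$loss, 1)
  )
}
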