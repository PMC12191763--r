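#' Continuous tanh bottleneck
#'
#' Elementwise `tanh`, constricting bottleneck values to `(-1, 1)`; the
#' continuous counterpart of the quantizing bottlenecks.
#'
#' @param c Numeric matrix (or vector).
#' @return Same shape, values in `(-1, 1)`.
#' @export
tanh_bottleneck <- function(c) tanh(c)

#' Create a VQ codebook
#'
#' @param size Codebook size `C`.
#' @param d_c Code vector dimension.
#' @param seed Integer seed.
#' @return `C x d_c` matrix of code vectors.
#' @export
new_codebook <- function(size, d_c, seed = 1) {
  if (!is_count(size) || !is_count(d_c)) {
    cheap_abort("`size` and `d_c` must be positive integers.", "cheap_bad_config")
  }
  withr::with_seed(as.integer(seed), rmat(size, d_c, sd = 1 / sqrt(d_c)))
}

new_tokenized_latent <- function(indices, mask, C) {
  structure(list(indices = as.integer(indices), mask = as.numeric(mask),
                 C = as.numeric(C)),
            class = "tokenized_latent")
}

#' @export
print.tokenized_latent <- function(x, ...) {
  cat(sprintf("<tokenized_latent> %d positions (%d valid), codebook size %g\n",
              length(x$indices), sum(x$mask), x$C))
  invisible(x)
}

#' Vector quantization (VQ-VAE bottleneck)
#'
#' Each row of `c` is assigned the nearest codebook vector in Euclidean
#' distance (ties broken toward the lowest index, deterministically). Along
#' with the quantized rows and 0-based indices, the two auxiliary losses of
#' the VQ-VAE objective are returned, both as means over valid positions and
#' dimensions: the codebook loss `||sg[c] - e||^2` (pulls codes toward the
#' encoder output) and the commitment loss `beta * ||c - sg[e]||^2` (keeps
#' the encoder close to its code). During training the gradient contract is
#' straight-through: the reconstruction gradient is copied from the
#' quantized output to the continuous input unchanged.
#'
#' @param c `L x d_c` matrix of continuous bottleneck rows.
#' @param codebook `C x d_c` matrix of code vectors.
#' @param beta Commitment weight (default 0.25).
#' @param mask Optional length-`L` 0/1 mask; invalid rows get index `NA`,
#'   quantized value 0, and do not contribute to the losses.
#' @return List with `tokens` (a `tokenized_latent`, 0-based indices),
#'   `quantized` (`L x d_c`), `codebook_loss`, `commitment_loss`.
#' @export
vq_quantize <- function(c, codebook, beta = 0.25, mask = NULL) {
  check_matrix(c); check_matrix(codebook, "codebook")
  if (nrow(codebook) < 1L) cheap_abort("empty codebook.", "cheap_empty_input")
  if (ncol(c) != ncol(codebook)) {
    cheap_abort("`c` and `codebook` must share the channel dimension.",
                "cheap_bad_shape")
  }
  L <- nrow(c)
  if (is.null(mask)) mask <- rep(1, L)
  mask <- check_mask(mask, L)
  # squared Euclidean distances via the expansion ||c||^2 + ||e||^2 - 2 c.e
  d2 <- outer(rowSums(c * c), rowSums(codebook * codebook), "+") -
    2 * tcrossprod(c, codebook)
  idx <- max.col(-d2, ties.method = "first")  # lowest index wins ties
  quant <- codebook[idx, , drop = FALSE] * mask
  idx[mask == 0] <- NA_integer_
  nv <- sum(mask)
  if (nv > 0) {
    diff <- (c - codebook[ifelse(is.na(idx), 1L, idx), , drop = FALSE]) * mask
    cb_loss <- sum(diff * diff) / (nv * ncol(c))
  } else {
    cb_loss <- 0
  }
  list(tokens = new_tokenized_latent(idx - 1L, mask, nrow(codebook)),
       quantized = quant,
       codebook_loss = cb_loss,
       commitment_loss = beta * cb_loss)
}

#' VQ code-selection perplexity
#'
#' The exponential of the entropy of the empirical code distribution; `C`
#' when all codes are used uniformly, 1 under complete codebook collapse.
#'
#' @param index_counts Non-negative counts per code (length `C`).
#' @return A single number in `[1, C]`.
#' @examples
#' vq_perplexity(rep(1, 16))  # 16
#' vq_perplexity(c(3, 1))     # ~1.7548
#' @export
vq_perplexity <- function(index_counts) {
  if (any(index_counts < 0)) cheap_abort("counts must be non-negative.",
                                         "cheap_bad_input")
  tot <- sum(index_counts)
  if (tot <= 0) cheap_abort("total count must be positive.", "cheap_empty_input")
  p <- index_counts[index_counts > 0] / tot
  exp(-sum(p * log(p)))
}

# per-channel FSQ geometry: half-width, offset (even levels use the
# half-integer offset scheme), and atanh shift so the bound is centered
fsq_geometry <- function(levels) {
  levels <- as.integer(levels)
  if (any(levels < 1L)) cheap_abort("FSQ levels must be >= 1.", "cheap_bad_config")
  half_l <- (levels - 1) / 2
  offset <- ifelse(levels %% 2L == 0L, 0.5, 0)
  shift <- ifelse(half_l > 0, atanh(offset / pmax(half_l, 1e-12)), 0)
  list(levels = levels, half_l = half_l, offset = offset, shift = shift,
       lo = -(levels %/% 2L), hi = levels - 1L - levels %/% 2L)
}

#' Finite scalar quantization
#'
#' Parameter-free quantizer: each channel `j` is bounded with `tanh` and
#' rounded to one of `L_j` integer bins, `q = round(floor(L_j/2) * tanh(z))`
#' for odd `L_j` (even level counts use the half-integer offset scheme,
#' which shifts the tanh so that rounding yields `L_j` bins at
#' half-integers). Decoder-facing values are rescaled to `[-1, 1]`. The
#' implicit codebook size is `prod(levels)`; per-position indices use a
#' mixed-radix encoding with channel 1 most significant. The training
#' gradient contract is straight-through around the rounding (the tanh
#' derivative is kept).
#'
#' With `bound = FALSE` the tanh bound is skipped and inputs are taken to be
#' already on the decoder value scale in `[-1, 1]`; quantization is then
#' idempotent on grid values, which is the natural re-quantization check.
#'
#' @param z `L x d` matrix (d = number of level entries).
#' @param levels Integer vector of per-channel level counts.
#' @param mask Optional 0/1 row mask; invalid rows get `NA` indices.
#' @param bound Apply the tanh bound (default `TRUE`).
#' @return List with `tokens` (a `tokenized_latent` over the implicit
#'   codebook), `quantized` (decoder-facing values in `[-1, 1]`), and
#'   `ints` (the per-channel integer codes).
#' @examples
#' fsq_quantize(matrix(0.3), levels = 5)$ints  # round(2 * tanh(0.3)) = 1
#' @export
fsq_quantize <- function(z, levels, mask = NULL, bound = TRUE) {
  check_matrix(z)
  geo <- fsq_geometry(levels)
  if (ncol(z) != length(geo$levels)) {
    cheap_abort("`z` must have one column per level entry.", "cheap_bad_shape")
  }
  if (is.null(mask)) mask <- rep(1, nrow(z))
  mask <- check_mask(mask, nrow(z))
  hl <- ifelse(geo$half_l == 0, 1, geo$half_l)
  if (bound) {
    zt <- tanh(sweep(z, 2, geo$shift, "+"))
    bounded <- sweep(sweep(zt, 2, geo$half_l, "*"), 2, geo$offset, "-")
  } else {
    bounded <- sweep(sweep(z, 2, hl, "*"), 2, geo$offset, "-")
  }
  q <- round(bounded)
  # clamp to the representable range (relevant only for unbounded inputs)
  q <- pmin(pmax(q, matrix(geo$lo, nrow(q), ncol(q), byrow = TRUE)),
            matrix(geo$hi, nrow(q), ncol(q), byrow = TRUE))
  values <- sweep(sweep(q, 2, geo$offset, "+"), 2, hl, "/")
  idx <- fsq_encode_index(q, geo$levels)
  idx[mask == 0] <- NA_integer_
  list(tokens = new_tokenized_latent(idx, mask, prod(geo$levels)),
       quantized = values, ints = q)
}

#' Mixed-radix FSQ index encoding and decoding
#'
#' Maps per-channel integer codes to a single index in
#' `[0, prod(levels))` and back; channel 1 is the most significant digit.
#' Encoding then decoding returns the identical code tuple.
#'
#' @param codes Integer matrix (`L x d`) or vector (length `d`) of
#'   per-channel codes, each within its channel's representable range.
#' @param levels Integer vector of per-channel level counts.
#' @return `fsq_encode_index()`: integer vector of 0-based indices;
#'   `fsq_decode_index()`: `L x d` integer matrix of codes.
#' @export
fsq_encode_index <- function(codes, levels) {
  geo <- fsq_geometry(levels)
  if (is.vector(codes)) codes <- matrix(codes, nrow = 1)
  if (ncol(codes) != length(geo$levels)) {
    cheap_abort("`codes` must have one column per level entry.", "cheap_bad_shape")
  }
  for (j in seq_along(geo$levels)) {
    if (any(codes[, j] < geo$lo[j] | codes[, j] > geo$hi[j], na.rm = TRUE)) {
      cheap_abort(sprintf("channel %d codes outside [%d, %d].", j, geo$lo[j], geo$hi[j]),
                  "cheap_bad_input")
    }
  }
  digits <- sweep(codes, 2, geo$lo, "-")  # 0-based digits in [0, L_j)
  idx <- rep(0, nrow(codes))
  for (j in seq_along(geo$levels)) idx <- idx * geo$levels[j] + digits[, j]
  as.integer(idx)
}

#' @rdname fsq_encode_index
#' @param index Integer vector of 0-based indices in `[0, prod(levels))`.
#' @export
fsq_decode_index <- function(index, levels) {
  geo <- fsq_geometry(levels)
  index <- as.numeric(index)
  if (any(index < 0 | index >= prod(geo$levels), na.rm = TRUE)) {
    cheap_abort("`index` outside [0, prod(levels)).", "cheap_bad_input")
  }
  d <- length(geo$levels)
  out <- matrix(NA_integer_, length(index), d)
  rem <- index
  for (j in rev(seq_len(d))) {
    out[, j] <- as.integer(rem %% geo$levels[j]) + geo$lo[j]
    rem <- rem %/% geo$levels[j]
  }
  out
}

#' Decoder-facing FSQ grid values for one channel
#'
#' @param levels Integer vector of level counts.
#' @param channel Which channel's grid to return.
#' @return Sorted numeric vector of the `L_j` representable values.
#' @export
fsq_grid <- function(levels, channel = 1) {
  geo <- fsq_geometry(levels)
  hl <- ifelse(geo$half_l[channel] == 0, 1, geo$half_l[channel])
  (seq(geo$lo[channel], geo$hi[channel]) + geo$offset[channel]) / hl
}

#' Codebook utilization
#'
#' Fraction of distinct codes observed among valid positions, the standard
#' collapse diagnostic for quantized autoencoders.
#'
#' @param tokens A `tokenized_latent`, a list of them, or an integer vector
#'   of 0-based codes.
#' @param C Codebook size.
#' @return A number in `[0, 1]`.
#' @export
codebook_utilization <- function(tokens, C) {
  if (!is_count(C)) cheap_abort("`C` must be a positive integer.", "cheap_bad_config")
  idx <- collect_token_indices(tokens)
  length(unique(idx)) / C
}

collect_token_indices <- function(tokens) {
  if (inherits(tokens, "tokenized_latent")) {
    return(tokens$indices[tokens$mask > 0 & !is.na(tokens$indices)])
  }
  if (is.list(tokens)) {
    return(unlist(lapply(tokens, collect_token_indices)))
  }
  as.integer(tokens[!is.na(tokens)])
}

## ---- model-internal dispatch used by the hourglass forward/backward ----

bottleneck_fwd <- function(c_pre, cfg, p, m_red) {
  switch(cfg$bottleneck,
    tanh = {
      v <- tanh(c_pre)
      list(values = v, codes = NULL, aux = list(),
           cache = list(kind = "tanh", values = v))
    },
    vq = {
      vq <- vq_quantize(c_pre, p$vq_codebook, beta = cfg$beta, mask = m_red)
      idx1 <- vq$tokens$indices + 1L
      sel <- p$vq_codebook[ifelse(is.na(idx1), 1L, idx1), , drop = FALSE]
      list(values = vq$quantized, codes = vq$tokens,
           aux = list(codebook_loss = vq$codebook_loss,
                      commitment_loss = cfg$beta * vq$codebook_loss),
           cache = list(kind = "vq", c_pre = c_pre, idx = idx1, sel = sel,
                        m_red = m_red, beta = cfg$beta,
                        C = nrow(p$vq_codebook)))
    },
    fsq = {
      fs <- fsq_quantize(c_pre, cfg$fsq_levels, mask = m_red)
      geo <- fsq_geometry(cfg$fsq_levels)
      zt <- tanh(sweep(c_pre, 2, geo$shift, "+"))
      list(values = fs$quantized, codes = fs$tokens, aux = list(),
           cache = list(kind = "fsq", zt = zt))
    }
  )
}

# returns list(dc, grads); dc is the gradient wrt the pre-bottleneck c.
bottleneck_bwd <- function(dc_q, cache, cfg, grads) {
  if (cache$kind == "tanh") {
    return(list(dc = dc_q * (1 - cache$values^2), grads = grads))
  }
  if (cache$kind == "fsq") {
    # straight-through around the rounding; tanh derivative retained
    return(list(dc = dc_q * (1 - cache$zt^2), grads = grads))
  }
  # VQ: straight-through copy + commitment pull; codebook gets its own
  # gradient from the codebook loss (total objective = recon MSE +
  # codebook_loss + beta * commitment_loss)
  m <- cache$m_red
  nv <- max(sum(m), 1)
  d_c <- ncol(cache$c_pre)
  diff <- (cache$c_pre - cache$sel) * m          # c - e at valid rows
  dc <- dc_q + cache$beta * 2 * diff / (nv * d_c)
  dE <- matrix(0, cache$C, d_c)
  ok <- !is.na(cache$idx) & m > 0
  if (any(ok)) {
    acc <- rowsum(-2 * diff[ok, , drop = FALSE] / (nv * d_c),
                  group = cache$idx[ok])
    dE[as.integer(rownames(acc)), ] <- acc
  }
  key <- "vq_codebook"
  grads[[key]] <- if (is.null(grads[[key]])) dE else grads[[key]] + dE
  list(dc = dc, grads = grads)
}
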