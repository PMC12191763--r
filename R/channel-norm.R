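#' Estimate per-channel min-max statistics
#'
#' Massive activations in a handful of channels enlarge the numerical range
#' of pLM latents by orders of magnitude, so any global rescaling would be
#' dominated by them. The remedy is per-channel min-max normalization:
#' extrema are computed independently for each channel over all valid
#' (masked-in) positions of a calibration sample, and each channel is later
#' rescaled to a common target interval `[c_min, c_max]`.
#'
#' Channels whose calibration range is numerically zero
#' (`x_max - x_min < 1e-12`) are flagged as constant; [normalize_embedding()]
#' maps them to `c_min` (divide guard) and [denormalize_embedding()] refuses
#' to invert them.
#'
#' @param samples A `cheap_dataset`, a list of `L x D` matrices, or a single
#'   matrix.
#' @param masks Optional list of validity masks matching `samples`; taken
#'   from the dataset when one is supplied. Padded (mask 0) positions never
#'   influence the statistics.
#' @param c_min,c_max Target bounds, defaults -1 and 1.
#' @return An object of class `channel_stats` with fields `x_min`, `x_max`
#'   (length-`D`), `c_min`, `c_max`, `constant` (logical flags) and
#'   `n_samples_used`.
#' @examples
#' st <- estimate_channel_stats(matrix(c(0, 1, 0, 1), 2, 2))
#' st$x_min; st$x_max
#' @export
estimate_channel_stats <- function(samples, masks = NULL, c_min = -1, c_max = 1) {
  if (!is_scalar_num(c_min) || !is_scalar_num(c_max) || c_max <= c_min) {
    cheap_abort("`c_max` must exceed `c_min`.", "cheap_bad_config")
  }
  el <- as_embedding_list(samples, masks)
  rows <- do.call(rbind, Map(function(e, m) e[m > 0, , drop = FALSE],
                             el$embeddings, el$masks))
  if (is.null(rows) || nrow(rows) == 0L) {
    cheap_abort("no valid (masked-in) positions to estimate statistics from.",
                "cheap_empty_input")
  }
  x_min <- apply(rows, 2, min)
  x_max <- apply(rows, 2, max)
  structure(
    list(x_min = x_min, x_max = x_max, c_min = c_min, c_max = c_max,
         constant = (x_max - x_min) < 1e-12,
         n_samples_used = length(el$embeddings)),
    class = "channel_stats"
  )
}

#' @export
print.channel_stats <- function(x, ...) {
  cat(sprintf("<channel_stats> %d channels from %d samples, target [%g, %g], %d constant\n",
              length(x$x_min), x$n_samples_used, x$c_min, x$c_max, sum(x$constant)))
  invisible(x)
}

#' @describeIn estimate_channel_stats one row per channel with its extrema.
#' @param x A `channel_stats` object.
#' @param ... Unused.
#' @method tidy channel_stats
#' @export
tidy.channel_stats <- function(x, ...) {
  tibble::tibble(channel = seq_along(x$x_min), x_min = x$x_min, x_max = x$x_max,
                 range = x$x_max - x$x_min, constant = x$constant)
}

check_stats <- function(x, stats) {
  if (!inherits(stats, "channel_stats")) {
    cheap_abort("`stats` must be a `channel_stats` object.", "cheap_bad_input")
  }
  if (ncol(x) != length(stats$x_min)) {
    cheap_abort(sprintf("embedding has %d channels but stats were estimated for %d.",
                        ncol(x), length(stats$x_min)), "cheap_channel_mismatch")
  }
}

#' Apply / invert per-channel min-max normalization
#'
#' `normalize_embedding()` maps each channel through the affine map
#' `(x - x_min) / (x_max - x_min) * (c_max - c_min) + c_min`, so calibration
#' extrema land exactly on `c_min` / `c_max`. Values outside the calibration
#' range are *not* clipped: out-of-range outputs are permitted by design so
#' no information is destroyed at inference time. Constant channels map to
#' `c_min`. `denormalize_embedding()` is the exact algebraic inverse and
#' errors on constant channels, whose inverse is undefined.
#'
#' @param x An `L x D` embedding matrix.
#' @param stats A `channel_stats` object with matching channel count.
#' @return A matrix of the same shape.
#' @examples
#' st <- estimate_channel_stats(matrix(c(-5, 5), 2, 1))
#' normalize_embedding(matrix(0, 1, 1), st)  # midpoint -> 0
#' @export
normalize_embedding <- function(x, stats) {
  check_matrix(x)
  check_stats(x, stats)
  rng <- stats$x_max - stats$x_min
  scale <- ifelse(stats$constant, 0, (stats$c_max - stats$c_min) / ifelse(rng == 0, 1, rng))
  sweep(sweep(x, 2, stats$x_min, "-"), 2, scale, "*") + stats$c_min
}

#' @rdname normalize_embedding
#' @export
denormalize_embedding <- function(x, stats) {
  check_matrix(x)
  check_stats(x, stats)
  if (any(stats$constant)) {
    cheap_abort("cannot invert normalization: constant channel(s) present.",
                "cheap_constant_channel")
  }
  rng <- stats$x_max - stats$x_min
  sweep(sweep(x - stats$c_min, 2, rng / (stats$c_max - stats$c_min), "*"),
        2, stats$x_min, "+")
}

#' Diagnose massive activations
#'
#' Summarizes a collection of layer outputs the way outlier channels are
#' diagnosed in pLM latents: per-channel means, the `k` largest absolute
#' activations anywhere in the collection (with their channel), and the
#' median absolute activation, whose ratio to the top magnitudes quantifies
#' how pathological the latent space is.
#'
#' @param layer_outputs A `cheap_dataset`, list of matrices, or matrix.
#' @param k How many top magnitudes to report (default 3).
#' @param masks Optional masks; padded positions are ignored.
#' @return An object of class `activation_report` with fields
#'   `per_channel_mean`, `top_k` (tibble: channel, value), and
#'   `median_magnitude`.
#' @export
activation_report <- function(layer_outputs, k = 3, masks = NULL) {
  el <- as_embedding_list(layer_outputs, masks)
  rows <- do.call(rbind, Map(function(e, m) e[m > 0, , drop = FALSE],
                             el$embeddings, el$masks))
  if (is.null(rows) || nrow(rows) == 0L) {
    cheap_abort("no valid positions in `layer_outputs`.", "cheap_empty_input")
  }
  a <- abs(rows)
  # top-k absolute activations, reported with the channel they occur in
  chan_max <- apply(a, 2, max)
  ord <- order(chan_max, decreasing = TRUE)[seq_len(min(k, ncol(a)))]
  structure(
    list(per_channel_mean = colMeans(rows),
         top_k = tibble::tibble(channel = ord, value = chan_max[ord]),
         median_magnitude = median(a)),
    class = "activation_report"
  )
}

#' @export
print.activation_report <- function(x, ...) {
  cat(sprintf("<activation_report> %d channels, median |a| = %.4g\n",
              length(x$per_channel_mean), x$median_magnitude))
  cat("top magnitudes:\n")
  print(as.data.frame(x$top_k), row.names = FALSE)
  invisible(x)
}

#' @describeIn activation_report per-channel tibble of means and whether the
#'   channel is among the reported top-`k`.
#' @param x An `activation_report`.
#' @param ... Unused.
#' @method tidy activation_report
#' @export
tidy.activation_report <- function(x, ...) {
  tibble::tibble(channel = seq_along(x$per_channel_mean),
                 mean = x$per_channel_mean,
                 is_top = seq_along(x$per_channel_mean) %in% x$top_k$channel)
}

#' Zero out selected channels
#'
#' The outlier-channel ablation harness: returns a copy of `x` with the
#' listed channels set to zero and all others untouched (pure function).
#'
#' @param x An `L x D` matrix.
#' @param channels Integer channel indices (1-based); may be empty.
#' @return The modified copy of `x`.
#' @export
zero_channels <- function(x, channels) {
  check_matrix(x)
  channels <- as.integer(channels)
  if (length(channels) && (any(channels < 1L) || any(channels > ncol(x)))) {
    cheap_abort("`channels` contains out-of-range indices.", "cheap_bad_input")
  }
  if (length(channels)) x[, channels] <- 0
  x
}

#' @describeIn activation_report histogram of per-channel means, the
#'   standard visualization of massive activations.
#' @param object An `activation_report`.
#' @method autoplot activation_report
#' @export
autoplot.activation_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey35") +
    ggplot2::geom_rug(data = df[df$is_top, ], colour = "firebrick") +
    ggplot2::labs(x = "per-channel mean activation", y = "channels",
                  title = "Per-channel means (outlier channels rugged in red)") +
    ggplot2::theme_minimal()
}
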