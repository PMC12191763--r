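#' Linear interpolation between two latents
#'
#' Computes `x'(t) = t * x1 + (1 - t) * x2` elementwise, so `t = 1`
#' reproduces `x1` exactly and `t = 0` reproduces `x2` exactly. The
#' interpolation is agnostic to which space the latents live in (raw,
#' normalized or compressed); the caller chooses by what it passes in.
#'
#' @param x1,x2 Numeric matrices (or vectors) of identical shape.
#' @param ts Interpolation coefficients in `[0, 1]`.
#' @return An object of class `interp_trace`: list with `ts`, `latents`
#'   (one per `t`), and the endpoints.
#' @export
interpolate_latents <- function(x1, x2, ts = seq(0, 1, length.out = 11)) {
  if (!identical(dim(x1), dim(x2)) || length(x1) != length(x2)) {
    cheap_abort("`x1` and `x2` must have identical shape.", "cheap_bad_shape")
  }
  ts <- as.numeric(ts)
  if (any(ts < 0 | ts > 1)) {
    cheap_abort("`ts` must lie in [0, 1].", "cheap_bad_input")
  }
  latents <- lapply(ts, function(t) {
    if (t == 1) x1 else if (t == 0) x2 else t * x1 + (1 - t) * x2
  })
  structure(list(ts = ts, latents = latents, x1 = x1, x2 = x2),
            class = "interp_trace")
}

#' @export
print.interp_trace <- function(x, ...) {
  cat(sprintf("<interp_trace> %d interpolation points, t in [%g, %g]\n",
              length(x$ts), min(x$ts), max(x$ts)))
  invisible(x)
}

#' Randomly corrupt latent tokens
#'
#' Each valid position is independently replaced, with probability `rate`,
#' by a code drawn uniformly from `[0, C)` (the original code may be
#' redrawn, matching a literal "random token"); masked positions are never
#' touched.
#'
#' @param tokens A `tokenized_latent` (or integer vector of 0-based codes).
#' @param rate Corruption probability in `[0, 1]`.
#' @param C Codebook size (taken from the object when available).
#' @param seed Integer seed.
#' @return A `tokenized_latent` with the same mask and length.
#' @export
corrupt_tokens <- function(tokens, rate, C = NULL, seed = 1) {
  if (!is_scalar_num(rate) || rate < 0 || rate > 1) {
    cheap_abort("`rate` must be in [0, 1].", "cheap_bad_input")
  }
  if (inherits(tokens, "tokenized_latent")) {
    idx <- tokens$indices; mask <- tokens$mask
    if (is.null(C)) C <- tokens$C
  } else {
    idx <- as.integer(tokens); mask <- rep(1, length(idx))
  }
  if (is.null(C) || C < 1) cheap_abort("`C` must be a positive count.",
                                       "cheap_bad_config")
  withr::with_seed(as.integer(seed), {
    valid <- which(mask > 0 & !is.na(idx))
    hit <- valid[runif(length(valid)) < rate]
    if (length(hit)) idx[hit] <- as.integer(sample.int(C, length(hit),
                                                       replace = TRUE) - 1L)
  })
  new_tokenized_latent(idx, mask, C)
}

#' Smoothness of an interpolation trace
#'
#' Tabulates, for every interpolation point, a caller-supplied similarity
#' of the (optionally decoded) latent to both endpoints, plus a
#' monotonicity summary: the fraction of adjacent steps whose similarity to
#' the `x1` endpoint moves toward it as `t` grows (and symmetrically for
#' `x2` as `t` shrinks).
#'
#' @param trace An `interp_trace`.
#' @param similarity Function `(latent, endpoint) -> scalar`; larger must
#'   mean more similar.
#' @param decode Optional function applied to each latent (and both
#'   endpoints) before the similarity is computed — e.g. a decoder back to
#'   sequence space.
#' @return A tibble with columns `t`, `sim_to_x1`, `sim_to_x2`; the
#'   `"monotone_fraction"` attribute holds the named summary fractions.
#' @export
smoothness_curve <- function(trace, similarity, decode = NULL) {
  if (!inherits(trace, "interp_trace")) {
    cheap_abort("`trace` must be an `interp_trace`.", "cheap_bad_input")
  }
  dec <- if (is.null(decode)) identity else decode
  e1 <- dec(trace$x1); e2 <- dec(trace$x2)
  ord <- order(trace$ts)
  ts <- trace$ts[ord]
  s1 <- s2 <- numeric(length(ts))
  for (k in seq_along(ord)) {
    d <- dec(trace$latents[[ord[k]]])
    s1[k] <- similarity(d, e1)
    s2[k] <- similarity(d, e2)
  }
  out <- tibble::tibble(t = ts, sim_to_x1 = s1, sim_to_x2 = s2)
  if (length(ts) > 1) {
    mono1 <- mean(diff(s1) >= 0)          # toward x1 as t grows
    mono2 <- mean(diff(rev(s2)) >= 0)     # toward x2 as t shrinks
  } else {
    mono1 <- mono2 <- NA_real_
  }
  attr(out, "monotone_fraction") <- c(toward_x1 = mono1, toward_x2 = mono2)
  out
}

#' @describeIn smoothness_curve similarity-vs-t curves for both endpoints.
#' @param object A tibble returned by `smoothness_curve()`.
#' @param ... Unused.
#' @method autoplot interp_trace
#' @export
autoplot.interp_trace <- function(object, ...) {
  # convenience: plot latent-space distance to endpoints along t
  d1 <- vapply(object$latents, function(l) sqrt(sum((l - object$x1)^2)), numeric(1))
  d2 <- vapply(object$latents, function(l) sqrt(sum((l - object$x2)^2)), numeric(1))
  df <- tibble::tibble(t = rep(object$ts, 2),
                       distance = c(d1, d2),
                       endpoint = rep(c("x1", "x2"), each = length(object$ts)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$distance,
                                   colour = .data$endpoint)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "t", y = "latent-space distance to endpoint",
                  title = "Linear interpolation geometry") +
    ggplot2::theme_minimal()
}
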