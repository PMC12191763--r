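#' Sequence recovery accuracy
#'
#' Fraction of matching tokens between a decoded and a reference integer
#' sequence of equal length.
#'
#' @param pred,true Integer vectors of equal length.
#' @return A number in `[0, 1]`.
#' @export
sequence_recovery <- function(pred, true) {
  if (length(pred) != length(true)) {
    cheap_abort("`pred` and `true` must have equal length.", "cheap_bad_shape")
  }
  if (!length(pred)) cheap_abort("empty sequences.", "cheap_empty_input")
  mean(pred == true)
}

check_coords <- function(a, name = "a", min_n = 1L) {
  if (!is.matrix(a) || ncol(a) != 3 || !is.numeric(a)) {
    cheap_abort(sprintf("`%s` must be an N x 3 coordinate matrix.", name),
                "cheap_bad_input")
  }
  if (nrow(a) < min_n) {
    cheap_abort(sprintf("`%s` needs at least %d atoms.", name, min_n),
                "cheap_bad_input")
  }
  if (!all(is.finite(a))) cheap_abort(sprintf("`%s` has non-finite coordinates.", name),
                                      "cheap_bad_input")
  a
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rotation + translation of `a` onto `b` via SVD of the
#' cross-covariance, with the determinant correction that excludes
#' reflections.
#'
#' @param a,b `N x 3` coordinate matrices with corresponding rows.
#' @param weights Optional non-negative per-atom weights.
#' @return List with the transformed copy of `a` (`coords`), the `rotation`
#'   and `translation` applied.
#' @export
kabsch <- function(a, b, weights = NULL) {
  check_coords(a); check_coords(b, "b")
  if (nrow(a) != nrow(b)) cheap_abort("atom counts differ.", "cheap_bad_shape")
  w <- if (is.null(weights)) rep(1, nrow(a)) else weights
  w <- w / sum(w)
  ca <- colSums(a * w); cb <- colSums(b * w)
  A <- sweep(a, 2, ca); B <- sweep(b, 2, cb)
  H <- crossprod(A * w, B)
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  coords <- sweep(A %*% t(R), 2, cb, "+")
  list(coords = coords, rotation = R, translation = cb - as.vector(R %*% ca))
}

#' Root-mean-square deviation between paired atoms
#'
#' With `superimpose = TRUE` (default) an optimal rigid-body superposition
#' (Kabsch) is applied first, so rigid motions score 0; without it the raw
#' paired deviation is returned. Superposed RMSD never exceeds the
#' unsuperposed value.
#'
#' @param a,b `N x 3` coordinate matrices, rows in correspondence.
#' @param superimpose Superimpose before measuring (needs `N >= 3`).
#' @return RMSD in the coordinate units (Angstroms for structures).
#' @export
rmsd <- function(a, b, superimpose = TRUE) {
  check_coords(a); check_coords(b, "b")
  if (nrow(a) != nrow(b)) cheap_abort("atom counts differ.", "cheap_bad_shape")
  if (superimpose) {
    if (nrow(a) < 3) cheap_abort("superposition needs at least 3 atoms.",
                                 "cheap_bad_input")
    a <- kabsch(a, b)$coords
  }
  sqrt(mean(rowSums((a - b)^2)))
}

#' Root-mean-square paired-distance deviation (RMSPD)
#'
#' Compares all intra-structure pairwise distances `d(i, j)`, `i < j`,
#' between two structures; superposition-free by construction and therefore
#' invariant under rigid motions of either argument (and blind to
#' chirality: mirror images score 0 — a documented limitation).
#'
#' @param a,b `N x 3` coordinate matrices with `N >= 2`, rows in
#'   correspondence.
#' @return RMS deviation of pairwise distances.
#' @export
rmspd <- function(a, b) {
  check_coords(a, min_n = 2L); check_coords(b, "b", min_n = 2L)
  if (nrow(a) != nrow(b)) cheap_abort("atom counts differ.", "cheap_bad_shape")
  da <- dist(a); db <- dist(b)
  sqrt(mean((da - db)^2))
}

#' TM-score normalization distance
#'
#' `d0(L) = 1.24 * (L - 15)^(1/3) - 1.8`, clamped below at 0.5 (which also
#' covers `L <= 15`, where the formula is undefined or negative).
#'
#' @param L Number of residues.
#' @return `d0` in Angstroms.
#' @export
tm_d0 <- function(L) {
  if (L <= 15) return(0.5)
  max(0.5, 1.24 * (L - 15)^(1 / 3) - 1.8)
}

#' TM-score between aligned backbones
#'
#' Length-normalized backbone similarity in `(0, 1]`:
#' `max over superpositions of mean(1 / (1 + (d_i / d0)^2))` with the
#' standard `d0(L)`. Residue correspondence is assumed (reconstruction
#' pairs share it), so no alignment search is performed; the maximization
#' over superpositions uses iteratively reweighted Kabsch fits (weights
#' `1 / (1 + (d_i/d0)^2)^2`, the stationary condition of the score), and
#' the best score seen is returned. Normalization length is the length of
#' `b` (the target/reference).
#'
#' @param a,b `N x 3` backbone (CA) coordinates, `N >= 3`.
#' @param max_iter Reweighting iterations.
#' @return TM-score in `(0, 1]`; identical structures score exactly 1.
#' @export
tm_score <- function(a, b, max_iter = 20) {
  check_coords(a, min_n = 3L); check_coords(b, "b", min_n = 3L)
  if (nrow(a) != nrow(b)) cheap_abort("residue counts differ.", "cheap_bad_shape")
  L <- nrow(b)
  d0 <- tm_d0(L)
  score_of <- function(coords) {
    d2 <- rowSums((coords - b)^2)
    mean(1 / (1 + d2 / d0^2))
  }
  w <- rep(1, L)
  best <- -Inf
  for (it in seq_len(max_iter)) {
    fit <- kabsch(a, b, weights = w)
    s <- score_of(fit$coords)
    if (s > best) best <- s
    d2 <- rowSums((fit$coords - b)^2)
    w_new <- 1 / (1 + d2 / d0^2)^2
    if (sum(w_new) < 1e-12) break
    if (max(abs(w_new / sum(w_new) - w / sum(w))) < 1e-10) break
    w <- w_new
  }
  best
}

#' Reconstruction report for a trained model over a dataset
#'
#' Runs the autoencoder on every sample and tabulates, per sample, the
#' masked reconstruction MSE (in normalized space), the compression
#' geometry, per-sample latent statistics, and — when a sequence decoder is
#' supplied and the dataset carries labels — the sequence recovery accuracy
#' of tokens decoded from the reconstruction. Structure columns (TM-score,
#' RMSD, RMSPD against `coords`) are populated only when the dataset carries
#' coordinates and `reference_coords` decoding is provided by the caller;
#' the metric functions themselves are exported for direct use.
#'
#' @param model A trained `hpct_model`.
#' @param data A `cheap_dataset`.
#' @param seq_decoder Optional `seq_decoder` applied to the reconstructed
#'   (denormalized) embeddings.
#' @return A tibble with one row per sample; aggregate (mask-weighted)
#'   means are attached as the `"aggregate"` attribute.
#' @export
reconstruction_report <- function(model, data, seq_decoder = NULL) {
  stopifnot(inherits(model, "hpct_model"))
  el <- as_embedding_list(data)
  labels <- if (inherits(data, "cheap_dataset")) data$labels else NULL
  n <- length(el$embeddings)
  rows <- vector("list", n)
  tot_se <- 0; tot_n <- 0
  for (i in seq_len(n)) {
    x <- el$embeddings[[i]]; m <- el$masks[[i]]
    xn <- if (is.null(model$stats)) x else normalize_embedding(x, model$stats)
    lat <- hpct_encode(model, x, m)
    rec <- hpct_decode(model, lat, denormalized = FALSE)
    mse <- masked_mse(xn, rec, m)
    nv <- sum(m) * ncol(x)
    tot_se <- tot_se + mse * nv; tot_n <- tot_n + nv
    seq_acc <- NA_real_
    if (!is.null(seq_decoder) && !is.null(labels)) {
      rec_orig <- if (is.null(model$stats)) rec else denormalize_embedding(rec, model$stats)
      pred <- predict(seq_decoder, rec_orig)
      seq_acc <- sequence_recovery(pred[m > 0], labels[[i]][m > 0])
    }
    rows[[i]] <- tibble::tibble(
      sample = i, length = nrow(x), latent_positions = nrow(lat$values),
      latent_channels = ncol(lat$values),
      compression = (nrow(x) * ncol(x)) / (nrow(lat$values) * ncol(lat$values)),
      masked_mse = mse, latent_mean = mean(lat$values[lat$mask > 0, ]),
      latent_sd = sd(lat$values[lat$mask > 0, ]),
      sequence_recovery = seq_acc
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "aggregate") <- tibble::tibble(
    masked_mse = tot_se / tot_n,
    sequence_recovery = mean(out$sequence_recovery))
  out
}
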