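#' Training configuration
#'
#' AdamW (decoupled weight decay) with a linear warmup to the target
#' learning rate, constant afterwards. The defaults mirror the settings used
#' for full-scale continuous compression models (`8e-5`, 5000 warmup steps);
#' `preset = "discrete"` switches to the discrete-bottleneck settings
#' (`1e-4`, 1000 warmup steps). Batch size, weight decay and total steps are
#' free parameters; desk-scale experiments in this package use much smaller
#' warmups and larger rates, set explicitly.
#'
#' @param learning_rate Target learning rate (> 0).
#' @param warmup_steps Linear warmup length (>= 0).
#' @param max_steps Total optimization steps.
#' @param batch_size Samples per step.
#' @param weight_decay Decoupled weight decay applied to weight matrices.
#' @param seed Root seed for batching and any training-time randomness.
#' @param preset `"continuous"` or `"discrete"`, setting the documented
#'   default learning rate / warmup pair; explicit arguments win.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = NULL, warmup_steps = NULL,
                         max_steps = 1000, batch_size = 8,
                         weight_decay = 0.01, seed = 1,
                         preset = c("continuous", "discrete")) {
  preset <- match.arg(preset)
  if (is.null(learning_rate)) learning_rate <- if (preset == "discrete") 1e-4 else 8e-5
  if (is.null(warmup_steps)) warmup_steps <- if (preset == "discrete") 1000 else 5000
  if (!is_scalar_num(learning_rate) || learning_rate <= 0) {
    cheap_abort("`learning_rate` must be positive.", "cheap_bad_config")
  }
  if (!is_count(warmup_steps, min = 0L)) {
    cheap_abort("`warmup_steps` must be a non-negative integer.", "cheap_bad_config")
  }
  if (!is_count(max_steps, min = 0L)) {
    cheap_abort("`max_steps` must be a non-negative integer.", "cheap_bad_config")
  }
  structure(
    list(learning_rate = learning_rate, warmup_steps = as.integer(warmup_steps),
         max_steps = as.integer(max_steps), batch_size = as.integer(batch_size),
         weight_decay = weight_decay, seed = as.integer(seed), preset = preset),
    class = "train_config"
  )
}

#' Masked mean-squared error
#'
#' Mean of squared differences over valid positions and all channels;
#' padded positions contribute nothing, whatever they contain.
#'
#' @param x,xhat `L x D` matrices of identical shape.
#' @param mask Length-`L` 0/1 validity mask with at least one valid entry.
#' @return A single non-negative number.
#' @export
masked_mse <- function(x, xhat, mask) {
  check_matrix(x); check_matrix(xhat, "xhat")
  if (!all(dim(x) == dim(xhat))) {
    cheap_abort("`x` and `xhat` must have identical shape.", "cheap_bad_shape")
  }
  mask <- check_mask(mask, nrow(x))
  nv <- sum(mask)
  if (nv == 0) cheap_abort("mask has no valid positions.", "cheap_empty_input")
  d <- (x - xhat) * mask
  sum(d * d) / (nv * ncol(x))
}

#' Train a compression model
#'
#' End-to-end masked-MSE training of the hourglass autoencoder. Per-channel
#' statistics are estimated from the training data and stored with the
#' model, and all training happens in normalized space; for discrete
#' bottlenecks the VQ auxiliary losses are added to the objective and the
#' code-selection perplexity is logged. The loss trace (one row per step) is
#' attached to the returned model. A fixed seed reproduces the trace
#' bit-for-bit on one device; `max_steps = 0` returns the initialization
#' (with statistics attached).
#'
#' @param data A `cheap_dataset` (or list of embedding matrices).
#' @param hcfg An [hourglass_config()]; `hcfg$seed` controls initialization.
#' @param tcfg A [train_config()].
#' @param stats Optional pre-computed `channel_stats`; estimated from `data`
#'   when omitted.
#' @return The trained `hpct_model`, with `$stats` and `$trace` (a tibble
#'   with columns `step`, `lr`, `loss`, `recon_mse`, and `perplexity` for VQ
#'   models).
#' @export
train_compression <- function(data, hcfg, tcfg, stats = NULL) {
  el <- as_embedding_list(data)
  if (is.null(stats)) stats <- estimate_channel_stats(el$embeddings, el$masks)
  xs <- Map(function(e, m) normalize_embedding(e, stats), el$embeddings, el$masks)
  model <- init_hourglass(hcfg)
  model$stats <- stats
  n <- length(xs)
  pads <- Map(function(x, m) pad_to_multiple(x, m, hcfg$shorten_factor),
              xs, el$masks)
  if (tcfg$max_steps == 0L) {
    model$trace <- tibble::tibble(step = integer(), lr = numeric(),
                                  loss = numeric(), recon_mse = numeric())
    return(model)
  }
  p <- model$params
  state <- adamw_init(p)
  trace <- vector("list", tcfg$max_steps)
  is_vq <- hcfg$bottleneck == "vq"
  withr::with_seed(tcfg$seed, {
    for (step in seq_len(tcfg$max_steps)) {
      batch <- sample.int(n, min(tcfg$batch_size, n), replace = n < tcfg$batch_size)
      grads <- list()
      loss_acc <- 0; recon_acc <- 0; perp_counts <- NULL
      for (i in batch) {
        pd <- pads[[i]]
        fw <- hpct_fwd(p, hcfg, pd$x, pd$mask, keep_cache = TRUE)
        nv <- sum(pd$mask)
        target <- pd$x * pd$mask
        dres <- (fw$recon - target) * pd$mask
        recon <- sum(dres * dres) / (nv * hcfg$d_model)
        loss_i <- recon
        if (length(fw$aux)) {
          loss_i <- loss_i + fw$aux$codebook_loss + fw$aux$commitment_loss
        }
        if (!is.finite(loss_i)) {
          cheap_abort(sprintf("non-finite loss at step %d (sample %d): %g",
                              step, i, loss_i), "cheap_nan_loss")
        }
        d_recon <- 2 * dres / (nv * hcfg$d_model)
        g <- hpct_bwd(p, hcfg, fw, d_recon)
        for (nm in names(g)) {
          grads[[nm]] <- if (is.null(grads[[nm]])) g[[nm]] else grads[[nm]] + g[[nm]]
        }
        loss_acc <- loss_acc + loss_i
        recon_acc <- recon_acc + recon
        if (is_vq) {
          cnt <- tabulate(fw$codes$indices[fw$codes$mask > 0] + 1L,
                          nbins = hcfg$codebook_size)
          perp_counts <- if (is.null(perp_counts)) cnt else perp_counts + cnt
        }
      }
      nb <- length(batch)
      for (nm in names(grads)) grads[[nm]] <- grads[[nm]] / nb
      lr <- lr_at_step(step, tcfg$learning_rate, tcfg$warmup_steps)
      upd <- adamw_step(p, grads, state, lr, weight_decay = tcfg$weight_decay)
      p <- upd$params; state <- upd$state
      row <- list(step = step, lr = lr, loss = loss_acc / nb,
                  recon_mse = recon_acc / nb)
      if (is_vq) row$perplexity <- vq_perplexity(perp_counts)
      trace[[step]] <- row
    }
  })
  model$params <- p
  model$trace <- dplyr::bind_rows(trace)
  model
}

#' Masked reconstruction error of a model over a dataset
#'
#' Encodes and decodes every sample (in normalized space) and returns the
#' per-sample masked MSE.
#'
#' @param model A trained `hpct_model`.
#' @param data A `cheap_dataset` or list of matrices.
#' @return Numeric vector of per-sample masked MSEs.
#' @export
eval_masked_mse <- function(model, data) {
  el <- as_embedding_list(data)
  vapply(seq_along(el$embeddings), function(i) {
    x <- el$embeddings[[i]]; m <- el$masks[[i]]
    xn <- if (is.null(model$stats)) x else normalize_embedding(x, model$stats)
    lat <- hpct_encode(model, x, m)
    rec <- hpct_decode(model, lat, denormalized = FALSE)
    masked_mse(xn, rec, m)
  }, numeric(1))
}

#' @describeIn train_compression loss trace against steps.
#' @param object A trained `hpct_model`.
#' @param ... Unused.
#' @method autoplot hpct_model
#' @export
autoplot.hpct_model <- function(object, ...) {
  if (is.null(object$trace) || !nrow(object$trace)) {
    cheap_abort("model has no training trace to plot.", "cheap_bad_input")
  }
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$step, y = .data$loss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "step", y = "loss (log scale)",
                  title = "Hourglass training loss") +
    ggplot2::theme_minimal()
}

## ---- sequence decoder head ----

#' Train the per-residue sequence decoder head
#'
#' A fully connected head with two affine layers (hidden width 1024, GELU)
#' and exactly 21 output classes (20 amino acids plus the unknown
#' placeholder), trained with cross-entropy on per-position token labels and
#' evaluated on a seeded random 90/10 per-protein holdout split.
#'
#' @param embeddings A `cheap_dataset` or list of `L x D` matrices.
#' @param labels List of integer label vectors in `[0, 21)` (taken from the
#'   dataset when omitted).
#' @param hidden Hidden width (default 1024).
#' @param epochs Passes over the training positions.
#' @param batch_size Minibatch size (positions).
#' @param learning_rate AdamW learning rate.
#' @param holdout Fraction of proteins held out.
#' @param seed Seed for the split, init and batching.
#' @return An object of class `seq_decoder` with the weights, a per-epoch
#'   `trace` tibble and `holdout_accuracy`.
#' @export
train_sequence_decoder <- function(embeddings, labels = NULL, hidden = 1024,
                                   epochs = 30, batch_size = 512,
                                   learning_rate = 1e-3, holdout = 0.1,
                                   seed = 1) {
  if (inherits(embeddings, "cheap_dataset") && is.null(labels)) {
    labels <- embeddings$labels
  }
  el <- as_embedding_list(embeddings)
  if (is.null(labels) || length(labels) != length(el$embeddings)) {
    cheap_abort("one label vector per sample is required.", "cheap_bad_input")
  }
  lab_all <- unlist(labels)
  if (any(lab_all < 0 | lab_all >= 21)) {
    cheap_abort("labels must be integers in [0, 21).", "cheap_bad_label")
  }
  D <- ncol(el$embeddings[[1]])
  n_prot <- length(el$embeddings)
  withr::with_seed(as.integer(seed), {
    ho <- sample.int(n_prot, max(1, round(holdout * n_prot)))
    tr_idx <- setdiff(seq_len(n_prot), ho)
    stack <- function(ids) {
      list(x = do.call(rbind, Map(function(e, m) e[m > 0, , drop = FALSE],
                                  el$embeddings[ids], el$masks[ids])),
           y = unlist(Map(function(l, m) l[m > 0], labels[ids], el$masks[ids])))
    }
    tr <- stack(tr_idx); te <- stack(ho)
    # per-channel centering plus one global scale, fitted on the training
    # positions: centering removes the huge constant means of outlier
    # channels (which would saturate the head at initialization) while a
    # single scale preserves the relative variances of the channels
    feat_mean <- colMeans(tr$x)
    feat_sd <- rep(max(sqrt(mean(apply(tr$x, 2, var))), 1e-8), ncol(tr$x))
    std <- function(x) sweep(sweep(x, 2, feat_mean, "-"), 2, feat_sd, "/")
    tr$x <- std(tr$x); te$x <- std(te$x)
    W1 <- rmat(D, hidden, sd = sqrt(2 / D)); b1 <- rep(0, hidden)
    W2 <- rmat(hidden, 21, sd = sqrt(2 / hidden)); b2 <- rep(0, 21)
    params <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
    state <- adamw_init(params)
    n_tr <- nrow(tr$x)
    trace <- vector("list", epochs)
    stepc <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n_tr)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1, n_tr, by = batch_size)) {
        ids <- ord[start:min(start + batch_size - 1, n_tr)]
        fb <- mlp_ce_step(params, tr$x[ids, , drop = FALSE], tr$y[ids])
        stepc <- stepc + 1L
        upd <- adamw_step(params, fb$grads, state, learning_rate,
                          weight_decay = 0)
        params <- upd$params; state <- upd$state
        ep_loss <- ep_loss + fb$loss; nb <- nb + 1L
      }
      acc <- mean(mlp_predict(params, te$x) == te$y)
      trace[[ep]] <- list(epoch = ep, loss = ep_loss / nb, holdout_accuracy = acc)
    }
    structure(
      list(params = params, hidden = hidden, n_classes = 21L,
           feat_mean = feat_mean, feat_sd = feat_sd,
           trace = dplyr::bind_rows(trace),
           holdout_accuracy = trace[[epochs]]$holdout_accuracy),
      class = "seq_decoder"
    )
  })
}

# one cross-entropy forward/backward over a minibatch of positions
mlp_ce_step <- function(p, x, y) {
  h <- add_rowvec(x %*% p$W1, p$b1)
  ge <- gelu_fwd(h)
  logits <- add_rowvec(ge$y %*% p$W2, p$b2)
  lse <- logits - apply(logits, 1, max)
  el <- exp(lse)
  probs <- el / rowSums(el)
  n <- nrow(x)
  pick <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(probs[pick], 1e-12)))
  dlog <- probs
  dlog[pick] <- dlog[pick] - 1
  dlog <- dlog / n
  dW2 <- crossprod(ge$y, dlog); db2 <- colSums(dlog)
  dge <- tcrossprod(dlog, p$W2)
  dh <- gelu_bwd(dge, ge$cache)
  dW1 <- crossprod(x, dh); db1 <- colSums(dh)
  list(loss = loss, grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

mlp_logits <- function(p, x) {
  h <- add_rowvec(x %*% p$W1, p$b1)
  add_rowvec(gelu_fwd(h)$y %*% p$W2, p$b2)
}

mlp_predict <- function(p, x) max.col(mlp_logits(p, x), ties.method = "first") - 1L

#' @export
print.seq_decoder <- function(x, ...) {
  cat(sprintf("<seq_decoder> 2-layer head, hidden %d, 21 classes, holdout accuracy %.3f\n",
              x$hidden, x$holdout_accuracy))
  invisible(x)
}

#' Predict token labels from embeddings
#'
#' @param object A `seq_decoder`.
#' @param newdata An `L x D` matrix (or list of them).
#' @param type `"class"` for integer labels in `[0, 21)` or `"logits"` for
#'   the `L x 21` score matrix.
#' @param ... Unused.
#' @return Labels or logits, mirroring the structure of `newdata`.
#' @export
predict.seq_decoder <- function(object, newdata, type = c("class", "logits"), ...) {
  type <- match.arg(type)
  one <- function(x) {
    check_matrix(x)
    x <- sweep(sweep(x, 2, object$feat_mean, "-"), 2, object$feat_sd, "/")
    if (type == "logits") mlp_logits(object$params, x)
    else mlp_predict(object$params, x)
  }
  if (is.list(newdata) && !is.matrix(newdata)) lapply(newdata, one) else one(newdata)
}

#' @describeIn train_sequence_decoder one-row summary.
#' @param x A `seq_decoder`.
#' @method glance seq_decoder
#' @export
glance.seq_decoder <- function(x, ...) {
  tibble::tibble(hidden = x$hidden, n_classes = x$n_classes,
                 epochs = nrow(x$trace), holdout_accuracy = x$holdout_accuracy)
}

## ---- linear probe harness ----

#' Probe compressed latents for a per-protein target
#'
#' Mean-pools each latent over its valid positions, projects back to width
#' 1024 with a trainable linear layer (so the downstream network has the
#' same capacity regardless of compression level), and fits a 2-layer MLP
#' probe. Regression tasks report R-squared and Spearman correlation on the
#' holdout proteins; classification tasks report accuracy.
#'
#' @param compressed List of `compressed_latent` objects, or a list of
#'   matrices with masks all-valid, or a pre-pooled `n x d` matrix.
#' @param targets Numeric vector (regression) or integer class labels
#'   (classification), one per protein.
#' @param task `"regression"` or `"classification"`.
#' @param hidden Probe hidden width.
#' @param epochs Full-batch AdamW iterations.
#' @param learning_rate Probe learning rate.
#' @param holdout Holdout fraction.
#' @param seed Seed for split and initialization.
#' @return An object of class `linear_probe` with `$metric` (named numeric:
#'   `r_squared` and `spearman`, or `accuracy`) and `$predictions` tibble.
#' @export
linear_probe <- function(compressed, targets,
                         task = c("regression", "classification"),
                         hidden = 64, epochs = 300, learning_rate = 3e-3,
                         holdout = 0.2, seed = 1) {
  task <- match.arg(task)
  X <- pool_latents(compressed)
  if (nrow(X) != length(targets)) {
    cheap_abort("one target per protein is required.", "cheap_bad_input")
  }
  n <- nrow(X)
  withr::with_seed(as.integer(seed), {
    ho <- sample.int(n, max(1, round(holdout * n)))
    tr <- setdiff(seq_len(n), ho)
    # center pooled features and apply one global scale, fitted on the
    # training proteins: centering removes the constant offsets of outlier
    # channels (which saturate the probe otherwise); a per-feature scale
    # would instead inflate low-variance noise directions
    fm <- colMeans(X[tr, , drop = FALSE])
    fs <- max(sqrt(mean(apply(X[tr, , drop = FALSE], 2, var))), 1e-8)
    X <- sweep(X, 2, fm, "-") / fs
    d <- ncol(X)
    # regression targets are standardized on the training split as well
    # (outlier channels push a large constant into pooled-feature targets);
    # predictions are mapped back before metrics, leaving R^2 untouched
    ym <- 0; ys <- 1
    if (task == "regression") {
      ym <- mean(targets[tr]); ys <- max(sd(targets[tr]), 1e-8)
    }
    fit_targets <- if (task == "regression") (targets - ym) / ys else targets
    n_out <- if (task == "regression") 1L else length(unique(targets))
    params <- list(Wp = rmat(d, 1024, sd = sqrt(1 / d)),
                   W1 = rmat(1024, hidden, sd = sqrt(2 / 1024)), b1 = rep(0, hidden),
                   W2 = rmat(hidden, n_out, sd = sqrt(2 / hidden)), b2 = rep(0, n_out))
    state <- adamw_init(params)
    Xtr <- X[tr, , drop = FALSE]
    for (it in seq_len(epochs)) {
      fb <- probe_step(params, Xtr, fit_targets[tr], task)
      upd <- adamw_step(params, fb$grads, state, learning_rate, weight_decay = 0)
      params <- upd$params; state <- upd$state
    }
    pred <- probe_forward(params, X[ho, , drop = FALSE])$out
    if (task == "regression") {
      pred[, 1] <- pred[, 1] * ys + ym
      y <- targets[ho]
      ss_res <- sum((y - pred[, 1])^2)
      ss_tot <- sum((y - mean(y))^2)
      metric <- c(r_squared = 1 - ss_res / ss_tot,
                  spearman = suppressWarnings(
                    stats::cor(y, pred[, 1], method = "spearman")))
      predictions <- tibble::tibble(protein = ho, truth = y, estimate = pred[, 1])
    } else {
      cls <- max.col(pred, ties.method = "first") - 1L
      metric <- c(accuracy = mean(cls == targets[ho]))
      predictions <- tibble::tibble(protein = ho, truth = targets[ho], estimate = cls)
    }
    structure(list(task = task, metric = metric, predictions = predictions,
                   n_train = length(tr), n_holdout = length(ho)),
              class = "linear_probe")
  })
}

pool_latents <- function(compressed) {
  if (is.matrix(compressed)) return(compressed)
  rows <- lapply(compressed, function(ci) {
    if (inherits(ci, "compressed_latent")) {
      colSums(ci$values * ci$mask) / max(sum(ci$mask), 1)
    } else if (is.matrix(ci)) {
      colMeans(ci)
    } else {
      cheap_abort("`compressed` must contain compressed latents or matrices.",
                  "cheap_bad_input")
    }
  })
  do.call(rbind, rows)
}

probe_forward <- function(p, X) {
  z <- X %*% p$Wp
  h <- add_rowvec(z %*% p$W1, p$b1)
  ge <- gelu_fwd(h)
  list(out = add_rowvec(ge$y %*% p$W2, p$b2), z = z, ge = ge)
}

probe_step <- function(p, X, y, task) {
  fw <- probe_forward(p, X)
  n <- nrow(X)
  if (task == "regression") {
    r <- fw$out[, 1] - y
    loss <- mean(r^2)
    dout <- matrix(2 * r / n, ncol = 1)
  } else {
    logits <- fw$out
    lse <- logits - apply(logits, 1, max)
    el <- exp(lse); probs <- el / rowSums(el)
    pick <- cbind(seq_len(n), y + 1L)
    loss <- -mean(log(pmax(probs[pick], 1e-12)))
    dout <- probs; dout[pick] <- dout[pick] - 1; dout <- dout / n
  }
  dW2 <- crossprod(fw$ge$y, dout); db2 <- colSums(dout)
  dge <- tcrossprod(dout, p$W2)
  dh <- gelu_bwd(dge, fw$ge$cache)
  dW1 <- crossprod(fw$z, dh); db1 <- colSums(dh)
  dz <- tcrossprod(dh, p$W1)
  dWp <- crossprod(X, dz)
  list(loss = loss,
       grads = list(Wp = dWp, W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

#' @export
print.linear_probe <- function(x, ...) {
  cat(sprintf("<linear_probe> %s over %d train / %d holdout proteins\n",
              x$task, x$n_train, x$n_holdout))
  print(round(x$metric, 4))
  invisible(x)
}

#' @describeIn linear_probe one-row metric summary.
#' @param x A `linear_probe`.
#' @param ... Unused.
#' @method glance linear_probe
#' @export
glance.linear_probe <- function(x, ...) {
  tibble::as_tibble(as.list(x$metric)) |>
    dplyr::mutate(task = x$task, n_train = x$n_train, n_holdout = x$n_holdout)
}

## ---- checkpointing ----

#' Save / load a model checkpoint
#'
#' A checkpoint is a single-file archive bundling the weights, the
#' `hourglass_config`, the `channel_stats` and the training trace; writes
#' are atomic (write-temp-then-rename).
#'
#' @param model An `hpct_model`.
#' @param path Destination file.
#' @return `save_checkpoint()` the path, invisibly; `read_checkpoint()` the
#'   restored `hpct_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "hpct_model"))
  write_atomic(function(tmp) saveRDS(model, tmp), path)
}

#' @rdname save_checkpoint
#' @export
read_checkpoint <- function(path) {
  if (!file.exists(path)) {
    cheap_abort(sprintf("checkpoint '%s' does not exist.", path), "cheap_io_error")
  }
  model <- tryCatch(readRDS(path), error = function(e) {
    cheap_abort(sprintf("failed to read checkpoint '%s': %s", path,
                        conditionMessage(e)), "cheap_io_error")
  })
  if (!inherits(model, "hpct_model")) {
    cheap_abort("file does not contain an hourglass checkpoint.", "cheap_io_error")
  }
  model
}
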