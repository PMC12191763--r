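# Container, sidecar and structure/sequence I/O.
#
# The embedding container keeps the array schema used by array stores
# (`embeddings` [N x Lmax x D], `lengths` [N], optional `labels` [N x Lmax])
# in a single RDS file; all writes are atomic.

CONTAINER_KEYS <- c("embeddings", "lengths")

#' Write / read an embedding container
#'
#' Samples are padded to the batch maximum with zeros; a `lengths` index
#' records validity (zero is the pad value everywhere). The reader
#' reconstructs the ragged list honoring `lengths` and validates shapes;
#' a missing required key or a length exceeding the padded dimension is an
#' explicit error.
#'
#' @param data A `cheap_dataset` or list of `L x D` matrices.
#' @param path Destination/source file path.
#' @param labels Optional list of per-residue label vectors.
#' @param seed Optional seed echoed into the container header.
#' @return `write_embedding_container()` the path, invisibly;
#'   `read_embedding_container()` a `cheap_dataset`.
#' @export
write_embedding_container <- function(data, path, labels = NULL, seed = NULL) {
  el <- as_embedding_list(data)
  if (inherits(data, "cheap_dataset") && is.null(labels)) labels <- data$labels
  n <- length(el$embeddings)
  lengths <- vapply(el$embeddings, nrow, integer(1))
  D <- ncol(el$embeddings[[1]])
  Lmax <- max(lengths)
  arr <- array(0, dim = c(n, Lmax, D))
  lab <- if (!is.null(labels)) matrix(NA_integer_, n, Lmax) else NULL
  for (i in seq_len(n)) {
    arr[i, seq_len(lengths[i]), ] <- el$embeddings[[i]]
    if (!is.null(lab)) lab[i, seq_len(lengths[i])] <- as.integer(labels[[i]])
  }
  obj <- list(embeddings = arr, lengths = lengths, labels = lab,
              header = list(n_channels = D, created = "cheap",
                            seed = if (is.null(seed)) NA_integer_ else as.integer(seed)))
  write_atomic(function(tmp) saveRDS(obj, tmp), path)
}

#' @rdname write_embedding_container
#' @export
read_embedding_container <- function(path) {
  if (!file.exists(path)) {
    cheap_abort(sprintf("container '%s' does not exist.", path), "cheap_io_error")
  }
  obj <- tryCatch(readRDS(path), error = function(e) {
    cheap_abort(sprintf("failed to parse container '%s': %s", path,
                        conditionMessage(e)), "cheap_io_error")
  })
  for (key in CONTAINER_KEYS) {
    if (is.null(obj[[key]])) {
      cheap_abort(sprintf("container is missing required key '%s'.", key),
                  "cheap_missing_key")
    }
  }
  arr <- obj$embeddings
  if (length(dim(arr)) != 3) {
    cheap_abort("`embeddings` must be an N x Lmax x D array.", "cheap_bad_shape")
  }
  lengths <- as.integer(obj$lengths)
  if (length(lengths) != dim(arr)[1]) {
    cheap_abort("`lengths` does not match the number of samples.", "cheap_bad_shape")
  }
  if (any(lengths > dim(arr)[2])) {
    cheap_abort("`lengths` exceed the padded length dimension.", "cheap_bad_shape")
  }
  embeddings <- lapply(seq_along(lengths), function(i) {
    matrix(arr[i, seq_len(lengths[i]), ], nrow = lengths[i], ncol = dim(arr)[3])
  })
  labels <- NULL
  if (!is.null(obj$labels)) {
    labels <- lapply(seq_along(lengths), function(i) {
      as.integer(obj$labels[i, seq_len(lengths[i])])
    })
  }
  out <- list(embeddings = embeddings,
              masks = lapply(lengths, function(L) rep(1, L)),
              labels = labels, coords = NULL, config = obj$header)
  class(out) <- "cheap_dataset"
  out
}

#' Serialize channel statistics as a JSON sidecar
#'
#' @param stats A `channel_stats` object.
#' @param path Destination/source `.json` path.
#' @return The path (write) or the restored `channel_stats` (read).
#' @export
write_channel_stats <- function(stats, path) {
  stopifnot(inherits(stats, "channel_stats"))
  payload <- list(x_min = stats$x_min, x_max = stats$x_max,
                  c_min = stats$c_min, c_max = stats$c_max,
                  n_samples_used = stats$n_samples_used)
  write_atomic(function(tmp) {
    jsonlite::write_json(payload, tmp, digits = NA, auto_unbox = TRUE)
  }, path)
}

#' @rdname write_channel_stats
#' @export
read_channel_stats <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(x_min = as.numeric(obj$x_min), x_max = as.numeric(obj$x_max),
         c_min = obj$c_min, c_max = obj$c_max,
         constant = (as.numeric(obj$x_max) - as.numeric(obj$x_min)) < 1e-12,
         n_samples_used = obj$n_samples_used),
    class = "channel_stats"
  )
}

#' Compress an embedding container through a trained model
#'
#' Reads a container, encodes every sample, and writes a compressed
#' container (continuous values or integer tokens, reduced masks, and a
#' header recording `S`, `K`, the bottleneck kind and a digest of the
#' channel statistics). The reported storage reduction factor per protein
#' is `(L * D) / (L' * d_c)`.
#'
#' @param model A trained `hpct_model` (or path to its checkpoint).
#' @param in_path Path to an embedding container.
#' @param out_path Destination for the compressed container.
#' @return A tibble summary (one row per protein, with the reduction
#'   factor), invisibly; the `"mean_reduction"` attribute aggregates it.
#' @export
compress_file <- function(model, in_path, out_path) {
  if (is.character(model)) model <- read_checkpoint(model)
  stopifnot(inherits(model, "hpct_model"))
  ds <- read_embedding_container(in_path)
  D <- ncol(ds$embeddings[[1]])
  if (D != model$cfg$d_model) {
    cheap_abort(sprintf("container has %d channels; model expects %d.",
                        D, model$cfg$d_model), "cheap_channel_mismatch")
  }
  lat <- lapply(seq_along(ds$embeddings), function(i) {
    hpct_encode(model, ds$embeddings[[i]], ds$masks[[i]])
  })
  stats_digest <- if (is.null(model$stats)) NA_character_ else {
    sprintf("%.8g/%.8g", sum(model$stats$x_min), sum(model$stats$x_max))
  }
  obj <- list(
    values = lapply(lat, function(l) l$values),
    codes = lapply(lat, function(l) if (is.null(l$codes)) NULL else l$codes$indices),
    masks = lapply(lat, function(l) l$mask),
    lengths = vapply(lat, function(l) l$length, integer(1)),
    header = list(S = model$cfg$shorten_factor, K = model$cfg$downproject_factor,
                  d_c = model$cfg$d_c, bottleneck = model$cfg$bottleneck,
                  stats_digest = stats_digest)
  )
  write_atomic(function(tmp) saveRDS(obj, tmp), out_path)
  summary <- tibble::tibble(
    sample = seq_along(lat),
    length = vapply(lat, function(l) l$length, integer(1)),
    latent_positions = vapply(lat, function(l) nrow(l$values), integer(1)),
    reduction = vapply(lat, function(l) {
      (l$length * D) / (nrow(l$values) * ncol(l$values))
    }, numeric(1))
  )
  attr(summary, "mean_reduction") <- mean(summary$reduction)
  invisible(summary)
}

#' Stream embeddings from a provider through a validated contract
#'
#' The seam where real pLM latents would enter: a provider is any function
#' returning a list with `embeddings` (list of `L x D` matrices) and
#' optionally `masks`. The contract validates the channel width so that
#' synthetic and real providers behave identically downstream; the core
#' never imports the provider's internals.
#'
#' @param provider A function of no arguments returning the bundle.
#' @param n_channels Required channel width `D` (default 1024).
#' @return A validated bundle (list with `embeddings` and `masks`).
#' @export
adapter_interface <- function(provider, n_channels = 1024) {
  if (!is.function(provider)) cheap_abort("`provider` must be a function.",
                                          "cheap_bad_input")
  bundle <- provider()
  el <- as_embedding_list(bundle$embeddings, bundle$masks)
  bad <- vapply(el$embeddings, ncol, integer(1)) != n_channels
  if (any(bad)) {
    cheap_abort(sprintf("provider emitted %d channels; %d required.",
                        ncol(el$embeddings[[which(bad)[1]]]), n_channels),
                "cheap_channel_mismatch")
  }
  el
}

## ---- sequence / structure formats ----

CHEAP_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

#' Export integer token labels as FASTA
#'
#' Labels in `[0, 21)` map onto the fixed 21-letter alphabet (20 amino
#' acids plus `'X'` for the unknown placeholder).
#'
#' @param labels List of integer vectors in `[0, 21)`.
#' @param path Destination FASTA path.
#' @param names Optional sequence names.
#' @return The path, invisibly.
#' @export
labels_to_fasta <- function(labels, path, names = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    cheap_abort("Biostrings is required for FASTA export.", "cheap_missing_dep")
  }
  if (is.numeric(labels)) labels <- list(labels)
  bad <- vapply(labels, function(l) any(l < 0 | l >= 21), logical(1))
  if (any(bad)) cheap_abort("labels must be integers in [0, 21).", "cheap_bad_label")
  seqs <- vapply(labels, function(l) paste(CHEAP_ALPHABET[l + 1L], collapse = ""),
                 character(1))
  if (is.null(names)) names <- sprintf("sample_%d", seq_along(seqs))
  x <- Biostrings::AAStringSet(seqs)
  names(x) <- names
  write_atomic(function(tmp) Biostrings::writeXStringSet(x, tmp), path)
}

#' Write / read CA-only coordinates as PDB
#'
#' Single chain `A`, one CA atom per residue, fixed-column PDB records.
#'
#' @param coords `N x 3` coordinate matrix.
#' @param path PDB file path.
#' @return The path (write) or an `N x 3` matrix (read).
#' @export
write_structure_pdb <- function(coords, path) {
  check_coords(coords)
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    cheap_abort("bio3d is required for PDB output.", "cheap_missing_dep")
  }
  n <- nrow(coords)
  write_atomic(function(tmp) {
    bio3d::write.pdb(
      file = tmp, xyz = as.vector(t(coords)),
      type = rep("ATOM", n), eleno = seq_len(n), elety = rep("CA", n),
      resid = rep("ALA", n), chain = rep("A", n), resno = seq_len(n)
    )
  }, path)
}

#' @rdname write_structure_pdb
#' @export
read_structure_pdb <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    cheap_abort("bio3d is required for PDB input.", "cheap_missing_dep")
  }
  pdb <- bio3d::read.pdb(path)
  matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("x", "y", "z")))
}

#' Read a strict YAML run configuration
#'
#' Top-level keys are restricted to `seed`, `verbosity`, `paths`,
#' `synthetic`, `model` and `train`; unknown keys are rejected so that
#' typos fail loudly rather than silently falling back to defaults.
#'
#' @param path YAML file path.
#' @return A named list of configuration sections.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("seed", "verbosity", "paths", "synthetic", "model", "train")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    cheap_abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
                "cheap_bad_config")
  }
  section_keys <- list(
    synthetic = names(formals(synthetic_config)),
    model = names(formals(hourglass_config)),
    train = names(formals(train_config))
  )
  for (sec in names(section_keys)) {
    if (!is.null(cfg[[sec]])) {
      bad <- setdiff(names(cfg[[sec]]), section_keys[[sec]])
      if (length(bad)) {
        cheap_abort(sprintf("unknown key(s) in `%s`: %s", sec,
                            paste(bad, collapse = ", ")), "cheap_bad_config")
      }
    }
  }
  cfg
}
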