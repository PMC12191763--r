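# internal helpers shared across modules

# stop with a classed condition so callers/tests can match on class
cheap_abort <- function(msg, class = "cheap_error", ...) {
  rlang::abort(msg, class = c(class, "cheap_error"), ...)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == as.integer(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# coerce 0/1-ish mask to numeric vector, validating values
check_mask <- function(mask, len = NULL) {
  m <- as.numeric(mask)
  if (!all(m %in% c(0, 1))) {
    cheap_abort("`mask` must contain only 0/1 values.", "cheap_bad_mask")
  }
  if (!is.null(len) && length(m) != len) {
    cheap_abort(
      sprintf("`mask` has length %d but %d positions were expected.", length(m), len),
      "cheap_bad_mask"
    )
  }
  m
}

check_matrix <- function(x, name = "x") {
  if (!is.matrix(x) || !is.numeric(x)) {
    cheap_abort(sprintf("`%s` must be a numeric matrix (positions x channels).", name),
                "cheap_bad_input")
  }
  x
}

# accept a dataset object, list of matrices, or a single matrix; return list of
# matrices plus matching list of masks (all-ones when absent)
as_embedding_list <- function(x, masks = NULL) {
  if (inherits(x, "cheap_dataset")) {
    return(list(embeddings = x$embeddings, masks = x$masks))
  }
  if (is.matrix(x)) x <- list(x)
  if (!is.list(x) || !length(x) || !all(vapply(x, is.matrix, logical(1)))) {
    cheap_abort("expected a `cheap_dataset`, a matrix, or a list of matrices.",
                "cheap_bad_input")
  }
  if (is.null(masks)) {
    masks <- lapply(x, function(m) rep(1, nrow(m)))
  } else {
    if (is.numeric(masks)) masks <- list(masks)
    masks <- Map(function(m, e) check_mask(m, nrow(e)), masks, x)
  }
  list(embeddings = x, masks = masks)
}

# atomic write contract: write to a temp file in the same directory, then rename
write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".", basename(path), ".tmp"))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    cheap_abort(sprintf("failed to move temporary file into place at '%s'.", path),
                "cheap_io_error")
  }
  invisible(path)
}

# derive a child seed from a root seed; stays below 2^31
derive_seed <- function(seed, salt) {
  (as.integer(seed) * 2654435L + as.integer(salt) * 97L) %% 2147483629L
}
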