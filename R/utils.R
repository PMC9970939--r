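# Internal helpers: typed conditions, scoped RNG, small utilities.

#' @keywords internal
"_PACKAGE"

# Typed errors. Every failure mode the pipeline can hit gets a condition class
# so callers (and the batch runner) can distinguish, e.g., an empty Otsu band
# from an unreadable file.
stop_nir <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("nirphantom_", class), "nirphantom_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

warn_nir <- function(class, msg, ...) {
  warning(structure(
    class = c(paste0("nirphantom_", class), "nirphantom_warning", "warning", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

check_number <- function(x, name, min = -Inf, strict_min = FALSE, len = 1L) {
  if (!is.numeric(x) || length(x) != len || anyNA(x) || any(!is.finite(x))) {
    stop_nir("invalid_parameter", "`%s` must be %d finite numeric value(s)", name, len)
  }
  bad <- if (strict_min) any(x <= min) else any(x < min)
  if (bad) {
    stop_nir("invalid_parameter", "`%s` must be %s %g (got %g)",
             name, if (strict_min) ">" else ">=", min, x[which(if (strict_min) x <= min else x < min)[1]])
  }
  invisible(x)
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state after.
# All stochastic steps of the simulator go through this so that a spec seed
# yields bit-identical rasters without clobbering the session RNG.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive child seeds from a parent seed (keeps everything < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

# 32-bit FNV-1a over a character scalar; used to stamp outputs with a short
# config fingerprint.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "")))
  p <- 16777619
  h <- 2166136261
  for (b in bytes) {
    # xor on the low 16 bits (the byte only touches those), then a 32-bit
    # modular multiply by the FNV prime, split into 16-bit halves to stay
    # within exact double-precision integer arithmetic
    hi <- h %/% 65536
    lo <- bitwXor(h %% 65536, b)
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(config) {
  fnv1a32(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
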