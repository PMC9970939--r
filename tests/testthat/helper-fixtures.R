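# Shared fixtures and independent oracles.

# Brute-force Otsu oracle: for every interior edge of a `bins`-bin histogram
# on [0, 1], split the raw pixel values at the edge and compute the
# between-class variance directly; ties resolved to the midpoint of the tied
# edges. Independent of the package's cumulative-histogram implementation.
oracle_otsu <- function(x, bins = 256L) {
  x <- as.numeric(x)
  edges <- seq_len(bins - 1L) / bins
  bcv <- vapply(edges, function(e) {
    lo <- x[x <= e]
    hi <- x[x > e]
    if (length(lo) == 0L || length(hi) == 0L) return(0)
    w0 <- length(lo) / length(x)
    w0 * (1 - w0) * (mean(lo) - mean(hi))^2
  }, 0)
  mx <- max(bcv)
  mean(edges[bcv >= mx - 1e-12 * max(mx, 1)])
}

# Noiseless, flat-field spec for exact-value checks.
clean_spec <- function(...) {
  args <- list(blur_sigma = 0, field_inhomogeneity_amplitude = 0,
               noise = noise_model(0, 0))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_spec, args)
}

# The blurred-peaked-tumor study fixture: a medium inclusion under strong
# blur, giving images with a bright peak and broad shoulders like the
# physical phantoms.
peaked_spec <- function(seed, c_background = 0.03, c_tumor = 1) {
  phantom_spec(tumor = tumor_ellipse(c(25.6, 25.6), c(8, 6)),
               tumor_depth = 2.2, c_tumor = c_tumor, c_background = c_background,
               blur_sigma = 3, field_inhomogeneity_amplitude = 0.05,
               noise = noise_model(0.01, 0), seed = seed)
}

# Random region statistics with strictly positive means and SDs.
random_stats <- function() {
  list(mean = runif(1, 0.01, 1), sd = runif(1, 0.001, 0.3), n_pixels = 100L)
}
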