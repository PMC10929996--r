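# Shared fixtures and independent oracles for the test suite.

# Brute-force Dice on plain arrays (independent of the package's accessors).
bf_dice <- function(p, g) {
  sp <- sum(p); sg <- sum(g)
  if (sp + sg == 0) return(1)
  2 * sum(p == 1 & g == 1) / (sp + sg)
}

# Brute-force directed/symmetric Hausdorff over explicit point sets (O(n^2)).
bf_hausdorff <- function(p, g, spacing = c(1, 1, 1), percentile = 1) {
  pp <- which(p == 1, arr.ind = TRUE)
  gg <- which(g == 1, arr.ind = TRUE)
  pp <- sweep(pp - 1, 2, spacing, "*")
  gg <- sweep(gg - 1, 2, spacing, "*")
  directed <- function(a, b) {
    d <- apply(a, 1, function(q) sqrt(min(colSums((t(b) - q)^2))))
    if (percentile >= 1) max(d) else as.numeric(stats::quantile(d, percentile))
  }
  max(directed(pp, gg), directed(gg, pp))
}

# A random small binary mask with at least one foreground voxel.
random_mask <- function(dims, p = 0.15) {
  m <- array(as.integer(stats::runif(prod(dims)) < p), dims)
  if (sum(m) == 0) m[sample(length(m), 1)] <- 1L
  m
}

# Central finite-difference gradient of f (scalar-valued) at selected indices.
fd_grad <- function(f, x, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

# Tiny model configuration used throughout the architecture tests.
tiny_config <- function(...) {
  model_config(patch_size = 16L, base_channels = 4L, fpn_channels = 12L,
               n_layers = 1L, n_heads = 2L, n_points = 2L, ffn_mult = 2L, ...)
}

# A small preprocessed phantom training case.
small_case <- function(seed = 1L, dims = c(32L, 32L, 32L), noise_sd = 0,
                       radii = c(5, 9), n_tumors = 1L, spacing = c(2, 2, 2)) {
  ph <- generate_phantom(phantom_spec(dims = dims, spacing = spacing,
                                      n_tumors = n_tumors,
                                      tumor_radii_mm = radii,
                                      noise_sd = noise_sd, seed = seed))
  list(volume = minmax_normalize(truncate_hu(ph$volume)),
       mask = ph$mask, tumors = ph$tumors)
}

ag_ns <- function(name) get(name, envir = asNamespace("coretr"))
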