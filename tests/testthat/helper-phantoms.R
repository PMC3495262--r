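# Small, fast phantom specs shared across test files; phantoms are cached
# per seed so multiple tests can reuse one rendering.

small_spec <- function(seed = 1L, noise_sd = 10,
                       layer_thicknesses_um = c(4, 16, 8), ...) {
  phantom_spec(
    artery_class = "muscular_two_lamellae",
    inner_radius_um = 30, layer_thicknesses_um = layer_thicknesses_um,
    constituent_fractions = c(elastin = 0.10, sma = 0.30, collagen = 0.20,
                              cd34 = 0.02, mac387 = 0.01),
    nuclei_density_cells_per_um2 = 0.004,
    noise_sd = noise_sd, seed = seed, ...
  )
}

.phantom_cache <- new.env(parent = emptyenv())

cached_phantom <- function(seed = 1L) {
  key <- paste0("p", seed)
  if (is.null(.phantom_cache[[key]]))
    .phantom_cache[[key]] <- make_artery_phantom(small_spec(seed))
  .phantom_cache[[key]]
}

lumen_seed_point <- function(phantom) {
  round(colMeans(which(phantom$masks$lumen, arr.ind = TRUE)))
}

# brute-force painted-pixel fraction from the recorded ground-truth set
painted_fraction <- function(phantom, what) {
  length(phantom$truth$painted[[what]]) / phantom$truth$wall_pixels
}

# balanced 2 x 2 fixture for the ANOVA oracle comparisons
balanced_2x2 <- function() {
  data.frame(
    condition = rep(c("NT", "HT"), each = 6),
    week = rep(rep(c(2, 8), each = 3), 2),
    y = c(10, 12, 11, 14, 13, 15, 20, 22, 21, 30, 29, 31)
  )
}
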