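# Shared fixtures: small synthetic datasets and a couple of hand-built
# spectra used across test files.

small_dataset <- function(effect_size = 0.5, n_per_class = 12, seed = 1,
                          mode = "fixed", ...) {
  simulate_dataset(make_class_profiles(effect_size),
                   sim_config(mode = mode, n_per_class = n_per_class,
                              seed = seed, ...))
}

# spectrum that is exactly a degree-2 polynomial of the wavenumber
poly2_spectrum <- function(grid = default_grid("fixed"),
                           coeffs = c(2, 0.5, 0.3)) {
  t <- (grid - min(grid)) / diff(range(grid))
  raman_spectrum(grid, coeffs[1] + coeffs[2] * t + coeffs[3] * t^2,
                 spectrum_id = "poly2")
}

lorentz <- function(x, center, width) 1 / (1 + ((x - center) / width)^2)
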