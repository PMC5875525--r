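# Shared fixtures: small synthetic renders reused across test files.
# Render sizes are kept modest (matrix 256, partial z coverage where a
# test only needs one module) so the whole suite runs quickly.

.render_cache <- new.env(parent = emptyenv())

cached_render <- function(key, cfg) {
  if (!exists(key, .render_cache))
    assign(key, render_phantom(cfg), .render_cache)
  get(key, .render_cache)
}

small_cfg <- function(...) {
  sim_config(matrix_size = 256, fov = 250, ...)
}

# full-phantom noiseless sharp render: exact-recovery reference
series_exact <- function() {
  cached_render("exact", small_cfg(noise_sigma = 0, psf_fwhm = 0,
                                   seed = 1))
}

# full-phantom CT-like render at default conditions
series_ct <- function() {
  cached_render("ct", sim_preset("ct-sim", seed = 11))
}

series_cbct <- function() {
  cached_render("cbct", sim_preset("cbct-head", seed = 11))
}

# minimal localization stand-in for single-module renders, where full
# slice assignment is impossible by construction
quick_loc <- function(series, center = c(0, 0), roll = 0,
                      m1 = NULL, m2 = NULL, m3 = NULL, m4 = NULL) {
  near <- function(z0) which.min(abs(series$z - z0))
  structure(list(center = center, roll = roll,
                 module_slices = c(m1 = m1 %||% near(0),
                                   m2 = m2 %||% near(40),
                                   m3 = m3 %||% near(80),
                                   m4 = m4 %||% near(120)),
                 bbs = NULL, method = "manual", flags = character()),
            class = "localization")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
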