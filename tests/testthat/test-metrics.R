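test_that("ROI statistics match a brute-force pixel oracle", {
  # constant disc
  slice <- matrix(100, 80, 80)
  st <- extract_roi_stats(slice, 1, list(label = "c", x = 0, y = 0,
                                         radius = 8))
  expect_equal(st$mean, 100)
  expect_equal(st$sd, 0)
  expect_equal(st$area, st$n * 1)
  # seeded Gaussian noise sigma = 10 over constant 0: SD within 10 +/- 1
  # at >= 700 pixels, and mean/SD equal an explicit pixel-loop oracle
  set.seed(42)
  noisy <- matrix(rnorm(160 * 160, 0, 10), 160, 160)
  roi <- list(label = "n", x = 3, y = -2, radius = 16)
  st2 <- extract_roi_stats(noisy, 1, roi)
  expect_gte(st2$n, 700)
  expect_lt(abs(st2$sd - 10), 1)
  grid <- pixel_grid(160, 160, 1)
  vals <- c()
  for (i in 1:160) for (j in 1:160)
    if ((grid$x[i, j] - 3)^2 + (grid$y[i, j] + 2)^2 <= 16^2)
      vals <- c(vals, noisy[i, j])
  expect_equal(st2$mean, mean(vals))
  expect_equal(st2$sd, sd(vals))
  expect_equal(st2$n, length(vals))
})

test_that("a half-masked ROI halves the pixel count and is flagged", {
  slice <- matrix(50, 80, 80)
  mask <- matrix(FALSE, 80, 80)
  mask[, 41:80] <- TRUE                 # right half of the image
  # ROI on the phantom axis: angular re-seating cannot reduce the
  # masked fraction, so the stat is flagged as-is
  st <- extract_roi_stats(slice, 1, list(label = "m", x = 0, y = 0,
                                         radius = 10),
                          artifact_mask = mask)
  full <- extract_roi_stats(slice, 1, list(label = "m", x = 0, y = 0,
                                           radius = 10))
  expect_equal(st$n / full$n, 0.5, tolerance = 0.05)
  expect_equal(st$masked_frac, 0.5, tolerance = 0.05)
  expect_true(st$flagged)
  # fully outside the image
  expect_error(extract_roi_stats(slice, 1, list(label = "x", x = 500,
                                                y = 0, radius = 5)),
               "outside the image")
})

test_that("heavily masked ROIs are re-seated about the phantom axis", {
  # gradient-free field with an artifact sector at 12 o'clock
  slice <- matrix(0, 120, 120)
  mask <- matrix(FALSE, 120, 120)
  grid <- pixel_grid(120, 120, 1)
  mask[grid$y > 30 & abs(grid$x) < 12] <- TRUE
  roi <- list(label = "edge_12", x = 0, y = 40, radius = 8)
  st <- extract_roi_stats(slice, 1, roi, artifact_mask = mask,
                          center = c(0, 0))
  expect_true(st$reseated)
  expect_lt(st$masked_frac, 0.3)
  # re-seated centre stays on the same radius about the axis
  expect_equal(sqrt(sum(st$center^2)), 40, tolerance = 1e-6)
})

test_that("CNR follows the ACR formula and its invariances", {
  st <- function(m, s) list(mean = m, sd = s)
  expect_equal(compute_cnr(st(120, 5), st(0, 60)), 2)
  expect_equal(compute_cnr(st(7, 1), st(7, 3)), 0)   # zero contrast
  expect_true(is.na(compute_cnr(st(10, 0), st(0, 0))))
  # offset invariance (exact) and halving under doubled background SD
  expect_equal(compute_cnr(st(120 + 50, 5), st(0 + 50, 60)),
               compute_cnr(st(120, 5), st(0, 60)))
  expect_equal(compute_cnr(st(120, 5), st(0, 120)),
               compute_cnr(st(120, 5), st(0, 60)) / 2)
})

test_that("noise uses the +1000 HU rescale and is offset-sensitive", {
  st <- function(m, s) list(mean = m, sd = s)
  expect_equal(compute_noise(st(0, 0)), 0)
  expect_equal(compute_noise(st(0, 10)), 1.0)        # denominator 1000
  expect_equal(compute_noise(st(120, 5)), 100 * 5 / 1120)
  expect_equal(round(compute_noise(st(120, 5)), 3), 0.446)
  # NOT offset invariant: the denominator shifts with the mean
  expect_false(isTRUE(all.equal(compute_noise(st(120 + 50, 5)),
                                compute_noise(st(120, 5)))))
  expect_error(compute_noise(st(-1000, 5)), "undefined")
})

test_that("noiseless plug means are recovered exactly away from edges", {
  s <- series_exact()
  loc <- localize_phantom(s)
  hu <- measure_hu_accuracy(s, loc)
  g <- acr_geometry()
  expect_equal(hu$table$mean[match(g$plugs$name, hu$table$plug)],
               g$plugs$nominal_hu)
  expect_true(all(hu$table$in_range))
})

test_that("out-of-range plug means are flagged", {
  s <- cached_render("water8", small_cfg(noise_sigma = 0, psf_fwhm = 0,
                                         plug_hu = c(water = 8),
                                         seed = 1))
  hu <- measure_hu_accuracy(s, localize_phantom(s))
  expect_false(hu$table$in_range[hu$table$plug == "water"])
  expect_true(all(hu$table$in_range[hu$table$plug != "water"]))
})

test_that("plug HU recovery is within 3 sigma/sqrt(n) under noise", {
  s <- cached_render("sigma5", small_cfg(noise_sigma = 5, psf_fwhm = 0.7,
                                         seed = 12))
  hu <- measure_hu_accuracy(s, localize_phantom(s))
  g <- acr_geometry()
  nominal <- g$plugs$nominal_hu[match(hu$table$plug, g$plugs$name)]
  expect_true(all(abs(hu$table$mean - nominal) <
                    3 * 5 / sqrt(hu$table$n)))
})

test_that("uniformity is 0 on a clean field and tracks cupping within 15%", {
  s0 <- series_exact()
  un0 <- measure_uniformity(s0, localize_phantom(s0))
  expect_equal(un0$value, 0)
  for (A in c(10, 20)) {
    sA <- cached_render(paste0("cup", A),
                        small_cfg(noise_sigma = 0, psf_fwhm = 0,
                                  cupping = A, seed = 1))
    unA <- measure_uniformity(sA, localize_phantom(sA))
    expect_lt(abs(unA$value - A) / A, 0.15)
    expect_lt(unA$center_mean, 0)       # depressed centre
  }
})

test_that("in-plane distance is sub-pixel accurate and detects a short phantom", {
  s <- series_exact()
  d <- measure_inplane_distance(localize_phantom(s))
  expect_lt(abs(d - 100.0), 0.5 * s$pixel_spacing)
  # BBs rendered 98 mm apart measured as such, outside a +/-1.0 mm band
  g98 <- acr_geometry(distance_nominal = 98)
  s98 <- cached_render("dist98",
                       small_cfg(geometry = g98, noise_sigma = 0,
                                 psf_fwhm = 0, seed = 1))
  d98 <- measure_inplane_distance(localize_phantom(s98))
  expect_lt(abs(d98 - 98), 0.5 * s98$pixel_spacing)
  expect_gt(abs(d98 - 100), 1.0)
})

test_that("wire-ramp count recovers 2.5 and 3.0 mm slices exactly", {
  for (th in c(2.5, 3.0)) {
    s <- cached_render(paste0("thick", th),
                       small_cfg(noise_sigma = 0, psf_fwhm = 0.7,
                                 slice_thickness = th, seed = 1))
    st <- measure_slice_thickness(s, localize_phantom(s))
    expect_equal(st$value, th)
    expect_equal(st$counts, rep(th / 0.5, 2))
  }
})

test_that("low-contrast rods: visible at CT-like noise, gone at CBCT-like", {
  s_ct <- series_ct()                  # contrast 6 HU, sigma 4
  lc <- score_low_contrast(s_ct, localize_phantom(s_ct))
  expect_equal(lc$n_visible, 4)
  expect_gte(lc$cnr, 1.0)
  s_cb <- series_cbct()                # sigma 30 >= 3 x rod contrast
  lc2 <- score_low_contrast(s_cb, localize_phantom(s_cb))
  expect_equal(lc2$n_visible, 0)
  # zero-contrast rods are never "visible"
  s_flat <- cached_render("flat_rods",
                          small_cfg(noise_sigma = 3, psf_fwhm = 0.7,
                                    rod_contrast = 0, seed = 9))
  lc3 <- score_low_contrast(s_flat, localize_phantom(s_flat))
  expect_equal(lc3$n_visible, 0)
})

test_that("high-contrast score agrees with an analytic blur oracle", {
  # independent oracle: 1D square wave convolved with the Gaussian PSF on
  # a fine grid; predicted score from the same relative-SD criterion
  oracle_score <- function(fwhm, lpcm, spacing, f = 0.4) {
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    stat <- vapply(lpcm, function(lp) {
      p <- 10 / lp
      if (1 / p > 1 / (2 * spacing)) return(0)  # beyond grid Nyquist
      x <- seq(0, 20 * p, by = p / 400)
      wave <- as.numeric((x / p) %% 1 < 0.5)
      if (sigma > 0) {
        k <- seq(-4 * sigma, 4 * sigma, by = p / 400)
        kern <- exp(-k^2 / (2 * sigma^2)); kern <- kern / sum(kern)
        wave <- stats::filter(wave, kern, circular = TRUE)
      }
      stats::sd(wave)
    }, 0)
    ok <- stat > f * stat[1]
    if (any(!ok)) ok[seq_along(ok) >= min(which(!ok))] <- FALSE
    max(lpcm[ok])
  }
  g <- acr_geometry()
  sp <- 250 / 512
  for (fwhm in c(0.85, 1.6)) {
    s <- cached_render(paste0("bars", fwhm),
                       sim_config(matrix_size = 512, fov = 250,
                                  noise_sigma = 0, psf_fwhm = fwhm,
                                  z_range = c(100, 140), seed = 1))
    loc <- quick_loc(s)
    hc <- score_high_contrast(s, loc)
    expect_equal(hc$value,
                 oracle_score(fwhm, g$bar_patterns$lpcm, sp))
  }
})

test_that("high-contrast score is monotone non-increasing in PSF width", {
  scores <- vapply(c(0.8, 1.2, 1.8), function(fwhm) {
    s <- render_phantom(sim_config(matrix_size = 512, fov = 250,
                                   noise_sigma = 0, psf_fwhm = fwhm,
                                   z_range = c(100, 140), seed = 1))
    score_high_contrast(s, quick_loc(s))$value
  }, 0)
  expect_true(all(diff(scores) <= 0))
  expect_lt(scores[3], 12)              # wide PSF does lose resolution
  # heavy blur (PSF >> bar width at 4 lp/cm): not evaluable
  s_blur <- render_phantom(sim_config(matrix_size = 512, fov = 250,
                                      noise_sigma = 0, psf_fwhm = 5,
                                      z_range = c(100, 140), seed = 1))
  hc <- score_high_contrast(s_blur, quick_loc(s_blur))
  expect_true(is.na(hc$value))
})

test_that("run_session produces a full panel on CT-like input", {
  ses <- run_session(series_ct())
  expect_s3_class(ses, "qa_session")
  expect_true(all(ses$metrics$evaluable))
  expect_equal(nrow(ses$metrics), 16)
  df <- as.data.frame(ses)
  expect_equal(df$protocol[1], "ct-sim")
  f <- tempfile(fileext = ".json")
  write_session_json(ses, f)
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(nrow(j$metrics), 16)
  unlink(f)
})

test_that("run_session on CBCT-like input: rods gone, the rest evaluable", {
  ses <- run_session(series_cbct())
  m <- ses$metrics
  expect_equal(m$value[m$metric == "lowcontrast_rods"], 0)
  expect_true(all(m$evaluable))
  expect_gt(m$value[m$metric == "uniformity"], 10)
})

test_that("a truncated volume yields a flagged, not crashed, session", {
  s_part <- cached_render("partial",
                          small_cfg(noise_sigma = 0, psf_fwhm = 0,
                                    z_range = c(-20, 60), seed = 1))
  ses <- run_session(s_part)
  expect_true(all(!ses$metrics$evaluable))
  expect_true(any(grepl("incomplete phantom coverage", ses$metrics$note)))
})

test_that("CNR is offset-invariant on images while noise is not", {
  s <- series_ct()
  loc <- localize_phantom(s)
  hu1 <- measure_hu_accuracy(s, loc)
  s2 <- s
  s2$hu <- s$hu + 60
  loc2 <- localize_phantom(s2)
  hu2 <- measure_hu_accuracy(s2, loc2)
  for (p in c("polyethylene", "acrylic")) {
    expect_equal(compute_cnr(hu2$stats[[p]], hu2$stats$water),
                 compute_cnr(hu1$stats[[p]], hu1$stats$water),
                 tolerance = 1e-10)
    expect_false(isTRUE(all.equal(compute_noise(hu2$stats[[p]]),
                                  compute_noise(hu1$stats[[p]]))))
  }
})
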