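test_that("volumetric signal dilution is the cube of the linear factor", {
  expect_equal(signal_dilution_factor(5), 125)
  expect_equal(signal_dilution_factor(1), 1)
  expect_equal(signal_dilution_factor(2), 8)
  expect_error(signal_dilution_factor(0.9), class = "exmloc_invalid_expansion")
  expect_error(acquisition_model(expansion_factor = 0.5),
               class = "exmloc_invalid_expansion")
})

test_that("geometry honours the type-specific nuclei signatures", {
  g1 <- build_geometry(1, c(192, 192, 48), params = test_gp(), seed = 7)
  tab1 <- table(factor(g1$nuclei$orientation,
                       levels = c("axial", "peripheral", "perpendicular")))
  expect_gte(tab1[["axial"]], 3)
  expect_lte(tab1[["peripheral"]], 2)
  expect_identical(tab1[["perpendicular"]], 0L)

  g3 <- build_geometry(3, c(192, 192, 48), params = test_gp(), seed = 7)
  expect_gte(sum(g3$nuclei$orientation == "perpendicular"), 1)

  g2 <- build_geometry(2, c(192, 192, 48), params = test_gp(), seed = 7)
  expect_gte(sum(g2$nuclei$orientation == "peripheral"), 4)
})

test_that("geometry construction is deterministic and checks the fit", {
  a <- build_geometry(1, c(192, 192, 48), params = test_gp(), seed = 11)
  b <- build_geometry(1, c(192, 192, 48), params = test_gp(), seed = 11)
  expect_identical(a, b)
  expect_error(build_geometry(1, c(32, 32, 8), params = test_gp()),
               class = "exmloc_geometry_fit")
})

test_that("spot placement follows the requested bin mixture", {
  g <- build_geometry(1, c(192, 192, 48), params = test_gp(), seed = 1)

  tr <- place_spots(g, 50, c(abluminal = 1), seed = 2)
  expect_true(all(tr$spots$true_distance_nm >= 0 &
                    tr$spots$true_distance_nm < 100))
  expect_identical(tr$abluminal_fraction_true, 1)

  big <- place_spots(g, 10000, c(abluminal = 0.32,
                                 intracellular_proximal = 0.34,
                                 intracellular_distal = 0.34), seed = 1)
  expect_lt(abs(mean(big$spots$true_bin == "abluminal") - 0.32), 0.01)

  # the recorded bin must match re-binning the true distance
  rebin <- as.character(exmloc:::assign_bins(big$spots$true_distance_nm,
                                             bin_spec()))
  expect_identical(rebin, big$spots$true_bin)

  expect_error(place_spots(g, 0, c(abluminal = 1)), class = "exmloc_config")
  expect_error(place_spots(g, 10, c(abluminal = 0.6)),
               class = "exmloc_config")
  # residual bin (up to 3000 nm) cannot fit inside a 1000 nm inner radius
  expect_error(place_spots(g, 10, c(abluminal = 0.5, residual = 0.5)),
               class = "exmloc_placement_infeasible")
})

test_that("rendered foreground scales as 1/E^3 at fixed photon budget", {
  meds <- vapply(c(1, 2, 5), function(E) {
    acq <- acquisition_model(expansion_factor = E, psf_sigma_gel = c(0, 0, 0),
                             background_rate = 0, read_noise_sd = 0)
    g <- build_geometry(1, c(96, 96, 32), acq,
                        list(lumen_radius = 300, wall_thickness = 150,
                             n_axial = 0L,
                             n_peripheral_range = c(0L, 0L)), seed = 3)
    rast <- rasterize_truth(NULL, g, acq)
    stack <- render_stack(NULL, g, acq, noise = FALSE, rast = rast)
    median(stack$channels$collagen[rast$collagen_mask])
  }, numeric(1))
  slope <- coef(lm(log(meds) ~ log(c(1, 2, 5))))[2]
  expect_lt(abs(slope + 3), 0.1)
})

test_that("dilution identity: photons/E^3 sets the pre-noise signal level", {
  gp <- list(lumen_radius = 300, wall_thickness = 150, n_axial = 0L,
             n_peripheral_range = c(0L, 0L))
  render_med <- function(photons, E) {
    acq <- acquisition_model(expansion_factor = E, psf_sigma_gel = c(0, 0, 0),
                             background_rate = 0, read_noise_sd = 0,
                             collagen_photons_per_voxel = photons)
    g <- build_geometry(1, c(96, 96, 32), acq, gp, seed = 3)
    rast <- rasterize_truth(NULL, g, acq)
    stack <- render_stack(NULL, g, acq, noise = FALSE, rast = rast)
    median(stack$channels$collagen[rast$collagen_mask])
  }
  expect_equal(render_med(12500, 5), render_med(100, 1))
})

test_that("true surface distances agree with the rasterized shell", {
  sim <- fixture("noiseless_sim_small", function()
    simulate_capillary(1, 60, c(abluminal = 0.4, intracellular_proximal = 0.3,
                                intracellular_distal = 0.3),
                       c(160, 160, 40), noiseless_acq(), test_gp(),
                       seed = 42, noise = FALSE))
  E <- 5
  truth_pts <- as_spotset(as.matrix(sim$truth$spots[, c("x_nm", "y_nm",
                                                        "z_nm")]) * E)
  bf <- brute_force_nearest(truth_pts, sim$truth$collagen_shell_mask,
                            expansion_model(E))
  voxdiag <- sqrt(sum(c(108, 108, 310)^2))
  expect_lt(max(abs(bf$distance_bio_nm - sim$truth$spots$true_distance_nm)),
            voxdiag / E)
})

test_that("identical seed reproduces stacks and truth bit-identically", {
  a <- simulate_capillary(1, 40, mix_basigin, c(144, 144, 48),
                          geometry_params = test_gp(n_axial = 2L), seed = 9)
  b <- simulate_capillary(1, 40, mix_basigin, c(144, 144, 48),
                          geometry_params = test_gp(n_axial = 2L), seed = 9)
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$truth$spots, b$truth$spots)
  c2 <- simulate_capillary(1, 40, mix_basigin, c(144, 144, 48),
                           geometry_params = test_gp(n_axial = 2L), seed = 10)
  expect_false(identical(a$stack$channels$receptor,
                         c2$stack$channels$receptor))
})

test_that("the frozen low-SNR preset renders in the intended 2-5 band", {
  sim <- noisy_sim()
  snr <- channel_snr(sim$stack, sim$truth, "receptor")
  expect_gte(snr, 2)
  expect_lte(snr, 5)
})
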