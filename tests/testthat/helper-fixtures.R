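# Shared fixtures, generated in code and cached for the session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) assign(name, builder(), envir = .fixtures)
  .fixtures[[name]]
}

# reduced tube geometry used throughout the tests (biological nm); the tube
# plus shell fits fully inside a 192x192x48 gel-voxel volume at 5x expansion
test_gp <- function(...) {
  utils::modifyList(list(lumen_radius = 700, wall_thickness = 300), list(...))
}

# nuclei sized for the 256x256x48 typing volume
typing_gp <- function(...) {
  utils::modifyList(list(lumen_radius = 700, wall_thickness = 300,
                         axial_radii = c(600, 250, 250),
                         perpendicular_radii = c(600, 250, 250),
                         peripheral_radii = c(350, 280, 280)), list(...))
}

mix_basigin <- c(abluminal = 0.32, intracellular_proximal = 0.28,
                 intracellular_distal = 0.40)
mix_tfr <- c(abluminal = 0.08, intracellular_proximal = 0.22,
             intracellular_distal = 0.70)

noiseless_acq <- function() {
  acquisition_model(psf_sigma_gel = c(0, 0, 0), background_rate = 0,
                    read_noise_sd = 0)
}

# a noisy low-SNR simulated capillary (frozen seed)
noisy_sim <- function() {
  fixture("noisy_sim", function() {
    simulate_capillary(1, 150, mix_basigin, c(192, 192, 48),
                       acquisition_model(), test_gp(), seed = 7)
  })
}

# two noisy training stacks plus receptor/collagen segmenters
trained_models <- function() {
  fixture("trained_models", function() {
    acq <- acquisition_model()
    sims <- lapply(1:2, function(i)
      simulate_capillary(1, 150, mix_basigin, c(192, 192, 48), acq,
                         test_gp(), seed = 100 + i))
    stacks <- lapply(sims, `[[`, "stack")
    oracle <- truth_oracle(stacks)
    feats_r <- lapply(stacks, extract_features, channel = "receptor")
    list(
      stacks = stacks,
      receptor_r1 = train_segmenter(stacks, oracle, "receptor", rounds = 1,
                                    seed = 5, features = feats_r),
      receptor = train_segmenter(stacks, oracle, "receptor", rounds = 12,
                                 seed = 5, features = feats_r),
      collagen = train_segmenter(stacks, oracle, "collagen", rounds = 12,
                                 seed = 5))
  })
}

# build a minimal spot_set from a coordinate matrix (gel nm)
as_spotset <- function(coords, ids = seq_len(nrow(coords)),
                       voxel_size = c(108, 108, 310)) {
  df <- data.frame(spot_id = ids, cx_nm = coords[, 1], cy_nm = coords[, 2],
                   cz_nm = coords[, 3], voxels = rep(1L, nrow(coords)))
  structure(df, class = c("spot_set", "data.frame"),
            voxel_size_gel = voxel_size)
}

# independent flood-fill connected-component counter (26-neighborhood)
flood_fill_count <- function(mask) {
  d <- dim(mask)
  seen <- array(FALSE, d)
  idx <- which(mask)
  comp <- 0L
  for (s in idx) {
    if (seen[s]) next
    comp <- comp + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      px <- (p - 1) %% d[1]; py <- ((p - 1) %/% d[1]) %% d[2]
      pz <- (p - 1) %/% (d[1] * d[2])
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        qx <- px + dx; qy <- py + dy; qz <- pz + dz
        if (qx < 0 || qx >= d[1] || qy < 0 || qy >= d[2] ||
            qz < 0 || qz >= d[3]) next
        q <- 1 + qx + d[1] * (qy + d[2] * qz)
        if (mask[q] && !seen[q]) { seen[q] <- TRUE; queue <- c(queue, q) }
      }
    }
  }
  comp
}
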