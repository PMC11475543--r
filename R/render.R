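# --- low-level volume helpers ------------------------------------------------

gauss_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# separable anisotropic Gaussian blur of a 3D array (mass conserving in the
# interior; zero padding at the volume boundary)
blur_volume <- function(vol, sigma_vox) {
  d <- dim(vol)
  v <- as.numeric(vol)
  for (ax in 1:3) {
    if (sigma_vox[ax] <= 0) next
    v <- .conv_axis(v, as.integer(d), ax, gauss_kernel(sigma_vox[ax]))
  }
  array(v, d)
}

lin_index <- function(ix, iy, iz, d) {
  # 0-based voxel indices to 1-based linear index
  1 + ix + d[1] * (iy + d[2] * iz)
}

# deposit point masses with trilinear weights onto a voxel grid (gel nm)
deposit_points <- function(pos_gel, mass, d, voxel_size) {
  vol <- numeric(prod(d))
  if (nrow(pos_gel) == 0) return(array(vol, d))
  f <- sweep(pos_gel, 2, voxel_size, "/") - 0.5  # fractional 0-based index
  i0 <- floor(f)
  w1 <- f - i0
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- i0[, 1] + cx; iy <- i0[, 2] + cy; iz <- i0[, 3] + cz
    w <- (if (cx) w1[, 1] else 1 - w1[, 1]) *
         (if (cy) w1[, 2] else 1 - w1[, 2]) *
         (if (cz) w1[, 3] else 1 - w1[, 3])
    ok <- ix >= 0 & ix < d[1] & iy >= 0 & iy < d[2] & iz >= 0 & iz < d[3] & w > 0
    if (!any(ok)) next
    idx <- lin_index(ix[ok], iy[ok], iz[ok], d)
    acc <- rowsum(mass[ok] * w[ok], idx)
    at <- as.integer(rownames(acc))
    vol[at] <- vol[at] + acc[, 1]
  }
  array(vol, d)
}

# --- rasterization of ground truth structures --------------------------------

#' Rasterize a capillary geometry and spot truth onto the voxel grid
#'
#' Maps biological coordinates to gel space (multiplying by the expansion
#' factor) and rasterizes the collagen shell, the nuclei ellipsoids, and the
#' receptor point spots onto the acquisition voxel grid.
#'
#' @param truth a `simulation_truth` from [place_spots()] (may be `NULL` for a
#'   spot-free volume).
#' @param geometry a `capillary_geometry`.
#' @param acq an [acquisition_model()].
#' @return list with `collagen_mask` (logical array), `nuclei_labels`
#'   (integer array, one label per nucleus), and per-channel expected photon
#'   rate arrays `rates` (before PSF blur, background and noise).
#' @export
rasterize_truth <- function(truth, geometry, acq) {
  d <- geometry$volume_shape
  E <- acq$expansion_factor
  vs <- acq$voxel_size_gel
  dil <- signal_dilution_factor(E)

  yc <- voxel_centers(d[2], vs[2])
  zc <- voxel_centers(d[3], vs[3])
  r_in <- (geometry$lumen_radius + geometry$wall_thickness) * E
  r_out <- r_in + geometry$collagen_shell_thickness * E

  collagen <- array(FALSE, d)
  dz2 <- matrix(rep((zc - geometry$extent_bio[3] / 2 * E)^2, each = d[2]), d[2], d[3])
  for (i in seq_len(d[1])) {
    ctr_y <- geometry$centerline[i, 2] * E
    r2 <- (yc - ctr_y)^2 + dz2  # d[2] x d[3] cross-section at this x
    collagen[i, , ] <- r2 >= r_in^2 & r2 <= r_out^2
  }

  nuclei <- array(0L, d)
  nuc <- geometry$nuclei
  if (nrow(nuc) > 0) {
    xc <- voxel_centers(d[1], vs[1])
    for (k in seq_len(nrow(nuc))) {
      ctr <- c(nuc$cx[k], nuc$cy[k], nuc$cz[k]) * E
      a <- nuc$ra[k] * E; b <- nuc$rb[k] * E
      o <- c(nuc$ox[k], nuc$oy[k], nuc$oz[k])
      half <- max(a, b)
      rng <- function(ax) {
        lo <- max(1L, ceiling((ctr[ax] - half) / vs[ax]))
        hi <- min(d[ax], ceiling((ctr[ax] + half) / vs[ax]))
        if (lo > hi) integer(0) else lo:hi
      }
      ix <- rng(1); iy <- rng(2); iz <- rng(3)
      if (!length(ix) || !length(iy) || !length(iz)) next
      ux <- xc[ix] - ctr[1]; uy <- yc[iy] - ctr[2]; uz <- zc[iz] - ctr[3]
      g <- expand.grid(ux = ux, uy = uy, uz = uz)
      t_par <- g$ux * o[1] + g$uy * o[2] + g$uz * o[3]
      s2 <- g$ux^2 + g$uy^2 + g$uz^2 - t_par^2
      inside <- (t_par / a)^2 + s2 / b^2 <= 1
      sub <- nuclei[ix, iy, iz, drop = FALSE]
      sub[inside & sub == 0L] <- k
      nuclei[ix, iy, iz] <- sub
    }
  }

  receptor_rate <- if (!is.null(truth) && nrow(truth$spots) > 0) {
    pos_gel <- as.matrix(truth$spots[, c("x_nm", "y_nm", "z_nm")]) * E
    deposit_points(pos_gel, rep(acq$photons_per_marker / dil, nrow(truth$spots)),
                   d, vs)
  } else array(0, d)

  list(collagen_mask = collagen,
       nuclei_labels = nuclei,
       rates = list(
         receptor = receptor_rate,
         collagen = collagen * (acq$collagen_photons_per_voxel / dil),
         nuclei = (nuclei > 0L) * (acq$nuclei_photons_per_voxel / dil)))
}

# --- rendering ---------------------------------------------------------------

#' Render a synthetic multi-channel confocal stack
#'
#' Blurs the rasterized structure rates with the anisotropic Gaussian PSF,
#' adds the background rate, draws Poisson photon counts and adds Gaussian
#' read noise, yielding unsigned-integer intensity volumes for the nuclei,
#' receptor and collagen channels. The mean foreground signal scales as
#' `photons_per_marker / E^3` (volumetric dilution). Deterministic under a
#' fixed seed.
#'
#' @param truth a `simulation_truth` (or `NULL`).
#' @param geometry a `capillary_geometry`.
#' @param acq an [acquisition_model()].
#' @param noise logical; `FALSE` renders the noiseless expected image
#'   (no Poisson or read noise).
#' @param seed integer seed for the noise substream (default `acq$seed`).
#' @param rast optional precomputed [rasterize_truth()] result.
#' @return an `exm_stack`: named channel volumes plus voxel/expansion
#'   metadata. The stack carries the annotation label volumes derived from
#'   the noiseless rates as attribute `annotation_codes` (+1 confident
#'   signal, -1 confident background, 0 uncertain) for the training oracle.
#' @export
render_stack <- function(truth, geometry, acq, noise = TRUE,
                         seed = acq$seed, rast = NULL) {
  if (is.null(rast)) rast <- rasterize_truth(truth, geometry, acq)
  d <- geometry$volume_shape
  E <- acq$expansion_factor
  sigma_vox <- acq$psf_sigma_gel / acq$voxel_size_gel
  channels <- list()
  codes <- list()
  vs <- acq$voxel_size_gel
  with_seed(seed_stream(seed, "noise"), {
    for (ch in c("nuclei", "receptor", "collagen")) {
      rate <- blur_volume(rast$rates[[ch]], sigma_vox)
      # annotation reference: typical structure plateau / spot peak intensity.
      # Confident signal and background are labeled symmetrically around the
      # half-maximum, so a classifier separating them places its boundary at
      # the blurred structure's half-max crossing, i.e. at the true edge.
      ref <- if (ch == "receptor") {
        if (!is.null(truth) && nrow(truth$spots) > 0) {
          pos <- as.matrix(truth$spots[, c("x_nm", "y_nm", "z_nm")]) * E
          iv <- pmin(pmax(round(sweep(pos, 2, vs, "/") - 0.5), 0),
                     matrix(rep(d - 1, each = nrow(pos)), ncol = 3))
          peaks <- vapply(seq_len(nrow(iv)), function(k) {
            ix <- max(1, iv[k, 1]):min(d[1], iv[k, 1] + 2)
            iy <- max(1, iv[k, 2]):min(d[2], iv[k, 2] + 2)
            iz <- max(1, iv[k, 3]):min(d[3], iv[k, 3] + 2)
            max(rate[ix, iy, iz])
          }, numeric(1))
          stats::median(peaks)
        } else max(rate)
      } else if (ch == "collagen") {
        if (any(rast$collagen_mask)) stats::median(rate[rast$collagen_mask])
        else max(rate)
      } else {
        if (any(rast$nuclei_labels > 0L))
          stats::median(rate[rast$nuclei_labels > 0L]) else max(rate)
      }
      code <- array(0L, d)
      if (ref > 0) {
        code[rate > 0.65 * ref] <- 1L
        code[rate < 0.35 * ref] <- -1L
      } else code[] <- -1L
      codes[[ch]] <- code
      lambda <- rate + acq$background_rate
      img <- if (noise) {
        n <- length(lambda)
        counts <- stats::rpois(n, as.numeric(lambda))
        if (acq$read_noise_sd > 0)
          counts <- counts + stats::rnorm(n, 0, acq$read_noise_sd)
        array(pmax(0, round(counts)), d)
      } else array(round(lambda), d)
      channels[[ch]] <- img
    }
  })
  stack <- image_stack(channels, voxel_size_gel = acq$voxel_size_gel,
                       expansion_factor = acq$expansion_factor)
  attr(stack, "annotation_codes") <- codes
  stack
}

#' Simulate a complete ground-truthed capillary stack
#'
#' Convenience wrapper running geometry construction, spot placement,
#' rasterization and rendering under named substreams of one master seed.
#'
#' @param capillary_type 1, 2 or 3.
#' @param n_spots number of receptor spots.
#' @param bin_mixture named probability vector over bin labels.
#' @param volume_shape volume size in voxels.
#' @param acq an [acquisition_model()].
#' @param geometry_params overrides for [capillary_params()].
#' @param bins a [bin_spec()].
#' @param seed master seed; geometry, placement and noise use substreams.
#' @param noise render photon and read noise (default `TRUE`).
#' @return list with `stack` (`exm_stack`), `truth` (`simulation_truth`,
#'   including the rasterized `collagen_shell_mask` and `nuclei_mask`), and
#'   `geometry`.
#' @export
simulate_capillary <- function(capillary_type = 1, n_spots = 150,
                               bin_mixture = c(abluminal = 0.08,
                                               intracellular_proximal = 0.22,
                                               intracellular_distal = 0.70),
                               volume_shape = c(384, 384, 128),
                               acq = acquisition_model(),
                               geometry_params = list(),
                               bins = bin_spec(),
                               seed = 1L, noise = TRUE) {
  geometry <- build_geometry(capillary_type, volume_shape, acq,
                             geometry_params, seed = seed)
  truth <- place_spots(geometry, n_spots, bin_mixture, bins, acq, seed = seed)
  rast <- rasterize_truth(truth, geometry, acq)
  stack <- render_stack(truth, geometry, acq, noise = noise, seed = seed,
                        rast = rast)
  truth$collagen_shell_mask <- rast$collagen_mask
  truth$nuclei_mask <- rast$nuclei_labels
  list(stack = stack, truth = truth, geometry = geometry)
}

#' Estimate the signal-to-noise ratio of a rendered channel
#'
#' SNR is defined as (mean spot-peak intensity - mean background) divided by
#' the background standard deviation, with background voxels taken from the
#' confident-background region of the stack's annotation codes.
#'
#' @param stack an `exm_stack` carrying annotation codes.
#' @param truth the matching `simulation_truth`.
#' @param channel channel name (default `"receptor"`).
#' @return single numeric SNR value.
#' @export
channel_snr <- function(stack, truth, channel = "receptor") {
  codes <- attr(stack, "annotation_codes")
  if (is.null(codes)) stop_exm("stack carries no annotation codes",
                               "exmloc_config")
  img <- stack$channels[[channel]]
  d <- dim(img)
  bg <- img[codes[[channel]] == -1L]
  E <- stack$expansion_factor
  vs <- stack$voxel_size_gel
  pos <- as.matrix(truth$spots[, c("x_nm", "y_nm", "z_nm")]) * E
  iv <- pmin(pmax(round(sweep(pos, 2, vs, "/") - 0.5), 0),
             matrix(rep(d - 1, each = nrow(pos)), ncol = 3))
  peaks <- vapply(seq_len(nrow(iv)), function(k) {
    ix <- max(1, iv[k, 1]):min(d[1], iv[k, 1] + 2)
    iy <- max(1, iv[k, 2]):min(d[2], iv[k, 2] + 2)
    iz <- max(1, iv[k, 3]):min(d[3], iv[k, 3] + 2)
    max(img[ix, iy, iz])
  }, numeric(1))
  (mean(peaks) - mean(bg)) / stats::sd(bg)
}
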