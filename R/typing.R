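#' Estimate the capillary axis from a structure mask or point set
#'
#' Principal direction (leading eigenvector) of the voxel-center coordinates
#' of a mask (subsampled for speed) or of a point matrix, in gel nm.
#'
#' @param x logical 3D mask array or an n x 3 coordinate matrix (gel nm).
#' @param voxel_size_gel voxel pitch, used when `x` is a mask.
#' @param max_points subsample cap for mask voxels.
#' @return list with unit `direction` (length-3), `center` (gel nm) and
#'   `radial_median` (median radial distance of the points from the axis,
#'   gel nm).
#' @export
estimate_capillary_axis <- function(x, voxel_size_gel = c(108, 108, 310),
                                    max_points = 20000) {
  if (is.array(x) || is.logical(x)) {
    d <- dim(x)
    fg <- which(as.logical(x))
    if (!length(fg)) stop_exm("empty mask", "exmloc_no_reference")
    if (length(fg) > max_points)
      fg <- fg[round(seq(1, length(fg), length.out = max_points))]
    ix <- (fg - 1L) %% d[1]
    iy <- ((fg - 1L) %/% d[1]) %% d[2]
    iz <- (fg - 1L) %/% (d[1] * d[2])
    pts <- cbind((ix + 0.5) * voxel_size_gel[1],
                 (iy + 0.5) * voxel_size_gel[2],
                 (iz + 0.5) * voxel_size_gel[3])
  } else pts <- as.matrix(x)
  ctr <- colMeans(pts)
  cv <- stats::cov(sweep(pts, 2, ctr))
  ev <- eigen(cv, symmetric = TRUE)
  dir <- ev$vectors[, 1]
  dir <- dir / sqrt(sum(dir^2))
  cent <- sweep(pts, 2, ctr)
  t_par <- cent %*% dir
  radial <- sqrt(pmax(rowSums(cent^2) - t_par[, 1]^2, 0))
  list(direction = dir, center = ctr, radial_median = stats::median(radial))
}

#' Classify a capillary by its nuclei signature
#'
#' Rule-based formalization of visual capillary typing from nuclei density
#' and positioning: nuclei are classed as axial (near the axis line),
#' peripheral (radially displaced), or perpendicular (elongated with long
#' axis more than `perp_angle_deg` away from the capillary axis). Type 1 has
#' at most `t1_max_peripheral` peripheral nuclei and no perpendicular ones;
#' any perpendicular nucleus makes type 3; everything else is type 2.
#'
#' @param nuclei_spots a `spot_set` of detected nuclei extracted with
#'   `moments = TRUE`.
#' @param axis capillary axis estimate from [estimate_capillary_axis()]
#'   (typically from the collagen mask).
#' @param t1_max_peripheral maximum peripheral nuclei for type 1 (default 2).
#' @param perp_angle_deg angle threshold to the capillary axis beyond which
#'   an elongated nucleus counts as perpendicular (default 60).
#' @param min_elongation minimum long/short axis ratio for a nucleus to have
#'   a defined orientation (default 1.4).
#' @param peripheral_frac radial offset, as a fraction of the axis estimate's
#'   median radial distance, beyond which a nucleus is peripheral
#'   (default 0.5).
#' @return list with `capillary_type` (1, 2 or 3) and a per-nucleus feature
#'   report (`radial_offset_nm`, `angle_deg`, `elongation`, `class`).
#' @export
classify_capillary_type <- function(nuclei_spots, axis,
                                    t1_max_peripheral = 2,
                                    perp_angle_deg = 60,
                                    min_elongation = 1.4,
                                    peripheral_frac = 0.5) {
  if (nrow(nuclei_spots) == 0)
    stop_exm("no nuclei detected; capillary cannot be typed",
             "exmloc_untypeable")
  mom <- attr(nuclei_spots, "moments")
  if (is.null(mom))
    stop_exm("nuclei spot_set must be extracted with moments = TRUE",
             "exmloc_config")
  pts <- spot_coords(nuclei_spots)
  cent <- sweep(pts, 2, axis$center)
  t_par <- cent %*% axis$direction
  radial <- sqrt(pmax(rowSums(cent^2) - t_par[, 1]^2, 0))
  feats <- data.frame(spot_id = nuclei_spots$spot_id,
                      radial_offset_nm = radial,
                      angle_deg = NA_real_, elongation = NA_real_,
                      class = NA_character_)
  thresh <- peripheral_frac * axis$radial_median
  for (k in seq_len(nrow(nuclei_spots))) {
    ev <- eigen(mom[[k]], symmetric = TRUE)
    long_axis <- ev$vectors[, 1]
    elong <- sqrt(max(ev$values[1], 0) / max(ev$values[2], 1e-12))
    ang <- acos(pmin(abs(sum(long_axis * axis$direction)), 1)) * 180 / pi
    feats$angle_deg[k] <- ang
    feats$elongation[k] <- elong
    feats$class[k] <-
      if (elong >= min_elongation && ang > perp_angle_deg) "perpendicular"
      else if (radial[k] > thresh) "peripheral"
      else "axial"
  }
  n_perp <- sum(feats$class == "perpendicular")
  n_peri <- sum(feats$class == "peripheral")
  type <- if (n_perp >= 1) 3L
          else if (n_peri <= t1_max_peripheral) 1L
          else 2L
  list(capillary_type = type, features = feats,
       counts = c(axial = sum(feats$class == "axial"),
                  peripheral = n_peri, perpendicular = n_perp))
}

#' Nuclei size uniformity QC
#'
#' Capillaries whose nuclei are not uniform in size indicate locally
#' non-uniform expansion and are disregarded. The check computes the
#' coefficient of variation of the nuclei equivalent spherical diameters
#' (from component voxel volumes) and passes when it is at most
#' `cv_threshold`.
#'
#' @param nuclei_spots a `spot_set` of detected nuclei.
#' @param cv_threshold maximum allowed CV (default 0.25).
#' @return list with `qc_pass`, `cv` and the equivalent diameters (gel nm).
#' @export
nuclei_uniformity_qc <- function(nuclei_spots, cv_threshold = 0.25) {
  if (nrow(nuclei_spots) < 3)
    stop_exm("need at least 3 nuclei for a size-uniformity QC",
             "exmloc_insufficient_nuclei")
  vs <- attr(nuclei_spots, "voxel_size_gel")
  vol_nm3 <- nuclei_spots$voxels * prod(vs)
  diam <- (6 * vol_nm3 / pi)^(1 / 3)
  cv <- stats::sd(diam) / mean(diam)
  list(qc_pass = cv <= cv_threshold, cv = cv, equivalent_diameter_nm = diam)
}

#' Detect nuclei in the nuclei channel
#'
#' Nuclei are bright, large structures occupying a small volume fraction, so
#' the threshold is placed halfway between the background level (median of
#' the volume) and the structure plateau (0.999 quantile) -- a half-maximum
#' edge criterion that is robust when foreground is rare. Connected
#' components are extracted with second moments for orientation analysis.
#'
#' @param stack an `exm_stack` with a `nuclei` channel.
#' @param min_voxels minimum nucleus size in voxels.
#' @return a `spot_set` with moments.
#' @export
detect_nuclei <- function(stack, min_voxels = 50) {
  img <- stack$channels$nuclei
  thr <- 0.5 * (stats::quantile(img, 0.999, names = FALSE) +
                  stats::median(img))
  extract_spots(img > thr, stack$voxel_size_gel, min_voxels = min_voxels,
                moments = TRUE)
}
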