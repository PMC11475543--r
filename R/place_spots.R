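#' Place receptor spots at controlled distances from the collagen shell
#'
#' Draws a ground-truth receptor spot set for a capillary geometry. Each spot
#' is assigned a distance bin from `bin_mixture` and its distance to the inner
#' surface of the collagen shell is drawn uniformly inside that bin; the spot
#' is placed radially at `lumen_radius + wall_thickness - d` from the tube
#' axis (inside the endothelial wall for `d` up to the wall thickness, in the
#' lumen for larger `d`), at a uniform axial position and azimuth. Bins that
#' reach deeper than the tube's inner-shell radius are geometrically
#' infeasible and raise an error.
#'
#' @param geometry a [build_geometry()] result.
#' @param n_spots number of receptor spots, `>= 1`.
#' @param bin_mixture named probability vector over the labels of `bins`
#'   (must sum to 1).
#' @param bins a [bin_spec()].
#' @param acq acquisition model (used for an axial placement margin of 3 PSF
#'   sigmas so spots are not clipped at the volume ends).
#' @param seed integer seed for the placement substream.
#' @return object of class `simulation_truth`: list with `spots` (data.frame
#'   `spot_id, x_nm, y_nm, z_nm, true_distance_nm, true_bin`, biological nm),
#'   `abluminal_fraction_true`, `capillary_type`, `bins`.
#' @export
place_spots <- function(geometry, n_spots, bin_mixture,
                        bins = bin_spec(), acq = acquisition_model(),
                        seed = 1L) {
  if (!is.numeric(n_spots) || length(n_spots) != 1 || n_spots < 1)
    stop_exm("n_spots must be >= 1", "exmloc_config")
  n_spots <- as.integer(n_spots)
  if (is.null(names(bin_mixture)) ||
      !all(names(bin_mixture) %in% bins$labels))
    stop_exm("bin_mixture must be named by bin labels", "exmloc_config")
  mix <- stats::setNames(numeric(length(bins$labels)), bins$labels)
  mix[names(bin_mixture)] <- bin_mixture
  if (abs(sum(mix) - 1) > 1e-8)
    stop_exm("bin_mixture must sum to 1", "exmloc_config")

  r_in_shell <- geometry$lumen_radius + geometry$wall_thickness
  lo <- bins$edges_bio_nm[-length(bins$edges_bio_nm)]
  hi <- bins$edges_bio_nm[-1]
  infeasible <- mix > 0 & hi > r_in_shell
  if (any(infeasible))
    stop_exm(sprintf(
      "bin(s) %s extend beyond the inner-shell radius (%g nm); placement infeasible",
      paste(bins$labels[infeasible], collapse = ", "), r_in_shell),
      "exmloc_placement_infeasible")

  E <- acq$expansion_factor
  pad_x <- 3 * acq$psf_sigma_gel[1] / E + 100
  if (geometry$extent_bio[1] <= 2 * pad_x)
    stop_exm("volume too short along x for spot placement",
             "exmloc_geometry_fit")

  with_seed(seed_stream(seed, "placement"), {
    bin_idx <- sample.int(length(mix), n_spots, replace = TRUE, prob = mix)
    d <- stats::runif(n_spots, lo[bin_idx], hi[bin_idx])
    x <- stats::runif(n_spots, pad_x, geometry$extent_bio[1] - pad_x)
    theta <- stats::runif(n_spots, 0, 2 * pi)
    rho <- r_in_shell - d
    ctr <- tube_center_at(geometry, x)
    spots <- data.frame(
      spot_id = seq_len(n_spots),
      x_nm = x,
      y_nm = ctr[, 1] + rho * cos(theta),
      z_nm = ctr[, 2] + rho * sin(theta),
      true_distance_nm = d,
      true_bin = bins$labels[bin_idx],
      stringsAsFactors = FALSE
    )
    structure(list(
      spots = spots,
      abluminal_fraction_true = mean(bins$labels[bin_idx] == bins$labels[1]),
      capillary_type = geometry$capillary_type,
      bins = bins,
      seed = as.integer(seed)
    ), class = "simulation_truth")
  })
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("Simulation truth: %d receptor spots (type %d capillary)\n",
              nrow(x$spots), x$capillary_type))
  cat(sprintf("  true abluminal fraction: %.3f\n", x$abluminal_fraction_true))
  print(table(factor(x$spots$true_bin, levels = x$bins$labels)))
  invisible(x)
}
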