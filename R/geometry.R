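#' Default geometry parameters for a capillary type
#'
#' Capillaries are typed by their nuclei signature: type 1 (microcapillaries)
#' show a discontinuous axial line of endothelial nuclei with at most a few
#' peripheral nuclei; type 2 adds several peripheral nuclei around the axial
#' line; type 3 (pre-capillary-like) additionally carries elongated nuclei
#' oriented perpendicular to the vessel axis, as mural cells wrap around the
#' tube. All lengths are biological nm.
#'
#' @param capillary_type 1, 2 or 3.
#' @return named list of geometry parameters (radii, nuclei counts and radii,
#'   jitter settings) that [build_geometry()] consumes.
#' @export
capillary_params <- function(capillary_type = 1) {
  if (!capillary_type %in% 1:3)
    stop_exm("capillary_type must be 1, 2 or 3", "exmloc_bad_type")
  base <- list(
    lumen_radius = 2700,
    wall_thickness = 500,
    collagen_shell_thickness = 100,
    bend_amplitude = 0,          # sinusoidal centerline bend, bio nm
    bend_period = 20000,
    n_axial = 4L,
    n_peripheral_range = c(0L, 2L),
    n_perpendicular_range = c(0L, 0L),
    axial_radii = c(800, 300, 300),
    peripheral_radii = c(450, 350, 350),
    perpendicular_radii = c(800, 300, 300),
    axial_offset_frac = c(0, 0.2),        # radial offset / lumen_radius
    peripheral_offset_frac = c(0.85, 1),  # radial offset / (lumen + wall)
    nuclei_radius_cv = 0.08,              # lognormal size jitter
    nuclei_uniform = TRUE,
    nonuniform_radius_cv = 0.45
  )
  if (capillary_type == 2) {
    base$n_peripheral_range <- c(4L, 6L)
  } else if (capillary_type == 3) {
    base$n_axial <- 3L
    base$n_peripheral_range <- c(2L, 4L)
    base$n_perpendicular_range <- c(1L, 3L)
  }
  base
}

#' Build a ground-truth capillary geometry
#'
#' Constructs the tube (lumen, endothelial wall, thin abluminal collagen IV
#' shell) and the type-specific nuclei arrangement inside a simulation volume.
#' The tube axis runs along x through the volume center, optionally with a
#' gentle sinusoidal bend in y. The whole shell plus 3 PSF sigmas must fit
#' radially inside the volume, otherwise a geometry-fit error is raised.
#'
#' @param capillary_type 1, 2 or 3 (nuclei signature, see [capillary_params()]).
#' @param volume_shape integer length 3, volume size in voxels (x, y, z).
#' @param acq an [acquisition_model()] (voxel sizes, expansion factor, PSF).
#' @param params named list of overrides merged over [capillary_params()].
#' @param seed integer seed for the geometry substream.
#' @return object of class `capillary_geometry` with the centerline polyline,
#'   radii and a nuclei table (center, ellipsoid radii, orientation unit
#'   vector, orientation class).
#' @export
build_geometry <- function(capillary_type = 1,
                           volume_shape = c(384, 384, 128),
                           acq = acquisition_model(),
                           params = list(),
                           seed = 1L) {
  p <- utils::modifyList(capillary_params(capillary_type), params)
  E <- acq$expansion_factor
  extent_bio <- volume_shape * acq$voxel_size_gel / E
  psf_bio <- acq$psf_sigma_gel / E

  r_out <- p$lumen_radius + p$wall_thickness + p$collagen_shell_thickness
  margin_needed <- p$collagen_shell_thickness + 3 * max(psf_bio)
  if (r_out + abs(p$bend_amplitude) + margin_needed > min(extent_bio[2:3]) / 2)
    stop_exm(sprintf(
      "capillary (outer radius %g nm + margin %g nm) does not fit in volume of %g x %g nm cross-section (biological scale)",
      r_out, margin_needed, extent_bio[2], extent_bio[3]),
      "exmloc_geometry_fit")

  with_seed(seed_stream(seed, "geometry"), {
    # centerline sampled once per x-voxel column
    xs <- voxel_centers(volume_shape[1], acq$voxel_size_gel[1]) / E
    yc <- extent_bio[2] / 2 +
      p$bend_amplitude * sin(2 * pi * xs / p$bend_period)
    zc <- rep(extent_bio[3] / 2, length(xs))
    centerline <- cbind(x = xs, y = yc, z = zc)

    center_at <- function(x) {
      c(extent_bio[2] / 2 + p$bend_amplitude * sin(2 * pi * x / p$bend_period),
        extent_bio[3] / 2)
    }

    n_per <- if (p$n_peripheral_range[1] == p$n_peripheral_range[2])
      p$n_peripheral_range[1] else
      sample(p$n_peripheral_range[1]:p$n_peripheral_range[2], 1)
    n_perp <- if (p$n_perpendicular_range[1] == p$n_perpendicular_range[2])
      p$n_perpendicular_range[1] else
      sample(p$n_perpendicular_range[1]:p$n_perpendicular_range[2], 1)

    cv <- if (isTRUE(p$nuclei_uniform)) p$nuclei_radius_cv else
      p$nonuniform_radius_cv
    sdlog <- sqrt(log(1 + cv^2))

    nuclei <- list()
    add_nucleus <- function(x, offset, azim, radii, axis_vec, class) {
      ctr <- center_at(x)
      jit <- exp(stats::rnorm(1, -sdlog^2 / 2, sdlog))
      nuclei[[length(nuclei) + 1]] <<- data.frame(
        cx = x, cy = ctr[1] + offset * cos(azim), cz = ctr[2] + offset * sin(azim),
        ra = radii[1] * jit, rb = radii[2] * jit, rc = radii[3] * jit,
        ox = axis_vec[1], oy = axis_vec[2], oz = axis_vec[3],
        orientation = class, stringsAsFactors = FALSE)
    }

    # axial nuclei: evenly spaced discontinuous line along the tube axis
    pad_x <- p$axial_radii[1] * 1.2
    if ((p$n_axial > 0 || p$n_peripheral_range[2] > 0 ||
         p$n_perpendicular_range[2] > 0) && 2 * pad_x >= extent_bio[1])
      stop_exm(sprintf(
        "nuclei (axial radius %g nm) do not fit along a %g nm volume",
        p$axial_radii[1], extent_bio[1]), "exmloc_geometry_fit")
    if (p$n_axial > 0) {
      slots <- seq(pad_x, extent_bio[1] - pad_x, length.out = max(p$n_axial, 2))
      slots <- slots[seq_len(p$n_axial)] +
        stats::runif(p$n_axial, -0.05, 0.05) * extent_bio[1] / p$n_axial
      for (x in slots) {
        off <- stats::runif(1, p$axial_offset_frac[1], p$axial_offset_frac[2]) *
          p$lumen_radius
        add_nucleus(x, off, stats::runif(1, 0, 2 * pi), p$axial_radii,
                    c(1, 0, 0), "axial")
      }
    }
    r_wall <- p$lumen_radius + p$wall_thickness
    for (i in seq_len(n_per)) {
      x <- stats::runif(1, pad_x, extent_bio[1] - pad_x)
      off <- stats::runif(1, p$peripheral_offset_frac[1],
                          p$peripheral_offset_frac[2]) * r_wall
      add_nucleus(x, off, stats::runif(1, 0, 2 * pi), p$peripheral_radii,
                  c(1, 0, 0), "peripheral")
    }
    for (i in seq_len(n_perp)) {
      x <- stats::runif(1, pad_x, extent_bio[1] - pad_x)
      azim <- stats::runif(1, 0, 2 * pi)
      off <- stats::runif(1, p$peripheral_offset_frac[1],
                          p$peripheral_offset_frac[2]) * r_wall
      # long axis tangential in the cross-sectional plane: perpendicular to x
      axis_vec <- c(0, -sin(azim), cos(azim))
      add_nucleus(x, off, azim, p$perpendicular_radii, axis_vec, "perpendicular")
    }
    nuclei <- if (length(nuclei)) do.call(rbind, nuclei) else
      data.frame(cx = numeric(0), cy = numeric(0), cz = numeric(0),
                 ra = numeric(0), rb = numeric(0), rc = numeric(0),
                 ox = numeric(0), oy = numeric(0), oz = numeric(0),
                 orientation = character(0))

    structure(list(
      capillary_type = as.integer(capillary_type),
      centerline = centerline,
      lumen_radius = p$lumen_radius,
      wall_thickness = p$wall_thickness,
      collagen_shell_thickness = p$collagen_shell_thickness,
      nuclei = nuclei,
      volume_shape = as.integer(volume_shape),
      extent_bio = extent_bio,
      params = p,
      seed = as.integer(seed)
    ), class = "capillary_geometry")
  })
}

#' @export
print.capillary_geometry <- function(x, ...) {
  tab <- table(factor(x$nuclei$orientation,
                      levels = c("axial", "peripheral", "perpendicular")))
  cat(sprintf("Capillary geometry (type %d)\n", x$capillary_type))
  cat(sprintf("  lumen %g nm, wall %g nm, collagen shell %g nm (biological)\n",
              x$lumen_radius, x$wall_thickness, x$collagen_shell_thickness))
  cat(sprintf("  volume %d x %d x %d voxels (%.1f x %.1f x %.1f um biological)\n",
              x$volume_shape[1], x$volume_shape[2], x$volume_shape[3],
              x$extent_bio[1] / 1000, x$extent_bio[2] / 1000,
              x$extent_bio[3] / 1000))
  cat(sprintf("  nuclei: %d axial, %d peripheral, %d perpendicular\n",
              tab["axial"], tab["peripheral"], tab["perpendicular"]))
  invisible(x)
}

# y,z center of the tube at biological x (bend-aware)
tube_center_at <- function(geometry, x) {
  p <- geometry$params
  cbind(geometry$extent_bio[2] / 2 +
          p$bend_amplitude * sin(2 * pi * x / p$bend_period),
        geometry$extent_bio[3] / 2)
}
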