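#' Volumetric signal dilution for isotropic expansion
#'
#' Physical expansion of a specimen by a linear factor `E` in three dimensions
#' spreads the same fluorophores over an `E^3`-fold larger volume, so the
#' per-voxel signal is diluted by `E^3` (125-fold at 5x expansion).
#'
#' @param E linear expansion factor, `E >= 1`.
#' @return the volumetric dilution factor `E^3`.
#' @examples
#' signal_dilution_factor(5) # 125
#' @export
signal_dilution_factor <- function(E) {
  if (!is.numeric(E) || length(E) != 1 || is.na(E) || E < 1)
    stop_exm("expansion factor E must be a single number >= 1",
             "exmloc_invalid_expansion")
  E^3
}

#' Acquisition and noise model for simulated stacks
#'
#' Bundles the imaging parameters used to render synthetic capillary stacks:
#' voxel sizes of the (gel-space) confocal grid, the linear expansion factor,
#' an anisotropic Gaussian PSF, photon budgets and camera noise. The defaults
#' reproduce the acquisition geometry used throughout the package: 108 nm
#' lateral and 310 nm axial voxels at 5x expansion. The photon and noise
#' defaults are a frozen preset chosen so that the rendered receptor channel
#' has a low signal-to-noise ratio (peak over background sd of about 2-5),
#' the regime that motivates trained pixel classification over classical
#' thresholding.
#'
#' @param voxel_size_gel numeric length 3, voxel pitch (x, y, z) in gel nm.
#' @param expansion_factor linear expansion factor `E >= 1`.
#' @param psf_sigma_gel numeric length 3, Gaussian PSF sigma (x, y, z) in gel
#'   nm; `c(0, 0, 0)` renders with a delta-like PSF (no blur).
#' @param photons_per_marker expected photons per receptor fluorophore cluster
#'   before expansion dilution; the rendered mean scales as
#'   `photons_per_marker / E^3`.
#' @param collagen_photons_per_voxel,nuclei_photons_per_voxel expected photons
#'   per structure voxel before dilution for the extended structures.
#' @param background_rate mean background photons per voxel.
#' @param read_noise_sd Gaussian read noise sd in photons.
#' @param seed integer master seed for rendering noise.
#' @return an object of class `acquisition_model`.
#' @export
acquisition_model <- function(voxel_size_gel = c(108, 108, 310),
                              expansion_factor = 5,
                              psf_sigma_gel = c(110, 110, 300),
                              photons_per_marker = 20000,
                              collagen_photons_per_voxel = 2000,
                              nuclei_photons_per_voxel = 4000,
                              background_rate = 5,
                              read_noise_sd = 2,
                              seed = 1L) {
  if (!is.numeric(expansion_factor) || length(expansion_factor) != 1 ||
      expansion_factor < 1)
    stop_exm("expansion_factor must be >= 1", "exmloc_invalid_expansion")
  stopifnot(length(voxel_size_gel) == 3, all(voxel_size_gel > 0),
            length(psf_sigma_gel) == 3, all(psf_sigma_gel >= 0),
            photons_per_marker > 0, background_rate >= 0, read_noise_sd >= 0)
  structure(list(
    voxel_size_gel = as.numeric(voxel_size_gel),
    expansion_factor = as.numeric(expansion_factor),
    psf_sigma_gel = as.numeric(psf_sigma_gel),
    photons_per_marker = photons_per_marker,
    collagen_photons_per_voxel = collagen_photons_per_voxel,
    nuclei_photons_per_voxel = nuclei_photons_per_voxel,
    background_rate = background_rate,
    read_noise_sd = read_noise_sd,
    seed = as.integer(seed)
  ), class = "acquisition_model")
}

#' Expansion model mapping gel-space lengths to biological lengths
#'
#' @param linear_factor linear expansion factor `E >= 1`; biological length =
#'   gel length / E.
#' @param voxel_size_gel voxel pitch (x, y, z) in gel nm.
#' @return object of class `expansion_model`.
#' @export
expansion_model <- function(linear_factor = 5,
                            voxel_size_gel = c(108, 108, 310)) {
  if (!is.numeric(linear_factor) || length(linear_factor) != 1 ||
      linear_factor < 1)
    stop_exm("linear_factor must be >= 1", "exmloc_invalid_expansion")
  stopifnot(length(voxel_size_gel) == 3, all(voxel_size_gel > 0))
  structure(list(linear_factor = as.numeric(linear_factor),
                 voxel_size_gel = as.numeric(voxel_size_gel)),
            class = "expansion_model")
}

#' @export
print.acquisition_model <- function(x, ...) {
  cat("Acquisition model\n")
  cat(sprintf("  voxel size (gel): %g x %g x %g nm\n", x$voxel_size_gel[1],
              x$voxel_size_gel[2], x$voxel_size_gel[3]))
  cat(sprintf("  expansion factor: %gx (signal dilution %g)\n",
              x$expansion_factor, signal_dilution_factor(x$expansion_factor)))
  cat(sprintf("  PSF sigma (gel): %g x %g x %g nm\n", x$psf_sigma_gel[1],
              x$psf_sigma_gel[2], x$psf_sigma_gel[3]))
  cat(sprintf("  photons/marker: %g, background: %g, read noise sd: %g\n",
              x$photons_per_marker, x$background_rate, x$read_noise_sd))
  invisible(x)
}
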