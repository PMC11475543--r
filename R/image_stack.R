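#' Construct a multi-channel 3D image stack
#'
#' @param channels named list of 3D numeric arrays sharing one dimension
#'   (x, y, z).
#' @param voxel_size_gel voxel pitch (x, y, z) in gel-space nm.
#' @param expansion_factor linear expansion factor `E >= 1`; biological
#'   length = gel length / E.
#' @return object of class `exm_stack`.
#' @export
image_stack <- function(channels, voxel_size_gel = c(108, 108, 310),
                        expansion_factor = 5) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop_exm("channels must be a named list of arrays", "exmloc_config")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3))
    stop_exm("each channel must be a 3D array", "exmloc_config")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop_exm("all channels must share one shape", "exmloc_config")
  if (expansion_factor < 1)
    stop_exm("expansion_factor must be >= 1", "exmloc_invalid_expansion")
  stopifnot(length(voxel_size_gel) == 3, all(voxel_size_gel > 0))
  structure(list(channels = channels,
                 dim = dims[[1]],
                 voxel_size_gel = as.numeric(voxel_size_gel),
                 expansion_factor = as.numeric(expansion_factor)),
            class = "exm_stack")
}

#' @export
print.exm_stack <- function(x, ...) {
  cat(sprintf("Image stack: %d x %d x %d voxels, channels: %s\n",
              x$dim[1], x$dim[2], x$dim[3],
              paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  voxel size (gel): %g x %g x %g nm, expansion %gx\n",
              x$voxel_size_gel[1], x$voxel_size_gel[2], x$voxel_size_gel[3],
              x$expansion_factor))
  invisible(x)
}

#' Write a stack as multi-page TIFF with a JSON metadata sidecar
#'
#' Pages are z-slices, channel blocks in channel order; intensities are
#' stored as 16-bit unsigned integers. Voxel sizes, expansion factor and
#' channel names go to `<path>.json` so that the round trip is bit-exact.
#'
#' @param stack an `exm_stack` (integer-valued intensities in `[0, 65535]`).
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "exm_stack"))
  mx <- max(vapply(stack$channels, max, 0))
  if (mx > 65535)
    stop_exm("intensities exceed 16-bit range", "exmloc_config")
  pages <- list()
  for (ch in names(stack$channels)) {
    arr <- stack$channels[[ch]]
    for (z in seq_len(stack$dim[3]))
      pages[[length(pages) + 1]] <- t(arr[, , z]) / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  meta <- list(channels = names(stack$channels),
               dim = stack$dim,
               voxel_size_gel = stack$voxel_size_gel,
               expansion_factor = stack$expansion_factor)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a stack written by [write_stack()]
#'
#' @param path TIFF path; metadata comes from the `<path>.json` sidecar or,
#'   failing that, from the explicit arguments.
#' @param channels optional character vector of required channel names;
#'   a missing channel raises an error naming it. May also be a named
#'   character vector mapping stored names to new names
#'   (e.g. `c(ch488 = "receptor")`).
#' @param voxel_size_gel,expansion_factor metadata overrides used when no
#'   sidecar is present.
#' @return an `exm_stack`.
#' @export
read_stack <- function(path, channels = NULL, voxel_size_gel = NULL,
                       expansion_factor = NULL) {
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  } else {
    if (is.null(voxel_size_gel) || is.null(expansion_factor) ||
        is.null(channels))
      stop_exm("no metadata sidecar and no metadata supplied via arguments",
               "exmloc_metadata")
    meta <- NULL
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.null(meta)) {
    n_ch <- length(if (is.null(names(channels))) channels else names(channels))
    nz <- length(pages) / n_ch
    if (nz != floor(nz))
      stop_exm("page count is not a multiple of the channel count",
               "exmloc_metadata")
    meta <- list(channels = if (is.null(names(channels))) channels else
                   names(channels),
                 dim = c(ncol(pages[[1]]), nrow(pages[[1]]), nz),
                 voxel_size_gel = voxel_size_gel,
                 expansion_factor = expansion_factor)
  }
  d <- as.integer(meta$dim)
  stored <- as.character(meta$channels)
  chans <- list()
  for (i in seq_along(stored)) {
    arr <- array(0, d)
    for (z in seq_len(d[3]))
      arr[, , z] <- t(pages[[(i - 1) * d[3] + z]]) * 65535
    chans[[stored[i]]] <- round(arr)
  }
  if (!is.null(channels)) {
    want <- if (is.null(names(channels))) channels else names(channels)
    missing_ch <- setdiff(want, stored)
    if (length(missing_ch))
      stop_exm(paste0("channel(s) absent from stack: ",
                      paste(missing_ch, collapse = ", ")),
               "exmloc_channel")
    if (!is.null(names(channels)))
      names(chans)[match(names(channels), names(chans))] <- unname(channels)
  }
  image_stack(chans, voxel_size_gel = as.numeric(meta$voxel_size_gel),
              expansion_factor = as.numeric(meta$expansion_factor))
}
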