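# central finite differences with edge replication along one axis
shift_axis <- function(arr, axis, by) {
  d <- dim(arr)
  idx <- pmin(pmax(seq_len(d[axis]) + by, 1L), d[axis])
  switch(axis,
         arr[idx, , , drop = FALSE],
         arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}

gradient_magnitude <- function(arr, voxel_size) {
  g2 <- array(0, dim(arr))
  for (ax in 1:3) {
    g <- (shift_axis(arr, ax, 1L) - shift_axis(arr, ax, -1L)) /
      (2 * voxel_size[ax])
    g2 <- g2 + g * g
  }
  sqrt(g2)
}

laplacian <- function(arr, voxel_size) {
  out <- array(0, dim(arr))
  for (ax in 1:3)
    out <- out + (shift_axis(arr, ax, 1L) - 2 * arr +
                    shift_axis(arr, ax, -1L)) / voxel_size[ax]^2
  out
}

#' Extract per-voxel multiscale features from one channel
#'
#' Handcrafted feature hierarchy for trainable pixel classification: the raw
#' intensity plus, at each smoothing scale, the Gaussian-smoothed intensity,
#' the gradient magnitude and the Laplacian (both computed on the smoothed
#' volume with anisotropic physical voxel sizes). Deterministic.
#'
#' @param stack an `exm_stack`.
#' @param channel channel name.
#' @param scales_nm smoothing scales (Gaussian sigma) in gel nm; each must be
#'   at least one (finest) voxel.
#' @return numeric matrix, one row per voxel (R array order), one column per
#'   feature, with descriptive column names.
#' @export
extract_features <- function(stack, channel,
                             scales_nm = c(150, 300, 600)) {
  if (!channel %in% names(stack$channels))
    stop_exm(paste0("unknown channel: ", channel), "exmloc_channel")
  vs <- stack$voxel_size_gel
  if (any(scales_nm < min(vs)))
    stop_exm("feature scales must be at least one voxel", "exmloc_config")
  img <- stack$channels[[channel]]
  nvox <- prod(dim(img))
  feats <- matrix(0, nvox, 1 + 3 * length(scales_nm))
  cn <- "intensity"
  feats[, 1] <- as.numeric(img)
  j <- 1
  for (s in scales_nm) {
    sm <- blur_volume(img, s / vs)
    feats[, j + 1] <- as.numeric(sm)
    feats[, j + 2] <- as.numeric(gradient_magnitude(sm, vs))
    feats[, j + 3] <- as.numeric(laplacian(sm, vs))
    cn <- c(cn, paste0(c("smooth_", "gradmag_", "laplacian_"), s))
    j <- j + 3
  }
  colnames(feats) <- cn
  feats
}
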