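#' Extract labeled spots from a binary mask
#'
#' Connected components (26-neighborhood by default) of a segmentation mask;
#' components smaller than `min_voxels` are discarded (their voxel count is
#' reported in the attributes, never silently lost). Centroids are
#' intensity-unweighted means of voxel centers converted to gel-space nm.
#'
#' @param mask logical 3D array.
#' @param voxel_size_gel voxel pitch (x, y, z) in gel nm.
#' @param min_voxels minimum component size in voxels (default 4).
#' @param connectivity 26 (default) or 6.
#' @param moments also compute per-spot second central moment matrices
#'   (needed for nuclei orientation analysis).
#' @return a `spot_set`: data.frame with `spot_id, cx_nm, cy_nm, cz_nm,
#'   voxels` (gel nm), attributes `voxel_size_gel`, `total_mask_voxels`,
#'   `discarded_voxels`, `connectivity`, and (with `moments = TRUE`) a list
#'   column-free attribute `moments` of 3x3 covariance matrices in gel nm^2.
#' @export
extract_spots <- function(mask, voxel_size_gel = c(108, 108, 310),
                          min_voxels = 4, connectivity = 26,
                          moments = FALSE) {
  d <- dim(mask)
  stopifnot(length(d) == 3)
  labels <- .label_components(as.logical(mask), as.integer(d),
                              as.integer(connectivity))
  total <- sum(labels > 0L)
  empty <- data.frame(spot_id = integer(0), cx_nm = numeric(0),
                      cy_nm = numeric(0), cz_nm = numeric(0),
                      voxels = integer(0))
  if (total == 0) {
    return(structure(empty, class = c("spot_set", "data.frame"),
                     voxel_size_gel = voxel_size_gel, total_mask_voxels = 0L,
                     discarded_voxels = 0L, connectivity = connectivity))
  }
  fg <- which(labels > 0L)
  lab <- labels[fg]
  # 0-based voxel indices -> physical voxel-center coordinates
  ix <- (fg - 1L) %% d[1]
  iy <- ((fg - 1L) %/% d[1]) %% d[2]
  iz <- (fg - 1L) %/% (d[1] * d[2])
  px <- (ix + 0.5) * voxel_size_gel[1]
  py <- (iy + 0.5) * voxel_size_gel[2]
  pz <- (iz + 0.5) * voxel_size_gel[3]
  counts <- as.integer(rowsum(rep(1L, length(lab)), lab))
  keep_lab <- sort(unique(lab))[counts >= min_voxels]
  discarded <- total - sum(counts[counts >= min_voxels])
  if (!length(keep_lab)) {
    return(structure(empty, class = c("spot_set", "data.frame"),
                     voxel_size_gel = voxel_size_gel,
                     total_mask_voxels = as.integer(total),
                     discarded_voxels = as.integer(discarded),
                     connectivity = connectivity))
  }
  sel <- lab %in% keep_lab
  lab2 <- match(lab[sel], keep_lab)
  n <- as.integer(rowsum(rep(1L, sum(sel)), lab2))
  cx <- rowsum(px[sel], lab2)[, 1] / n
  cy <- rowsum(py[sel], lab2)[, 1] / n
  cz <- rowsum(pz[sel], lab2)[, 1] / n
  out <- data.frame(spot_id = seq_along(keep_lab), cx_nm = cx, cy_nm = cy,
                    cz_nm = cz, voxels = n)
  rownames(out) <- NULL
  mom <- NULL
  if (moments) {
    sxx <- rowsum(px[sel]^2, lab2)[, 1] / n - cx^2
    syy <- rowsum(py[sel]^2, lab2)[, 1] / n - cy^2
    szz <- rowsum(pz[sel]^2, lab2)[, 1] / n - cz^2
    sxy <- rowsum(px[sel] * py[sel], lab2)[, 1] / n - cx * cy
    sxz <- rowsum(px[sel] * pz[sel], lab2)[, 1] / n - cx * cz
    syz <- rowsum(py[sel] * pz[sel], lab2)[, 1] / n - cy * cz
    mom <- lapply(seq_along(keep_lab), function(k)
      matrix(c(sxx[k], sxy[k], sxz[k],
               sxy[k], syy[k], syz[k],
               sxz[k], syz[k], szz[k]), 3, 3))
  }
  structure(out, class = c("spot_set", "data.frame"),
            voxel_size_gel = voxel_size_gel,
            total_mask_voxels = as.integer(total),
            discarded_voxels = as.integer(discarded),
            connectivity = connectivity, moments = mom)
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("Spot set: %d spots (%d mask voxels, %d in discarded small components)\n",
              nrow(x), attr(x, "total_mask_voxels"),
              attr(x, "discarded_voxels")))
  NextMethod()
}
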