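spot_coords <- function(spots) {
  as.matrix(spots[, c("cx_nm", "cy_nm", "cz_nm")])
}

make_distance_table <- function(ids, ref, d_gel, E, mode) {
  out <- data.frame(receptor_spot_id = ids,
                    collagen_ref = ref,
                    distance_gel_nm = d_gel,
                    distance_bio_nm = d_gel / E)
  structure(out, class = c("distance_table", "data.frame"),
            metric_mode = mode, expansion_factor = E)
}

#' Nearest receptor-to-collagen distances
#'
#' For every receptor spot, the closest distance to the collagen IV reference
#' structure, computed on anisotropic physical (gel nm) coordinates and then
#' divided by the expansion factor to give the biological-scale distance.
#' Two metric modes: `centroid_to_centroid` takes the Euclidean distance to
#' the nearest collagen spot centroid (kd-tree accelerated);
#' `centroid_to_surface` (default) takes the distance to the nearest voxel
#' center of the collagen mask, the natural metric when the reference is an
#' extended membrane shell and localization is a membrane-proximity
#' statement. Ties are broken towards the smallest collagen identifier.
#'
#' @param receptors a `spot_set` of receptor spots.
#' @param collagen a `spot_set` (centroid mode) or logical mask array
#'   (surface mode).
#' @param exp an [expansion_model()] (or a single numeric expansion factor).
#' @param mode metric mode; defaults to surface if `collagen` is a mask.
#' @return a `distance_table`: one row per receptor spot with
#'   `receptor_spot_id, collagen_ref, distance_gel_nm, distance_bio_nm`.
#'   Empty receptor sets yield an empty table; an empty collagen reference
#'   is an error.
#' @export
nearest_distances <- function(receptors, collagen,
                              exp = expansion_model(),
                              mode = c("centroid_to_surface",
                                       "centroid_to_centroid")) {
  if (is.numeric(exp) && length(exp) == 1) exp <- expansion_model(exp)
  E <- exp$linear_factor
  is_mask <- is.array(collagen) || is.logical(collagen)
  mode <- if (missing(mode))
    (if (is_mask) "centroid_to_surface" else "centroid_to_centroid")
  else match.arg(mode)
  q <- spot_coords(receptors)
  if (mode == "centroid_to_centroid") {
    if (is_mask)
      stop_exm("centroid_to_centroid mode needs a collagen spot_set",
               "exmloc_config")
    if (nrow(collagen) == 0)
      stop_exm("collagen reference set is empty", "exmloc_no_reference")
    if (nrow(q) == 0)
      return(make_distance_table(integer(0), integer(0), numeric(0), E, mode))
    ord <- order(collagen$spot_id)
    ref <- spot_coords(collagen)[ord, , drop = FALSE]
    nn <- .nn_points(q, ref)
    make_distance_table(receptors$spot_id, collagen$spot_id[ord][nn$index],
                        nn$distance, E, mode)
  } else {
    if (!is_mask)
      stop_exm("centroid_to_surface mode needs a collagen mask array",
               "exmloc_config")
    if (!any(collagen))
      stop_exm("collagen mask is empty", "exmloc_no_reference")
    if (nrow(q) == 0)
      return(make_distance_table(integer(0), integer(0), numeric(0), E, mode))
    vs <- attr(receptors, "voxel_size_gel")
    nn <- .nn_points_to_mask(q, as.logical(collagen),
                             as.integer(dim(collagen)), as.numeric(vs))
    make_distance_table(receptors$spot_id, as.integer(nn$index),
                        nn$distance, E, mode)
  }
}

#' Exhaustive nearest-distance oracle
#'
#' Brute-force all-pairs minimum with the same row schema and tie rule
#' (smallest collagen identifier) as [nearest_distances()]; serves as the
#' independent reference implementation.
#'
#' @inheritParams nearest_distances
#' @return a `distance_table`.
#' @export
brute_force_nearest <- function(receptors, collagen,
                                exp = expansion_model(),
                                mode = c("centroid_to_surface",
                                         "centroid_to_centroid")) {
  if (is.numeric(exp) && length(exp) == 1) exp <- expansion_model(exp)
  E <- exp$linear_factor
  is_mask <- is.array(collagen) || is.logical(collagen)
  mode <- if (missing(mode))
    (if (is_mask) "centroid_to_surface" else "centroid_to_centroid")
  else match.arg(mode)
  q <- spot_coords(receptors)
  if (mode == "centroid_to_centroid") {
    if (nrow(collagen) == 0)
      stop_exm("collagen reference set is empty", "exmloc_no_reference")
    ord <- order(collagen$spot_id)
    ref <- spot_coords(collagen)[ord, , drop = FALSE]
    ids <- collagen$spot_id[ord]
  } else {
    if (!any(collagen))
      stop_exm("collagen mask is empty", "exmloc_no_reference")
    d <- dim(collagen)
    vs <- attr(receptors, "voxel_size_gel")
    fg <- which(as.logical(collagen))
    ix <- (fg - 1L) %% d[1]
    iy <- ((fg - 1L) %/% d[1]) %% d[2]
    iz <- (fg - 1L) %/% (d[1] * d[2])
    ref <- cbind((ix + 0.5) * vs[1], (iy + 0.5) * vs[2], (iz + 0.5) * vs[3])
    ids <- fg
  }
  if (nrow(q) == 0)
    return(make_distance_table(integer(0), integer(0), numeric(0), E, mode))
  n <- nrow(q)
  best_ref <- integer(n)
  best_d <- numeric(n)
  for (i in seq_len(n)) {
    dx <- q[i, 1] - ref[, 1]
    dy <- q[i, 2] - ref[, 2]
    dz <- q[i, 3] - ref[, 3]
    d2 <- dx * dx + dy * dy + dz * dz
    j <- which.min(d2)  # first minimum = smallest identifier (ids sorted)
    best_ref[i] <- ids[j]
    best_d[i] <- sqrt(d2[j])
  }
  make_distance_table(receptors$spot_id, best_ref, best_d, E, mode)
}
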