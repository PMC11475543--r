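#' Distance bin specification for receptor localization classes
#'
#' Receptor-to-collagen-IV distances on the biological scale are classified
#' into localization bins: 0-100 nm is considered abluminal (at the abluminal
#' membrane marked by collagen IV), 100-200 nm and 200-1000 nm intracellular,
#' and 1000-3000 nm residual. Intervals are half-open `[a, b)` except the last
#' which is closed; a distance of exactly 100 nm is therefore intracellular.
#'
#' @param edges_bio_nm strictly increasing numeric vector of bin edges in
#'   biological nm.
#' @param labels character labels, one per interval.
#' @return object of class `bin_spec`.
#' @export
bin_spec <- function(edges_bio_nm = c(0, 100, 200, 1000, 3000),
                     labels = c("abluminal", "intracellular_proximal",
                                "intracellular_distal", "residual")) {
  if (any(diff(edges_bio_nm) <= 0))
    stop_exm("bin edges must be strictly increasing", "exmloc_config")
  if (length(labels) != length(edges_bio_nm) - 1)
    stop_exm("need exactly one label per interval", "exmloc_config")
  structure(list(edges_bio_nm = as.numeric(edges_bio_nm),
                 labels = as.character(labels)),
            class = "bin_spec")
}

#' @export
print.bin_spec <- function(x, ...) {
  n <- length(x$labels)
  brack <- c(rep(")", n - 1), "]")
  cat("Distance bins (biological nm):\n")
  for (i in seq_len(n))
    cat(sprintf("  [%g, %g%s  %s\n", x$edges_bio_nm[i], x$edges_bio_nm[i + 1],
                brack[i], x$labels[i]))
  invisible(x)
}

# assign distances to bin labels; NA for distances beyond the last edge
assign_bins <- function(d, bins) {
  if (any(d < 0)) stop_exm("negative distances", "exmloc_data_integrity")
  idx <- findInterval(d, bins$edges_bio_nm, rightmost.closed = TRUE)
  idx[idx > length(bins$labels)] <- NA_integer_  # beyond last edge: overflow
  idx[idx == 0 & d < bins$edges_bio_nm[1]] <- NA_integer_
  factor(bins$labels[idx], levels = bins$labels)
}

#' Bin receptor distances into localization classes
#'
#' @param distances a `distance_table` from [nearest_distances()], or a
#'   numeric vector of biological-nm distances.
#' @param bins a [bin_spec()].
#' @return named integer vector of counts per bin label, with attribute
#'   `overflow` counting distances beyond the last edge (reported, never
#'   silently dropped) and attribute `n` for the total number of rows.
#' @export
bin_distances <- function(distances, bins = bin_spec()) {
  d <- if (is.data.frame(distances)) distances$distance_bio_nm else distances
  if (length(d) == 0) {
    out <- stats::setNames(integer(length(bins$labels)), bins$labels)
    attr(out, "overflow") <- 0L
    attr(out, "n") <- 0L
    return(out)
  }
  f <- assign_bins(d, bins)
  out <- stats::setNames(as.integer(table(f)), bins$labels)
  attr(out, "overflow") <- sum(is.na(f))
  attr(out, "n") <- length(d)
  if (attr(out, "overflow") > 0)
    message(sprintf("bin_distances: %d distance(s) beyond the last bin edge counted as overflow",
                    attr(out, "overflow")))
  out
}
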