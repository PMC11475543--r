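#' Per-capillary bin counts and fractions
#'
#' Tabulates binned receptor-to-collagen distances per capillary. The
#' capillary, not the spot, is the replication unit for all downstream
#' statistics. Capillaries with no distance rows are excluded with a warning.
#'
#' @param distances data.frame with columns `capillary_id`, `receptor` and
#'   `distance_bio_nm` (one row per receptor spot), plus optional
#'   `capillary_type` and `qc_pass` columns carried through.
#' @param bins a [bin_spec()].
#' @return a `capillary_profiles` data.frame: one row per capillary with
#'   `capillary_id, receptor, capillary_type, qc_pass, n_total, n_overflow`,
#'   one count column per bin label and one `frac_<label>` column per bin
#'   label (fractions of binned spots; they sum to 1).
#' @export
capillary_fractions <- function(distances, bins = bin_spec()) {
  stopifnot(all(c("capillary_id", "receptor", "distance_bio_nm") %in%
                  names(distances)))
  ids <- unique(distances$capillary_id)
  rows <- lapply(ids, function(id) {
    sub <- distances[distances$capillary_id == id, , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    cnt <- suppressMessages(bin_distances(sub$distance_bio_nm, bins))
    n_binned <- sum(cnt)
    fr <- if (n_binned > 0) cnt / n_binned else cnt * NA_real_
    out <- data.frame(capillary_id = id,
                      receptor = sub$receptor[1],
                      capillary_type = if ("capillary_type" %in% names(sub))
                        sub$capillary_type[1] else NA_integer_,
                      qc_pass = if ("qc_pass" %in% names(sub))
                        sub$qc_pass[1] else NA,
                      n_total = attr(cnt, "n"),
                      n_overflow = attr(cnt, "overflow"))
    for (lb in bins$labels) out[[lb]] <- cnt[[lb]]
    for (lb in bins$labels) out[[paste0("frac_", lb)]] <- unname(fr[lb])
    out
  })
  empty_ids <- ids[vapply(rows, is.null, TRUE)]
  if (length(empty_ids))
    warning(sprintf("excluded %d capillary(ies) with zero spots: %s",
                    length(empty_ids), paste(empty_ids, collapse = ", ")))
  out <- do.call(rbind, rows)
  structure(out, class = c("capillary_profiles", "data.frame"), bins = bins)
}

significance_stars <- function(p) {
  ifelse(is.na(p), "ns",
  ifelse(p < 1e-4, "****",
  ifelse(p < 1e-3, "***",
  ifelse(p < 1e-2, "**",
  ifelse(p < 0.05, "*", "ns")))))
}

profiles_long <- function(profiles, response = c("count", "fraction")) {
  response <- match.arg(response)
  bins <- attr(profiles, "bins") %||% bin_spec()
  cols <- if (response == "count") bins$labels else
    paste0("frac_", bins$labels)
  long <- do.call(rbind, lapply(seq_along(bins$labels), function(i)
    data.frame(capillary_id = profiles$capillary_id,
               receptor = profiles$receptor,
               bin = bins$labels[i],
               value = profiles[[cols[i]]])))
  long$receptor <- factor(long$receptor)
  long$bin <- factor(long$bin, levels = bins$labels)
  long
}

#' Two-way ANOVA with Tukey multiple comparisons on capillary profiles
#'
#' Fixed-effects two-way ANOVA of the per-capillary binned distances with
#' factors receptor and distance bin (type-II sums of squares, appropriate
#' for the unbalanced per-receptor capillary counts), followed by
#' Tukey-adjusted pairwise receptor comparisons within each bin. Stars follow
#' the convention *p<0.05, **p<0.01, ***p<0.001, ****p<0.0001, ns otherwise.
#'
#' @param profiles a `capillary_profiles` data.frame ([capillary_fractions()]).
#' @param response `"count"` (default; per-capillary spot counts per bin) or
#'   `"fraction"`.
#' @param alpha significance level used by `print`.
#' @param tukey compute the Tukey-adjusted pairwise comparisons (default
#'   `TRUE`; disable for speed in large simulation studies that only need
#'   the ANOVA table).
#' @return an `exm_anova` object: `anova_table` (term, F, p, stars),
#'   `tukey` (bin, contrast, estimate, SE, adjusted p, stars), the fitted
#'   `lm`, and the response used.
#' @export
two_way_anova_tukey <- function(profiles, response = c("count", "fraction"),
                                alpha = 0.05, tukey = TRUE) {
  response <- match.arg(response)
  long <- profiles_long(profiles, response)
  if (nlevels(long$receptor) < 2 || nlevels(long$bin) < 2)
    stop_exm("need at least 2 receptor groups and 2 bins",
             "exmloc_degenerate_design")
  cell_n <- table(long$receptor, long$bin)
  if (any(cell_n < 2)) {
    bad <- which(cell_n < 2, arr.ind = TRUE)
    stop_exm(sprintf("design cell(s) with fewer than 2 capillaries: %s",
                     paste(sprintf("%s x %s", rownames(cell_n)[bad[, 1]],
                                   colnames(cell_n)[bad[, 2]]),
                           collapse = ", ")),
             "exmloc_degenerate_design")
  }
  fit <- stats::lm(value ~ receptor * bin, data = long)
  degenerate <- stats::sd(long$value) == 0
  if (degenerate) {
    terms <- c("receptor", "bin", "receptor:bin")
    atab <- data.frame(term = terms, F = 0, p = NA_real_,
                       stars = "ns", stringsAsFactors = FALSE)
  } else {
    a2 <- car::Anova(fit, type = 2)
    keep <- rownames(a2) != "Residuals"
    atab <- data.frame(term = rownames(a2)[keep],
                       F = a2$`F value`[keep],
                       p = a2$`Pr(>F)`[keep], stringsAsFactors = FALSE)
    atab$stars <- significance_stars(atab$p)
  }
  tukey_tab <- NULL
  if (tukey) {
    em_call <- function() {
      em <- emmeans::emmeans(fit, ~ receptor | bin)
      summary(emmeans::contrast(em, method = "pairwise", adjust = "tukey"))
    }
    # a zero-residual fit triggers spurious precision warnings downstream
    pr <- if (degenerate) suppressWarnings(em_call()) else em_call()
    tukey_tab <- data.frame(bin = pr$bin, contrast = as.character(pr$contrast),
                            estimate = pr$estimate, SE = pr$SE,
                            p_adj = if (degenerate) NA_real_ else pr$p.value,
                            stringsAsFactors = FALSE)
    tukey_tab$stars <- significance_stars(tukey_tab$p_adj)
  }
  structure(list(anova_table = atab, tukey = tukey_tab, fit = fit,
                 response = response, alpha = alpha),
            class = "exm_anova")
}

#' @export
print.exm_anova <- function(x, ...) {
  cat(sprintf("Two-way ANOVA (type II) on per-capillary %ss\n", x$response))
  print(x$anova_table, row.names = FALSE, digits = 4)
  if (!is.null(x$tukey)) {
    cat("\nTukey-adjusted receptor comparisons within bins:\n")
    print(x$tukey, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Simulate per-capillary bin-count tables directly
#'
#' Statistics-only generator (no imaging): per capillary, a Poisson total
#' spot count split multinomially over the distance bins by its group's
#' mixture. Used for null calibration of the ANOVA stage and residual-bin
#' properties on pre-tabulated counts.
#'
#' @param n_capillaries named integer vector, capillaries per receptor group.
#' @param mixtures named list (one per group) of probability vectors over the
#'   bin labels; a single vector is recycled to all groups.
#' @param mean_spots Poisson mean of the per-capillary spot total.
#' @param bins a [bin_spec()].
#' @param seed integer seed.
#' @return a `capillary_profiles` data.frame.
#' @export
simulate_capillary_counts <- function(n_capillaries = c(basigin = 10,
                                                        TfR = 14,
                                                        sortilin = 14),
                                      mixtures,
                                      mean_spots = 150,
                                      bins = bin_spec(),
                                      seed = 1L) {
  groups <- names(n_capillaries)
  if (!is.list(mixtures)) mixtures <- stats::setNames(
    rep(list(mixtures), length(groups)), groups)
  rows <- list()
  with_seed(seed_stream(seed, "counts"), {
    cid <- 0L
    for (g in groups) {
      mix <- stats::setNames(numeric(length(bins$labels)), bins$labels)
      mix[names(mixtures[[g]])] <- mixtures[[g]]
      if (abs(sum(mix) - 1) > 1e-8)
        stop_exm("mixtures must sum to 1", "exmloc_config")
      for (i in seq_len(n_capillaries[[g]])) {
        cid <- cid + 1L
        n <- stats::rpois(1, mean_spots)
        cnt <- if (n > 0) stats::rmultinom(1, n, mix)[, 1] else
          stats::setNames(integer(length(mix)), names(mix))
        row <- data.frame(capillary_id = sprintf("cap%03d", cid),
                          receptor = g, capillary_type = 1L, qc_pass = TRUE,
                          n_total = n, n_overflow = 0L)
        for (lb in bins$labels) row[[lb]] <- cnt[[lb]]
        for (lb in bins$labels)
          row[[paste0("frac_", lb)]] <- if (n > 0) cnt[[lb]] / n else NA_real_
        rows[[length(rows) + 1]] <- row
      }
    }
  })
  structure(do.call(rbind, rows),
            class = c("capillary_profiles", "data.frame"), bins = bins)
}

#' Bar plot of bin fractions or counts per receptor (mean with SD bars)
#'
#' @param profiles a `capillary_profiles` data.frame.
#' @param response `"fraction"` or `"count"`.
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the matrix of group means.
#' @export
plot_bin_profiles <- function(profiles, response = c("fraction", "count"),
                              ...) {
  response <- match.arg(response)
  long <- profiles_long(profiles,
                        if (response == "fraction") "fraction" else "count")
  means <- tapply(long$value, list(long$receptor, long$bin), mean)
  sds <- tapply(long$value, list(long$receptor, long$bin), stats::sd)
  bp <- graphics::barplot(means, beside = TRUE, legend.text = rownames(means),
                          ylab = paste0("mean ", response, " per capillary"),
                          xlab = "distance bin (biological nm)",
                          ylim = c(0, max(means + sds, na.rm = TRUE) * 1.15),
                          ...)
  ok <- is.finite(sds) & sds > 0
  if (any(ok))
    graphics::arrows(bp[ok], means[ok], bp[ok], means[ok] + sds[ok],
                     angle = 90, length = 0.03)
  invisible(means)
}
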