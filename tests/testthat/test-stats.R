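test_that("distance binning follows the half-open convention", {
  bn <- bin_distances(c(50, 150, 500, 2000))
  expect_equal(unname(bn[c("abluminal", "intracellular_proximal",
                           "intracellular_distal", "residual")]),
               c(1L, 1L, 1L, 1L))
  # boundary: exactly 100 nm is intracellular, exactly 3000 nm still residual
  b2 <- bin_distances(c(100, 3000))
  expect_equal(unname(b2["intracellular_proximal"]), 1L)
  expect_equal(unname(b2["residual"]), 1L)

  empty <- bin_distances(numeric(0))
  expect_true(all(empty == 0L))
  expect_error(bin_distances(c(-5, 10)), class = "exmloc_data_integrity")

  expect_message(over <- bin_distances(c(50, 3500)), "overflow")
  expect_identical(attr(over, "overflow"), 1L)
  expect_identical(sum(over) + attr(over, "overflow"), 2L)
})

test_that("per-capillary fractions are simple arithmetic on bin counts", {
  d <- data.frame(
    capillary_id = rep(c("a", "b", "c"), c(100, 100, 1)),
    receptor = "TfR",
    distance_bio_nm = c(c(rep(50, 8), rep(500, 92)),
                        c(rep(50, 32), rep(500, 68)),
                        20))
  prof <- capillary_fractions(d)
  expect_equal(prof$frac_abluminal, c(0.08, 0.32, 1.0))
  expect_equal(prof$n_total, c(100L, 100L, 1L))
  frac_cols <- paste0("frac_", bin_spec()$labels)
  expect_true(all(abs(rowSums(prof[, frac_cols]) - 1) < 1e-9))
  expect_true(all(rowSums(prof[, bin_spec()$labels]) == prof$n_total))
})

test_that("nuclei size CV matches the hand formula and gates QC", {
  vs <- c(108, 108, 310)
  mk <- function(voxels) {
    df <- data.frame(spot_id = seq_along(voxels), cx_nm = 0, cy_nm = 0,
                     cz_nm = 0, voxels = voxels)
    structure(df, class = c("spot_set", "data.frame"), voxel_size_gel = vs)
  }
  same <- nuclei_uniformity_qc(mk(c(4000, 4000, 4000)))
  expect_equal(same$cv, 0)
  expect_true(same$qc_pass)

  mixed <- nuclei_uniformity_qc(mk(c(1000, 8000, 4000)))
  diam <- (6 * c(1000, 8000, 4000) * prod(vs) / pi)^(1 / 3)
  expect_equal(mixed$cv, sd(diam) / mean(diam))

  expect_error(nuclei_uniformity_qc(mk(c(100, 100))),
               class = "exmloc_insufficient_nuclei")
})

test_that("two-way ANOVA F statistics match textbook sums of squares", {
  vals <- list(r1b1 = c(10, 12, 14), r1b2 = c(20, 22, 24),
               r2b1 = c(11, 13, 15), r2b2 = c(30, 32, 34))
  bins2 <- bin_spec(c(0, 100, 200), c("abluminal", "intracellular_proximal"))
  prof <- data.frame(
    capillary_id = sprintf("c%d", 1:6),
    receptor = rep(c("r1", "r2"), each = 3),
    abluminal = c(vals$r1b1, vals$r2b1),
    intracellular_proximal = c(vals$r1b2, vals$r2b2))
  prof <- structure(prof, class = c("capillary_profiles", "data.frame"),
                    bins = bins2)
  res <- two_way_anova_tukey(prof, response = "count")

  # hand-computed balanced two-way ANOVA with interaction
  y <- unlist(vals)
  n <- 3; a <- 2; b <- 2
  gm <- mean(y)
  m_r <- c(mean(c(vals$r1b1, vals$r1b2)), mean(c(vals$r2b1, vals$r2b2)))
  m_b <- c(mean(c(vals$r1b1, vals$r2b1)), mean(c(vals$r1b2, vals$r2b2)))
  m_cell <- sapply(vals, mean)
  ss_r <- n * b * sum((m_r - gm)^2)
  ss_b <- n * a * sum((m_b - gm)^2)
  ss_cell <- n * sum((m_cell - gm)^2)
  ss_int <- ss_cell - ss_r - ss_b
  ss_e <- sum((y - rep(m_cell, each = n))^2)
  df_e <- a * b * (n - 1)
  f_expect <- c(receptor = (ss_r / 1) / (ss_e / df_e),
                bin = (ss_b / 1) / (ss_e / df_e),
                `receptor:bin` = (ss_int / 1) / (ss_e / df_e))
  got <- setNames(res$anova_table$F, res$anova_table$term)
  expect_equal(got[names(f_expect)], f_expect, tolerance = 1e-10)
  expect_true(all(res$tukey$p_adj >= 0 & res$tukey$p_adj <= 1))
})

test_that("zero between-group variance reports ns, empty cells error", {
  bins2 <- bin_spec(c(0, 100, 200), c("abluminal", "intracellular_proximal"))
  prof <- structure(data.frame(
    capillary_id = sprintf("c%d", 1:6),
    receptor = rep(c("r1", "r2"), each = 3),
    abluminal = 5, intracellular_proximal = 5),
    class = c("capillary_profiles", "data.frame"), bins = bins2)
  res <- two_way_anova_tukey(prof, response = "count")
  expect_true(all(res$anova_table$stars == "ns"))
  expect_true(all(res$tukey$stars == "ns"))

  bad <- prof[-(4:6), ]
  expect_error(two_way_anova_tukey(bad, response = "count"),
               class = "exmloc_degenerate_design")
})

test_that("significance stars follow the published convention", {
  expect_identical(exmloc:::significance_stars(
    c(0.2, 0.04, 0.004, 4e-4, 4e-5, NA)),
    c("ns", "*", "**", "***", "****", "ns"))
})

test_that("rule-based typing matches constructed nuclei configurations", {
  vs <- c(108, 108, 310)
  axis <- list(direction = c(1, 0, 0), center = c(0, 0, 0),
               radial_median = 5000)
  mk <- function(centers, moms) {
    df <- data.frame(spot_id = seq_len(nrow(centers)),
                     cx_nm = centers[, 1], cy_nm = centers[, 2],
                     cz_nm = centers[, 3], voxels = rep(500L, nrow(centers)))
    structure(df, class = c("spot_set", "data.frame"), voxel_size_gel = vs,
              moments = moms)
  }
  along_x <- diag(c(16e6, 1e6, 1e6))
  along_y <- diag(c(1e6, 16e6, 1e6))
  round_m <- diag(c(2e6, 2e6, 2e6))

  # one elongated nucleus perpendicular to the axis -> type 3
  t3 <- classify_capillary_type(mk(rbind(c(0, 4000, 0)), list(along_y)), axis)
  expect_identical(t3$capillary_type, 3L)

  # axial line plus 5 peripheral nuclei -> type 2
  centers2 <- rbind(c(-5000, 0, 0), c(0, 0, 0), c(5000, 0, 0),
                    c(-4000, 4500, 0), c(-2000, -4500, 0), c(0, 4500, 0),
                    c(2000, -4500, 0), c(4000, 4500, 0))
  moms2 <- c(rep(list(along_x), 3), rep(list(round_m), 5))
  t2 <- classify_capillary_type(mk(centers2, moms2), axis)
  expect_identical(t2$capillary_type, 2L)
  expect_identical(unname(t2$counts["peripheral"]), 5L)

  # axial line with one peripheral nucleus -> type 1
  t1 <- classify_capillary_type(mk(centers2[1:4, ], moms2[1:4]), axis)
  expect_identical(t1$capillary_type, 1L)

  expect_error(classify_capillary_type(
    mk(matrix(numeric(0), ncol = 3), list()), axis),
    class = "exmloc_untypeable")
})

test_that("simulated rendered capillaries close the typing loop", {
  acq <- acquisition_model()
  for (ty in c(1L, 3L)) {
    sim <- simulate_capillary(ty, 15, c(abluminal = 1), c(256, 256, 48),
                              acq, typing_gp(), seed = 300 + ty)
    nuc <- detect_nuclei(sim$stack)
    ax <- estimate_capillary_axis(sim$truth$collagen_shell_mask,
                                  acq$voxel_size_gel)
    expect_identical(classify_capillary_type(nuc, ax)$capillary_type, ty)
  }
})

test_that("the simulator's non-uniform nuclei mode fails QC", {
  acq <- acquisition_model()
  sim <- simulate_capillary(2, 15, c(abluminal = 1), c(256, 256, 48), acq,
                            typing_gp(nuclei_uniform = FALSE), seed = 55)
  nuc <- detect_nuclei(sim$stack)
  qc <- nuclei_uniformity_qc(nuc)
  expect_false(qc$qc_pass)

  sim_u <- simulate_capillary(2, 15, c(abluminal = 1), c(256, 256, 48), acq,
                              typing_gp(), seed = 55)
  qc_u <- nuclei_uniformity_qc(detect_nuclei(sim_u$stack))
  expect_true(qc_u$qc_pass)
})

test_that("tabulated count simulation respects totals and mixtures", {
  mix <- c(abluminal = 0.1, intracellular_proximal = 0.2,
           intracellular_distal = 0.6, residual = 0.1)
  prof <- simulate_capillary_counts(c(A = 30, B = 30), mix, 200, seed = 3)
  expect_identical(nrow(prof), 60L)
  expect_true(all(rowSums(prof[, bin_spec()$labels]) == prof$n_total))
  expect_equal(mean(prof$frac_abluminal), 0.1, tolerance = 0.02)
})
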