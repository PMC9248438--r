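make_labels <- function(arr, voxel = c(0.5, 0.5, 1)) {
  structure(list(labels = arr, voxel_mm = voxel, codes = tissue_codes(),
                 tumor_center_mm = dim(arr) * voxel / 2,
                 tumor_radius_mm = 1,
                 meta = list(seed = 1, achieved_volume_mm3 = 0)),
            class = "tissue_labels")
}

test_that("the largest tumor slice is found (with a brute-force oracle)", {
  a <- array(1L, c(8, 8, 5))
  a[3:5, 3:5, 4] <- 2L
  expect_equal(select_largest_tumor_slice(make_labels(a)), 4)
  # spherical tumor: equatorial slice
  lab <- generate_label_volume(small_config(seed = 2))
  counts <- apply(lab$labels, 3, function(s) sum(s %in% 2:5))
  expect_equal(select_largest_tumor_slice(lab), which.max(counts))
  # random blobs against the per-slice count scan
  set.seed(8)
  b <- array(1L, c(10, 10, 6))
  b[sample(600, 60)] <- 2L
  oracle <- which.max(apply(b, 3, function(s) sum(s == 2L)))
  expect_equal(select_largest_tumor_slice(make_labels(b)), oracle)
  expect_error(select_largest_tumor_slice(make_labels(array(1L, c(4, 4, 2)))),
               "no tumor")
})

test_that("tessellation drops incomplete cells and partitions voxel centers", {
  g <- tessellate(c(96L, 96L), c(25.6 / 96, 25.6 / 96), 1)
  expect_equal(g$nx * g$ny, 625)
  # every voxel center is assigned to exactly one (possibly dropped) cell
  expect_true(all(is.na(g$vx_cell) | (g$vx_cell >= 0 & g$vx_cell < g$nx)))
  expect_equal(sum(is.na(g$vx_cell)), sum((seq_len(96) - 0.5) * 25.6 / 96 >= 25))
  # ROI side equal to the FOV gives a single cell
  g1 <- tessellate(c(10L, 10L), c(1, 1), 10)
  expect_equal(nrow(g1$cells), 1)
  expect_error(tessellate(c(10L, 10L), c(1, 1), 0.5), "voxel")
})

test_that("composition fractions match an independent tally and sum to one", {
  lab2 <- matrix(2L, 12, 12)
  lab2[1:2, 1:2] <- 4L  # 4 necrosis voxels in a 2x2-voxel corner
  g <- tessellate(c(12L, 12L), c(0.5, 0.5), 1)
  comp <- compute_composition(lab2, g)
  expect_true(all(abs(rowSums(as.matrix(
    comp[, paste0("frac_", names(tissue_codes()))])) - 1) < 1e-12))
  first <- comp[comp$ix == 0 & comp$iy == 0, ]
  expect_equal(first$frac_necrosis, 1)  # cell (0,0) is the 2x2 necrosis patch
  # hand case: 3 of 12 voxels necrosis -> 0.25 (1 mm cell of 3x4 voxels)
  lab3 <- matrix(2L, 6, 8)
  lab3[1:3, 1] <- 4L
  g3 <- tessellate(c(6L, 8L), c(1 / 3, 1 / 4), 1)
  comp3 <- compute_composition(lab3, g3)
  expect_equal(comp3$frac_necrosis[comp3$ix == 0 & comp3$iy == 0], 0.25)
  # brute-force per-voxel tally on a random slice
  set.seed(3)
  lab4 <- matrix(sample(0:5, 144, replace = TRUE), 12, 12)
  comp4 <- compute_composition(lab4, tessellate(c(12L, 12L), c(0.5, 0.5), 1))
  for (r in sample(nrow(comp4), 5)) {
    i <- which(floor(((seq_len(12) - 0.5) * 0.5) / 1) == comp4$ix[r])
    j <- which(floor(((seq_len(12) - 0.5) * 0.5) / 1) == comp4$iy[r])
    tab <- table(factor(lab4[i, j], levels = 0:5)) / (length(i) * length(j))
    expect_equal(unname(comp4$frac_tumor[r]), unname(tab["2"]))
    expect_equal(unname(comp4$frac_vessel[r]), unname(tab["3"]))
  }
})

test_that("inclusion filters apply the air, purity and composition rules", {
  base <- data.frame(frac_background = 0, frac_normal = 0, frac_tumor = 1,
                     frac_vessel = 0, frac_necrosis = 0,
                     frac_calcification = 0)
  pure_tumor <- base
  nec30 <- base; nec30$frac_tumor <- 0.7; nec30$frac_necrosis <- 0.3
  nec25 <- base; nec25$frac_tumor <- 0.75; nec25$frac_necrosis <- 0.25
  mixed <- base; mixed$frac_tumor <- 0.5; mixed$frac_normal <- 0.5
  airy <- mixed; airy$frac_background <- 0.1; airy$frac_tumor <- 0.4
  pure_normal <- base; pure_normal$frac_tumor <- 0; pure_normal$frac_normal <- 1
  comp <- rbind(pure_tumor, nec30, nec25, mixed, airy, pure_normal)
  out <- apply_inclusion_filters(comp)
  expect_equal(out$included, c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))
  # air takes precedence over mixed; the 25% rule is exclusive
  expect_equal(out$reason, c(NA, "composition", "composition", "mixed",
                             "air", NA))
  expect_equal(out$tissue, c("tumor", NA, NA, NA, NA, "normal"))
})

test_that("region classification uses a strict 1 mm boundary distance", {
  mask <- matrix(FALSE, 10, 10)
  mask[2, 2] <- TRUE  # single tumor pixel centered at (0.75, 0.75) mm
  centers <- rbind(c(1.75, 0.75),   # exactly 1.0 mm -> central
                   c(1.15, 0.75),   # 0.4 mm -> peripheral
                   c(4.75, 4.75))   # far -> central
  cls <- classify_region(centers, mask, c(0.5, 0.5))
  expect_equal(cls, c("central", "peripheral", "central"))
  expect_error(classify_region(centers, mask & FALSE, c(0.5, 0.5)), "empty")
})

test_that("aggregation reproduces constant maps and partitions the grid", {
  lab2 <- matrix(1L, 12, 12)
  lab2[4:9, 4:9] <- 2L
  maps <- list(D = matrix(4e-4, 12, 12), Dstar = matrix(3e-3, 12, 12),
               f = matrix(0.5, 12, 12), perfusion = matrix(1.5e-3, 12, 12),
               R2star = matrix(38, 12, 12),
               conv_ivim = matrix(TRUE, 12, 12),
               conv_r2star = matrix(TRUE, 12, 12))
  rec <- aggregate_roi(lab2, c(0.5, 0.5), maps)
  expect_equal(nrow(rec), 36)  # 6 mm FOV -> 6x6 complete cells, all listed
  expect_equal(sum(rec$included) + sum(!rec$included), 36)
  an <- rec[rec$analyzed, ]
  expect_true(all(abs(an$D - 4e-4) < 1e-15))
  expect_true(all(abs(an$R2star - 38) < 1e-12))
})

test_that("raising the composition threshold never shrinks the included set", {
  cfg <- small_config(seed = 14)
  lab <- generate_label_volume(cfg)
  sl <- select_largest_tumor_slice(lab)
  lab2 <- lab$labels[, , sl]
  g <- tessellate(dim(lab2), cfg$voxel_mm[1:2], 1)
  comp <- compute_composition(lab2, g)
  n_inc <- sapply(c(0.15, 0.25, 0.5, 1),
                  function(th) sum(apply_inclusion_filters(
                    comp, analysis_config(composition_threshold = th))$included))
  expect_true(all(diff(n_inc) >= 0))
})
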