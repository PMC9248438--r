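test_that("label volume is deterministic and respects degenerate fractions", {
  cfg <- small_config(seed = 3, fractions = c(vessel = 0, necrosis = 0,
                                              calcification = 0))
  lab1 <- generate_label_volume(cfg)
  lab2 <- generate_label_volume(cfg)
  expect_identical(lab1$labels, lab2$labels)
  expect_true(all(lab1$labels %in% c(0L, 1L, 2L)))
  expect_gt(sum(lab1$labels == 2L), 0)
})

test_that("tumor voxel volume matches the configured volume", {
  lab <- generate_label_volume(phantom_config(seed = 5))
  # independent oracle: count tumor-extent voxels and multiply by voxel vol
  v <- sum(lab$labels %in% 2:5) * prod(lab$voxel_mm)
  expect_lt(abs(v - 458) / 458, 0.02)
  expect_equal(tumor_volume(lab), v)
})

test_that("intratumoral component fractions land within one percentage point", {
  cfg <- small_config(seed = 9, fractions = c(vessel = 0.06, necrosis = 0.10,
                                              calcification = 0.02))
  lab <- generate_label_volume(cfg)
  n_t <- sum(lab$labels %in% 2:5)
  for (target in list(c(3L, 0.06), c(4L, 0.10), c(5L, 0.02))) {
    frac <- sum(lab$labels == target[1]) / n_t
    expect_lt(abs(frac - target[2]), 0.01)
  }
})

test_that("a tumor crossing the brain boundary rejects the configuration", {
  cfg <- small_config(seed = 1)
  cfg$tumor_center_mm <- cfg$brain_center_mm + c(-9, 0, 0)
  expect_error(generate_label_volume(cfg), "inside the brain")
})

test_that("truth maps respect parameter invariants and recover tissue moments", {
  cfg <- small_config(seed = 21, tumor_volume_mm3 = 200)
  lab <- generate_label_volume(cfg)
  tr <- generate_truth_maps(lab, cfg)
  expect_true(all(tr$Dstar >= tr$D))
  expect_true(all(tr$f >= 0 & tr$f <= 1))
  expect_true(all(tr$R2star > 0))
  expect_true(all(tr$HIF >= 0 & tr$HIF <= 300))
  tum <- lab$labels == 2L; nor <- lab$labels == 1L
  # HIF means: configured 123.73 (tumor) / 21.13 (normal), within 5%
  expect_lt(abs(mean(tr$HIF[lab$labels %in% 2:5]) - 123.73) / 123.73, 0.05)
  expect_lt(abs(mean(tr$HIF[nor]) - 21.13) / 21.13, 0.05)
  # imaging parameter moments (Monte-Carlo tolerances)
  expect_lt(abs(mean(tr$R2star[tum]) - 38.24) / 38.24, 0.05)
  expect_lt(abs(stats::sd(tr$Dstar[nor]) - 441.42e-6) / 441.42e-6, 0.2)
  expect_lt(abs(mean(tr$D[nor]) - 414.21e-6) / 414.21e-6, 0.05)
})

test_that("zero coupling leaves HIF uncorrelated with the imaging fields", {
  cfg <- phantom_config(seed = 31, tumor_volume_mm3 = 800,
                        coupling = c(r2star = 0, dstar = 0),
                        hif_radial_gradient = 0)
  lab <- generate_label_volume(cfg)
  tr <- generate_truth_maps(lab, cfg)
  tum <- lab$labels %in% 2:5
  expect_gt(sum(tum), 1e4)
  expect_lt(abs(cor(tr$HIF[tum], tr$R2star[tum], method = "spearman")), 0.1)
  expect_lt(abs(cor(tr$HIF[tum], tr$Dstar[tum], method = "spearman")), 0.1)
})

test_that("configured couplings are reproduced in population rank correlations", {
  cfg <- phantom_config(seed = 33, tumor_volume_mm3 = 800,
                        coupling = c(r2star = 0.5, dstar = -0.3),
                        hif_radial_gradient = 0)
  lab <- generate_label_volume(cfg)
  tr <- generate_truth_maps(lab, cfg)
  tum <- lab$labels %in% 2:5
  # rank-correlation oracle: stats::cor on >= 1e4 tumor voxels
  rho_r2 <- cor(tr$HIF[tum], tr$R2star[tum], method = "spearman")
  rho_ds <- cor(tr$HIF[tum], tr$Dstar[tum], method = "spearman")
  expect_gt(rho_r2, 0.35); expect_lt(rho_r2, 0.65)
  expect_lt(rho_ds, -0.15); expect_gt(rho_ds, -0.45)
})

test_that("HIF density is higher in the tumor core than at the rim", {
  cfg <- small_config(seed = 41, tumor_volume_mm3 = 250)
  lab <- generate_label_volume(cfg)
  tr <- generate_truth_maps(lab, cfg)
  d <- dim(lab$labels)
  idx <- which(lab$labels %in% 2:5)
  pos <- arrayInd(idx, d)
  ctr <- lab$tumor_center_mm
  dist <- sqrt(((pos[, 1] - 0.5) * lab$voxel_mm[1] - ctr[1])^2 +
               ((pos[, 2] - 0.5) * lab$voxel_mm[2] - ctr[2])^2 +
               ((pos[, 3] - 0.5) * lab$voxel_mm[3] - ctr[3])^2)
  rn <- dist / (3 * tumor_volume(lab) / (4 * pi))^(1 / 3)
  expect_gt(mean(tr$HIF[idx][rn < 0.5]), mean(tr$HIF[idx][rn > 0.9]))
})

test_that("invalid couplings are rejected", {
  expect_error(phantom_config(coupling = c(r2star = 1.2, dstar = -0.3)),
               "coupling")
  expect_error(phantom_config(coupling = c(r2star = 0.9, dstar = -0.9)),
               "latent")
})

test_that("noiseless DWI synthesis matches the closed-form model exactly", {
  tr <- flat_truth()
  dwi <- synthesize_dwi(tr, protocol_b, sigma = 0)
  for (k in seq_along(protocol_b)) {
    expected <- 1000 * ivim_signal(protocol_b[k], tumor_pars$D,
                                   tumor_pars$Dstar, tumor_pars$f)
    expect_equal(unname(dwi$data[1, 1, 1, k]), expected, tolerance = 1e-12)
  }
  # b = 0 returns S0; the Table-scale value at b = 1000 is ~0.3511 * S0
  expect_equal(unname(dwi$data[2, 3, 1, 1]), 1000)
  expect_equal(unname(dwi$data[1, 1, 1, which(protocol_b == 1000)]) / 1000,
               0.3510682, tolerance = 1e-6)
})

test_that("f = 0 gives a mono-exponential diffusion decay", {
  tr <- flat_truth(f = 0)
  dwi <- synthesize_dwi(tr, protocol_b, sigma = 0)
  expect_equal(as.vector(dwi$data[1, 1, 1, ]),
               1000 * exp(-protocol_b * tumor_pars$D), tolerance = 1e-12)
})

test_that("noiseless multi-echo synthesis follows the mono-exponential decay", {
  tr <- flat_truth(R2star = 38.24)
  me <- synthesize_mege(tr, protocol_te, sigma = 0)
  expect_equal(as.vector(me$data[1, 1, 1, ]),
               1000 * exp(-protocol_te * 38.24), tolerance = 1e-12)
  # closed-form oracle at TE = 92.1 ms: exponent 38.24 * 0.0921 = 3.5219
  expect_equal(unname(me$data[1, 1, 1, 16]) / 1000, exp(-3.521904),
               tolerance = 1e-9)
  expect_error(synthesize_mege(tr, c(0.002, 0.001)), "increasing")
})

test_that("noisy synthesis is reproducible for a fixed seed", {
  tr <- flat_truth()
  a <- synthesize_dwi(tr, protocol_b, sigma = 0.02, seed = 7)
  b <- synthesize_dwi(tr, protocol_b, sigma = 0.02, seed = 7)
  expect_identical(a$data, b$data)
  c1 <- synthesize_dwi(tr, protocol_b, sigma = 0.02, seed = 8)
  expect_false(identical(a$data, c1$data))
  expect_error(synthesize_dwi(tr, protocol_b, sigma = -1), "sigma")
})

test_that("Rician noise matches its closed-form moments", {
  expect_identical(add_rician_noise(c(1, 2, 3), 0), c(1, 2, 3))
  # pure noise is Rayleigh: mean sigma * sqrt(pi / 2)
  z <- add_rician_noise(rep(0, 2e5), 1, seed = 1)
  expect_lt(abs(mean(z) - sqrt(pi / 2)) / sqrt(pi / 2), 0.01)
  # high SNR: mean ~ sqrt(s^2 + sigma^2)
  s <- 50
  z <- add_rician_noise(rep(s, 2e5), 1, seed = 2)
  expect_lt(abs(mean(z) - sqrt(s^2 + 1)) / s, 0.001)
})

test_that("cell categories saturate at the HIF density extremes", {
  cfg <- small_config(seed = 51)
  lab <- generate_label_volume(cfg)
  tr <- generate_truth_maps(lab, cfg)
  sl <- select_largest_tumor_slice(lab)
  tr0 <- tr; tr0$HIF[] <- 0
  cells0 <- synthesize_cell_table(tr0, lab, sl, cells_per_mm2 = 100, seed = 1)
  expect_true(all(cells0$intensity == 0L))
  tr3 <- tr; tr3$HIF[] <- 300
  cells3 <- synthesize_cell_table(tr3, lab, sl, cells_per_mm2 = 100, seed = 1)
  expect_true(all(cells3$intensity == 3L))
  expect_warning(synthesize_cell_table(tr, lab, sl, cells_per_mm2 = 10,
                                       seed = 1), "unstable")
})

test_that("ROI scores are unbiased for a uniform HIF density", {
  tr <- flat_truth(HIF = 150, dim = c(8L, 8L, 1L))
  lab <- structure(list(labels = array(1L, c(8L, 8L, 1L)),
                        voxel_mm = c(0.5, 0.5, 1), codes = tissue_codes(),
                        tumor_center_mm = c(2, 2, 0.5),
                        tumor_radius_mm = 1,
                        meta = list(seed = 1, achieved_volume_mm3 = 0)),
                   class = "tissue_labels")
  cells <- synthesize_cell_table(tr, lab, 1, cells_per_mm2 = 1e4, seed = 3)
  # 4x4 mm tissue area at 1e4 cells/mm^2; score each 1 mm^2 cell block
  scores <- sapply(0:3, function(ix) sapply(0:3, function(iy) {
    sub <- cells[floor(cells$x_mm) == ix & floor(cells$y_mm) == iy, ]
    score_roi(sub)$score
  }))
  expect_lt(abs(mean(scores) - 150) / 150, 0.05)
})
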