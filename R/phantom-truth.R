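#' Generate ground-truth parameter maps
#'
#' Draws per-voxel D, D*, f, R2* and HIF-density fields over a label
#' volume. Each quantitative parameter is a tissue-wise Gaussian
#' (configured mean and SD) evaluated on a spatially smooth latent field,
#' so tissue-wise moments are recovered exactly in population. The HIF
#' field inside the tumor extent is a monotone Beta-quantile transform of
#' a latent that shares components with the R2* and D* latents:
#'
#' \deqn{L = a Z_{R2^*} - b Z_{D^*} + c Z_0,\quad a^2 + b^2 + c^2 = 1}
#'
#' with a and b set from the configured target Spearman correlations via
#' the Gaussian rank-correlation identity \eqn{a = 2\sin(\pi\rho/6)}.
#' Because rank correlations are invariant under monotone transforms, the
#' population Spearman of HIF with R2* (positive) and with D* (negative)
#' equals the configured coupling, regardless of the HIF marginal. A
#' linear core-to-rim shift of the latent makes HIF density highest in
#' the tumor core. Normal-tissue HIF uses the independent latent only.
#'
#' @param labels A `tissue_labels` volume.
#' @param config The [phantom_config()] used to generate it.
#' @return An object of class `truth_maps`: arrays `D`, `Dstar`, `f`
#'   (all with D* >= D and f in \[0, 1\]), `R2star` (Hz), `HIF` (0-300)
#'   and `S0`, plus grid metadata.
#' @export
generate_truth_maps <- function(labels, config) {
  stopifnot(inherits(labels, "tissue_labels"))
  validate_phantom_config(config)
  d <- dim(labels$labels)
  if (!identical(d, as.integer(config$shape)))
    stop("labels and config are not on the same grid")
  tp <- config$tissue_params
  sm <- config$field_smoothness_mm
  vox <- config$voxel_mm
  Zd  <- smooth_unit_field(d, sm, vox, stage_seed(config$seed, "fields", 1L))
  Zds <- smooth_unit_field(d, sm, vox, stage_seed(config$seed, "fields", 2L))
  Zf  <- smooth_unit_field(d, sm, vox, stage_seed(config$seed, "fields", 3L))
  Zr2 <- smooth_unit_field(d, sm, vox, stage_seed(config$seed, "fields", 4L))
  Zh  <- smooth_unit_field(d, sm, vox, stage_seed(config$seed, "fields", 5L))

  D <- array(tp$D_mean[1], d); Dstar <- array(tp$Dstar_mean[1], d)
  f <- array(tp$f_mean[1], d); R2 <- array(tp$R2star_mean[1], d)
  S0 <- array(0, d); HIF <- array(0, d)
  for (r in seq_len(nrow(tp))) {
    idx <- labels$labels == tp$code[r]
    if (!any(idx)) next
    D[idx] <- tp$D_mean[r] + tp$D_sd[r] * Zd[idx]
    Dstar[idx] <- tp$Dstar_mean[r] + tp$Dstar_sd[r] * Zds[idx]
    f[idx] <- tp$f_mean[r] + tp$f_sd[r] * Zf[idx]
    R2[idx] <- tp$R2star_mean[r] + tp$R2star_sd[r] * Zr2[idx]
    S0[idx] <- tp$S0[r]
  }
  D <- clamp(D, 1e-6, Inf)
  f <- clamp(f, 0, 0.999)
  R2 <- clamp(R2, 0.1, Inf)
  Dstar <- pmax(Dstar, D * (1 + 1e-9))

  # HIF field: tumor extent shares latents with R2* and D*.
  cp <- config$coupling
  a <- 2 * sin(pi * cp[["r2star"]] / 6)
  b <- 2 * sin(pi * abs(cp[["dstar"]]) / 6)
  cc <- sqrt(max(0, 1 - a^2 - b^2))
  tidx <- which(labels$labels %in% 2:5)
  if (length(tidx)) {
    L <- a * Zr2[tidx] - b * Zds[tidx] + cc * Zh[tidx]
    r_eff <- (3 * labels$meta$achieved_volume_mm3 / (4 * pi))^(1 / 3)
    pos <- arrayInd(tidx, d)
    dist <- sqrt((voxel_centers(d[1], vox[1])[pos[, 1]] - labels$tumor_center_mm[1])^2 +
                 (voxel_centers(d[2], vox[2])[pos[, 2]] - labels$tumor_center_mm[2])^2 +
                 (voxel_centers(d[3], vox[3])[pos[, 3]] - labels$tumor_center_mm[3])^2)
    r_norm <- clamp(dist / r_eff, 0, 1.2)
    # Linear core-to-rim latent shift, variance-compensated so the HIF
    # marginal keeps the configured mean and SD over the tumor voxels.
    g <- config$hif_radial_gradient
    shrink2 <- 1 - g^2 * stats::var(r_norm)
    if (shrink2 <= 0)
      stop("hif_radial_gradient too large for the tumor geometry")
    L <- sqrt(shrink2) * L + g * (mean(r_norm) - r_norm)
    bt <- beta_from_moments(tp$HIF_mean[2], tp$HIF_sd[2], 300)
    HIF[tidx] <- 300 * stats::qbeta(stats::pnorm(L), bt$shape1, bt$shape2)
  }
  nidx <- which(labels$labels == 1L)
  if (length(nidx)) {
    bn <- beta_from_moments(tp$HIF_mean[1], tp$HIF_sd[1], 300)
    HIF[nidx] <- 300 * stats::qbeta(stats::pnorm(Zh[nidx]), bn$shape1, bn$shape2)
  }

  out <- list(D = D, Dstar = Dstar, f = f, R2star = R2, HIF = HIF, S0 = S0,
              voxel_mm = vox,
              meta = list(seed = config$seed,
                          s0_ref = tp$S0[1],
                          coupling = cp,
                          tumor_center_mm = labels$tumor_center_mm))
  class(out) <- "truth_maps"
  out
}

#' @export
print.truth_maps <- function(x, ...) {
  cat("<truth_maps>", paste(dim(x$D), collapse = " x "), "voxels\n")
  cat(sprintf("  D in [%.3g, %.3g] mm^2/s; D* in [%.3g, %.3g]; f in [%.2f, %.2f]\n",
              min(x$D), max(x$D), min(x$Dstar), max(x$Dstar), min(x$f), max(x$f)))
  cat(sprintf("  R2* in [%.1f, %.1f] Hz; HIF in [%.1f, %.1f]\n",
              min(x$R2star), max(x$R2star), min(x$HIF), max(x$HIF)))
  invisible(x)
}
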