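#' Acquisition protocol constants
#'
#' Diffusion b-values (s/mm^2) and multi-echo gradient-echo echo times
#' (seconds) of the small-animal protocol the phantom emulates: 11 b-values
#' from 0 to 2000 s/mm^2 and 16 echoes from 3.4 to 92.1 ms, on a
#' 25.6 x 25.6 mm field of view with a 96 x 96 matrix and 1 mm slices.
#'
#' @return A list with elements `bvalues`, `echo_times_s`, `fov_mm`,
#'   `matrix_size` and `slice_mm`.
#' @export
#' @examples
#' acq_protocol()$bvalues
acq_protocol <- function() {
  list(
    bvalues = c(0, 25, 50, 75, 100, 150, 200, 300, 1000, 1500, 2000),
    echo_times_s = c(3.4, 9.3, 15.2, 21.2, 27.1, 33, 38.9, 44.8, 50.7,
                     56.6, 62.5, 68.5, 74.4, 80.3, 86.2, 92.1) / 1000,
    fov_mm = c(25.6, 25.6),
    matrix_size = c(96L, 96L),
    slice_mm = 1
  )
}

#' Tissue label codes
#' @return Named integer vector mapping tissue names to label codes.
#' @export
tissue_codes <- function() {
  c(background = 0L, normal = 1L, tumor = 2L, vessel = 3L,
    necrosis = 4L, calcification = 5L)
}

#' Default tissue parameter table
#'
#' Per-tissue means and SDs of the quantitative parameters used as
#' ground truth: D and D* in mm^2/s, perfusion fraction f (0-1), R2* in Hz,
#' HIF score density on the 0-300 scale, and a unitless proton-density-like
#' S0. Normal-brain and tumor rows carry literature-scale glioma-model
#' values; vessel, necrosis and calcification rows are physiologically
#' plausible settings for the minor intratumoral compartments (blood has
#' high pseudo-diffusion and perfusion fraction, necrotic fluid diffuses
#' freely with low perfusion, calcification is markedly hypointense with
#' very short T2*).
#'
#' @return A data.frame with one row per tissue code 1-5.
#' @export
tissue_defaults <- function() {
  data.frame(
    code = 1:5,
    tissue = c("normal", "tumor", "vessel", "necrosis", "calcification"),
    D_mean = c(414.21e-6, 419.50e-6, 900e-6, 1200e-6, 200e-6),
    D_sd   = c(53.38e-6, 81.97e-6, 150e-6, 200e-6, 50e-6),
    Dstar_mean = c(2755.02e-6, 2850.23e-6, 10000e-6, 2000e-6, 1000e-6),
    Dstar_sd   = c(441.42e-6, 444.48e-6, 2000e-6, 500e-6, 300e-6),
    f_mean = c(0.4629, 0.5109, 0.90, 0.10, 0.05),
    f_sd   = c(0.0275, 0.0858, 0.05, 0.05, 0.03),
    R2star_mean = c(36.74, 38.24, 60, 20, 150),
    R2star_sd   = c(9.35, 8.76, 10, 5, 30),
    HIF_mean = c(21.13, 123.73, NA, NA, NA),
    HIF_sd   = c(19.14, 70.18, NA, NA, NA),
    S0 = c(1000, 1100, 1200, 1300, 300)
  )
}

#' Phantom configuration
#'
#' Bundles the geometry, tissue parameters, coupling structure and noise
#' level that define one synthetic animal. All spatial quantities are in
#' mm. The defaults reproduce the emulated acquisition (25.6 mm FOV,
#' 96 x 96 in-plane matrix, 1 mm slices) and a basal-ganglia tumor of
#' 458 mm^3 placed 3 mm lateral of the volume midline.
#'
#' @param shape Integer vector, volume dimensions in voxels (x, y, z).
#' @param voxel_mm Voxel size in mm per axis.
#' @param brain_semiaxes_mm Semi-axes of the brain ellipsoid.
#' @param brain_center_mm Center of the brain ellipsoid; default volume
#'   center.
#' @param tumor_center_offset_mm Tumor center relative to the brain center.
#' @param tumor_volume_mm3 Target tumor volume; the generated tumor voxel
#'   count is matched to this within a fraction of a percent.
#' @param surface_irregularity Relative amplitude of the smooth angular
#'   perturbation of the tumor radius (0 = perfect sphere).
#' @param fractions Named fractions (of all tumor-extent voxels) assigned
#'   to `vessel`, `necrosis` and `calcification`.
#' @param noise_sigma Rician noise SD as a fraction of the mean
#'   normal-brain S0 (0.02 corresponds to SNR 50).
#' @param coupling Named vector with target population Spearman
#'   correlations of the HIF field with R2* (`r2star`, positive) and with
#'   D* (`dstar`, negative) inside the tumor.
#' @param hif_radial_gradient Strength (latent SD units per unit
#'   normalized radius) of the linear core-to-rim decrease of the HIF
#'   field inside the tumor; the default is calibrated so the mean
#'   HIF-score contrast between central and peripheral tumor ROIs is on
#'   the reported glioma-model scale (about 137 vs 109). The latent is
#'   variance-compensated, so the HIF marginal keeps its configured
#'   mean and SD regardless of the gradient.
#' @param field_smoothness_mm SD of the Gaussian kernel giving all latent
#'   parameter fields their spatial correlation length.
#' @param cells_per_mm2 Stained-cell density for the synthetic cell table.
#' @param tissue_params Tissue parameter table, see [tissue_defaults()].
#' @param protocol Acquisition protocol, see [acq_protocol()].
#' @param seed Master seed; every stochastic stage derives its own
#'   substream from it.
#'
#' @return An object of class `phantom_config`.
#' @export
#' @examples
#' cfg <- phantom_config(seed = 7)
#' cfg$tumor_radius_mm
phantom_config <- function(shape = c(96L, 96L, 16L),
                           voxel_mm = c(25.6 / 96, 25.6 / 96, 1),
                           brain_semiaxes_mm = c(10.5, 11.5, 7.5),
                           brain_center_mm = NULL,
                           tumor_center_offset_mm = c(-3, 1, 0),
                           tumor_volume_mm3 = 458,
                           surface_irregularity = 0.08,
                           fractions = c(vessel = 0.06, necrosis = 0.10,
                                         calcification = 0.02),
                           noise_sigma = 0.02,
                           coupling = c(r2star = 0.43, dstar = -0.30),
                           hif_radial_gradient = 1.4,
                           field_smoothness_mm = 0.3,
                           cells_per_mm2 = 1000,
                           tissue_params = tissue_defaults(),
                           protocol = acq_protocol(),
                           seed = 1L) {
  if (is.null(brain_center_mm)) brain_center_mm <- shape * voxel_mm / 2
  cfg <- list(
    shape = as.integer(shape), voxel_mm = voxel_mm,
    brain_semiaxes_mm = brain_semiaxes_mm,
    brain_center_mm = brain_center_mm,
    tumor_center_mm = brain_center_mm + tumor_center_offset_mm,
    tumor_volume_mm3 = tumor_volume_mm3,
    tumor_radius_mm = (3 * tumor_volume_mm3 / (4 * pi))^(1 / 3),
    surface_irregularity = surface_irregularity,
    fractions = fractions,
    noise_sigma = noise_sigma,
    coupling = coupling,
    hif_radial_gradient = hif_radial_gradient,
    field_smoothness_mm = field_smoothness_mm,
    cells_per_mm2 = cells_per_mm2,
    tissue_params = tissue_params,
    protocol = protocol,
    seed = as.integer(seed)
  )
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

#' Validate a phantom configuration
#'
#' Checks fractions, geometry, parameter moments and coupling magnitudes;
#' stops with an informative error on the first violation.
#'
#' @param cfg A `phantom_config`.
#' @return `cfg`, invisibly.
#' @export
validate_phantom_config <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  fr <- cfg$fractions
  if (!all(c("vessel", "necrosis", "calcification") %in% names(fr)))
    stop("fractions must name vessel, necrosis and calcification")
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (sum(fr) >= 1) stop("intratumoral component fractions must sum to < 1")
  if (cfg$tumor_volume_mm3 <= 0) stop("tumor volume must be positive")
  if (cfg$surface_irregularity < 0) stop("surface irregularity must be >= 0")
  if (cfg$noise_sigma < 0) stop("noise sigma must be >= 0")
  tp <- cfg$tissue_params
  if (any(tp$D_mean <= 0) || any(tp$Dstar_mean <= 0) || any(tp$R2star_mean <= 0))
    stop("tissue parameter means must be positive")
  if (any(tp$f_mean < 0 | tp$f_mean > 1)) stop("f means must lie in [0, 1]")
  cp <- cfg$coupling
  if (any(abs(cp) > 1)) stop("coupling coefficients must lie in [-1, 1]")
  a <- 2 * sin(pi * abs(cp[["r2star"]]) / 6)
  b <- 2 * sin(pi * abs(cp[["dstar"]]) / 6)
  if (a^2 + b^2 > 1)
    stop("joint coupling magnitudes too large for a shared latent field")
  if (cfg$cells_per_mm2 <= 0) stop("cell density must be positive")
  bv <- cfg$protocol$bvalues
  if (any(bv < 0) || !any(bv == 0)) stop("b-values must be >= 0 and include 0")
  te <- cfg$protocol$echo_times_s
  if (any(te <= 0) || any(diff(te) <= 0))
    stop("echo times must be positive and strictly increasing")
  invisible(cfg)
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("<phantom_config>\n")
  cat(sprintf("  volume: %s voxels @ %.3f x %.3f x %.2f mm\n",
              paste(x$shape, collapse = " x "),
              x$voxel_mm[1], x$voxel_mm[2], x$voxel_mm[3]))
  cat(sprintf("  tumor:  %.0f mm^3 (radius %.2f mm) at (%.1f, %.1f, %.1f) mm\n",
              x$tumor_volume_mm3, x$tumor_radius_mm,
              x$tumor_center_mm[1], x$tumor_center_mm[2], x$tumor_center_mm[3]))
  cat(sprintf("  components: vessel %.0f%%, necrosis %.0f%%, calcification %.0f%%\n",
              100 * x$fractions[["vessel"]], 100 * x$fractions[["necrosis"]],
              100 * x$fractions[["calcification"]]))
  cat(sprintf("  coupling: Spearman(HIF, R2*) = %+.2f, Spearman(HIF, D*) = %+.2f\n",
              x$coupling[["r2star"]], x$coupling[["dstar"]]))
  cat(sprintf("  noise sigma: %.3f x S0(normal), seed %d\n", x$noise_sigma, x$seed))
  invisible(x)
}
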