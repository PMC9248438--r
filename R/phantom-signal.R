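#' Add Rician noise to magnitude data
#'
#' Magnitude-MRI noise model: the output is
#' \eqn{\sqrt{(s + g_1)^2 + g_2^2}} with independent zero-mean Gaussian
#' `g1`, `g2` of SD `sigma`. With `sigma = 0` the input is returned
#' unchanged.
#'
#' @param x Numeric array or vector of noiseless magnitudes.
#' @param sigma Noise SD (same units as `x`); must be >= 0.
#' @param seed Optional seed; if given the result is reproducible and the
#'   caller's RNG state is untouched.
#' @return Noisy magnitudes with the shape of `x`.
#' @export
#' @examples
#' add_rician_noise(c(0, 10, 100), sigma = 1, seed = 1)
add_rician_noise <- function(x, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(x)
  draw <- function() {
    g1 <- stats::rnorm(length(x), 0, sigma)
    g2 <- stats::rnorm(length(x), 0, sigma)
    y <- sqrt((as.vector(x) + g1)^2 + g2^2)
    if (is.array(x)) array(y, dim(x)) else y
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

.series <- function(data, index, index_name, voxel_mm, slices, sigma, type) {
  out <- list(data = data, voxel_mm = voxel_mm, slices = slices,
              sigma = sigma, type = type)
  out[[index_name]] <- index
  class(out) <- "mri_series"
  out
}

#' Synthesize a multi-b diffusion-weighted series
#'
#' Noiseless voxel signal follows the IVIM biexponential
#' \eqn{S(b) = S_0[(1 - f)e^{-bD} + f e^{-bD^*}]}; Rician noise is added
#' when `sigma > 0`. `sigma` is expressed as a fraction of the mean
#' normal-brain S0 so that, e.g., `sigma = 0.02` gives SNR 50 in normal
#' brain.
#'
#' @param truth A `truth_maps` object.
#' @param bvalues b-values in s/mm^2; must be non-negative and include 0.
#' @param sigma Noise level (fraction of normal-brain S0), >= 0.
#' @param seed Seed for the noise substream.
#' @param slices Optional integer vector of slice indices to synthesize
#'   (default: all).
#' @return An `mri_series` with a 4D `data` array (x, y, slice, b) and
#'   the `bvalues` stored alongside.
#' @export
synthesize_dwi <- function(truth, bvalues = acq_protocol()$bvalues,
                           sigma = 0, seed = 1L, slices = NULL) {
  stopifnot(inherits(truth, "truth_maps"))
  if (any(bvalues < 0)) stop("b-values must be non-negative")
  if (!any(bvalues == 0)) stop("a b = 0 acquisition is required")
  if (sigma < 0) stop("sigma must be >= 0")
  d <- dim(truth$D)
  if (is.null(slices)) slices <- seq_len(d[3])
  sub <- function(a) a[, , slices, drop = FALSE]
  S0 <- sub(truth$S0); D <- sub(truth$D); Ds <- sub(truth$Dstar); f <- sub(truth$f)
  nb <- length(bvalues)
  sig <- array(0, c(d[1], d[2], length(slices), nb))
  for (k in seq_len(nb)) {
    b <- bvalues[k]
    sig[, , , k] <- S0 * ((1 - f) * exp(-b * D) + f * exp(-b * Ds))
  }
  if (sigma > 0)
    sig <- add_rician_noise(sig, sigma * truth$meta$s0_ref,
                            seed = stage_seed(seed, "dwi"))
  .series(sig, bvalues, "bvalues", truth$voxel_mm, slices, sigma, "dwi")
}

#' Synthesize a multi-echo gradient-echo series
#'
#' Noiseless voxel signal is \eqn{S(TE) = S_0 e^{-TE \cdot R2^*}} with TE
#' in seconds and R2* in Hz; Rician noise as in [synthesize_dwi()].
#'
#' @inheritParams synthesize_dwi
#' @param echo_times_s Echo times in seconds; strictly increasing,
#'   positive.
#' @return An `mri_series` with a 4D `data` array (x, y, slice, echo).
#' @export
synthesize_mege <- function(truth, echo_times_s = acq_protocol()$echo_times_s,
                            sigma = 0, seed = 1L, slices = NULL) {
  stopifnot(inherits(truth, "truth_maps"))
  if (any(echo_times_s <= 0) || any(diff(echo_times_s) <= 0))
    stop("echo times must be positive and strictly increasing")
  if (sigma < 0) stop("sigma must be >= 0")
  d <- dim(truth$D)
  if (is.null(slices)) slices <- seq_len(d[3])
  S0 <- truth$S0[, , slices, drop = FALSE]
  R2 <- truth$R2star[, , slices, drop = FALSE]
  ne <- length(echo_times_s)
  sig <- array(0, c(d[1], d[2], length(slices), ne))
  for (k in seq_len(ne)) sig[, , , k] <- S0 * exp(-echo_times_s[k] * R2)
  if (sigma > 0)
    sig <- add_rician_noise(sig, sigma * truth$meta$s0_ref,
                            seed = stage_seed(seed, "mege"))
  .series(sig, echo_times_s, "echo_times_s", truth$voxel_mm, slices, sigma,
          "mege")
}

#' @export
print.mri_series <- function(x, ...) {
  cat("<mri_series>", x$type, paste(dim(x$data), collapse = " x "), "\n")
  if (x$type == "dwi") cat("  b-values:", paste(x$bvalues, collapse = ", "), "s/mm^2\n")
  else cat("  echoes:", paste(round(x$echo_times_s * 1000, 1), collapse = ", "), "ms\n")
  cat("  sigma:", x$sigma, "\n")
  invisible(x)
}
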