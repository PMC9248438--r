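# Internal helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so generators never perturb
#' the session stream.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Deterministic per-stage substream seeds derived from one master seed.
# Seeds are drawn through the RNG itself (not by affine arithmetic on the
# master seed): linearly related seed values can leave detectable
# correlations between Mersenne-Twister streams, which would couple
# independently intended generator stages.
stage_seed <- function(master, stage, k = 0L) {
  offsets <- c(labels = 1, fields = 11, dwi = 31, mege = 41,
               cells = 51, noise = 61, study = 71, animal = 1000)
  idx <- offsets[[stage]] + as.integer(k)
  with_seed(master, sample.int(2147483646L, idx)[idx])
}

# Physical coordinates (mm) of voxel centers along one axis.
voxel_centers <- function(n, d) (seq_len(n) - 0.5) * d

gauss_kernel <- function(sd_vox) {
  if (sd_vox <= 0.05) return(1)
  r <- max(1L, ceiling(3 * sd_vox))
  x <- seq(-r, r)
  w <- exp(-x^2 / (2 * sd_vox^2))
  w / sum(w)
}

# Shift a 3D array along one axis with edge replication.
shift_arr3 <- function(a, axis, by) {
  d <- dim(a)
  idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  idx[[axis]] <- clamp(idx[[axis]] - by, 1L, d[axis])
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# Separable Gaussian convolution of a 3D array.
smooth3d <- function(a, sd_vox) {
  for (ax in 1:3) {
    w <- gauss_kernel(sd_vox[ax])
    if (length(w) == 1L) next
    r <- (length(w) - 1L) / 2L
    out <- array(0, dim(a))
    for (j in seq_along(w)) out <- out + w[j] * shift_arr3(a, ax, j - r - 1L)
    a <- out
  }
  a
}

#' Smooth unit-variance Gaussian random field
#'
#' White Gaussian noise convolved with an isotropic (in mm) Gaussian kernel
#' and rescaled by the theoretical post-convolution standard deviation so
#' the marginal is approximately N(0, 1) away from the volume edges.
#' @noRd
smooth_unit_field <- function(dim, sd_mm, voxel_mm, seed) {
  z <- with_seed(seed, array(stats::rnorm(prod(dim)), dim))
  if (sd_mm <= 0) return(z)
  sd_vox <- sd_mm / voxel_mm
  z <- smooth3d(z, sd_vox)
  v <- prod(vapply(sd_vox, function(s) sum(gauss_kernel(s)^2), numeric(1)))
  z / sqrt(v)
}

# Beta(a, b) shape parameters matching a mean and SD on [0, scale].
beta_from_moments <- function(mean, sd, scale = 300) {
  m <- mean / scale
  v <- (sd / scale)^2
  if (m <= 0 || m >= 1) stop("mean must lie strictly inside (0, scale)")
  if (v >= m * (1 - m)) stop("sd too large for a Beta distribution on [0, scale]")
  s <- m * (1 - m) / v - 1
  list(shape1 = m * s, shape2 = (1 - m) * s)
}
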