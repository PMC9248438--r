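#' Synthesize a stained-cell table for one slice
#'
#' Emulates the input of an IHC quantification package: individual cells
#' with a staining intensity category 0-3. Cells are placed by a seeded
#' homogeneous Poisson process over the tissue pixels of the chosen
#' slice. Each cell's category is drawn from the local HIF density
#' `h` (0-300): with `q = h/300`, a cell is positive with probability
#' `3q / (1 + 2q)` and a positive cell's category is `1 + Binomial(2, q)`.
#' The expected ROI score, percent-positive times mean positive
#' intensity, then equals `100 * 3q/(1+2q) * (1+2q) = h`, so grid scores
#' computed by [score_roi()] are unbiased for the local HIF density at
#' any density level, with exact saturation at 0 and 300.
#'
#' @param truth A `truth_maps` object (provides the HIF density field).
#' @param labels The matching `tissue_labels` volume.
#' @param slice Slice index the histology section corresponds to.
#' @param cells_per_mm2 Mean cell density (cells per mm^2); densities
#'   expecting fewer than 20 cells per 1 mm^2 ROI trigger a warning
#'   because scores become unstable.
#' @param seed Seed for the point process and category draws.
#' @param mask Optional logical matrix (in-plane) restricting where cells
#'   are generated; default is all tissue pixels.
#' @return A `cell_table` data.frame with columns `x_mm`, `y_mm`,
#'   `slice`, `intensity`.
#' @export
synthesize_cell_table <- function(truth, labels, slice,
                                  cells_per_mm2 = 1000, seed = 1L,
                                  mask = NULL) {
  stopifnot(inherits(truth, "truth_maps"), inherits(labels, "tissue_labels"))
  if (cells_per_mm2 <= 0) stop("cell density must be positive")
  if (cells_per_mm2 < 20)
    warning("fewer than 20 cells expected per 1 mm^2 ROI; scores will be unstable")
  lab2 <- labels$labels[, , slice]
  tissue <- lab2 > 0L
  if (!is.null(mask)) tissue <- tissue & mask
  pix <- which(tissue)
  vox <- labels$voxel_mm
  area <- length(pix) * vox[1] * vox[2]
  hif2 <- truth$HIF[, , slice]
  d <- dim(lab2)

  tab <- with_seed(stage_seed(seed, "cells"), {
    n <- stats::rpois(1, cells_per_mm2 * area)
    if (n == 0) {
      data.frame(x_mm = numeric(0), y_mm = numeric(0),
                 slice = integer(0), intensity = integer(0))
    } else {
      at <- pix[sample.int(length(pix), n, replace = TRUE)]
      i <- ((at - 1L) %% d[1]) + 1L
      j <- ((at - 1L) %/% d[1]) + 1L
      x <- (i - 1L) * vox[1] + stats::runif(n) * vox[1]
      y <- (j - 1L) * vox[2] + stats::runif(n) * vox[2]
      q <- clamp(hif2[at] / 300, 0, 1)
      p_pos <- 3 * q / (1 + 2 * q)
      pos <- stats::runif(n) < p_pos
      cat <- integer(n)
      cat[pos] <- 1L + stats::rbinom(sum(pos), 2L, q[pos])
      data.frame(x_mm = x, y_mm = y, slice = rep(as.integer(slice), n),
                 intensity = cat)
    }
  })
  attr(tab, "meta") <- list(seed = seed, cells_per_mm2 = cells_per_mm2,
                            area_mm2 = area)
  class(tab) <- c("cell_table", "data.frame")
  tab
}
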