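#' Classify a cell's staining intensity
#'
#' Maps a continuous optical density to a category 0-3 using three
#' strictly increasing thresholds: the category is the number of
#' thresholds at or below the density (ties go to the higher category).
#' Synthetic cell tables already carry categories, for which this is the
#' identity.
#'
#' @param density Numeric optical density value(s).
#' @param thresholds Strictly increasing numeric vector of length 3.
#' @return Integer category in \{0, 1, 2, 3\}.
#' @export
#' @examples
#' classify_cell_intensity(c(0.05, 0.2, 0.9), thresholds = c(0.1, 0.3, 0.6))
classify_cell_intensity <- function(density, thresholds) {
  if (length(thresholds) != 3 || any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing and of length 3")
  as.integer(rowSums(outer(density, thresholds, `>=`)))
}

#' Expression label from a HIF score
#'
#' A score above the cut (default 150) marks a high-expression region,
#' otherwise low. A score exactly at the cut is classed low, keeping the
#' rule a partition of the 0-300 range.
#'
#' @param score HIF score(s) in \[0, 300\].
#' @param cut High/low threshold.
#' @return Character vector `"high"` / `"low"`.
#' @export
#' @examples
#' label_expression(c(122.89, 174.12, 150))
label_expression <- function(score, cut = 150) {
  if (any(score < 0 | score > 300, na.rm = TRUE))
    stop("scores must lie in [0, 300]")
  ifelse(score > cut, "high", "low")
}

#' Score one ROI from its cells
#'
#' HALO-style ROI quantification: percent positive is the share of cells
#' with category >= 1 (on a 0-100 scale), the intensity score is the
#' arithmetic mean category among positive cells (0 if none), and the
#' final score is their product, spanning 0-300. The mean-category
#' convention makes the score continuous, like decimal-valued reported
#' scores; the binned histopathology H-score (sum of category times the
#' percent of cells in that category) is also returned as `h_score` for
#' reference but is not the headline score.
#'
#' @param cells A data.frame with an `intensity` column of categories
#'   0-3 (e.g. a subset of a `cell_table`).
#' @param cut High/low expression threshold passed to
#'   [label_expression()].
#' @return A one-row data.frame: `n_cells`, `percent_positive`,
#'   `intensity`, `score`, `label`, `h_score`, `valid`. An empty cell
#'   set yields an invalid (flagged) row with NA score.
#' @export
#' @examples
#' cells <- data.frame(intensity = c(rep(2L, 60), rep(0L, 40)))
#' score_roi(cells)  # percent 60, intensity 2, score 120, label "low"
score_roi <- function(cells, cut = 150) {
  if (!is.data.frame(cells) || !"intensity" %in% names(cells))
    stop("cells must be a data.frame with an intensity column")
  n <- nrow(cells)
  if (n == 0) {
    return(data.frame(n_cells = 0L, percent_positive = NA_real_,
                      intensity = NA_real_, score = NA_real_,
                      label = NA_character_, h_score = NA_real_,
                      valid = FALSE))
  }
  cat <- cells$intensity
  if (any(!cat %in% 0:3)) stop("intensity categories must be in {0, 1, 2, 3}")
  pos <- cat >= 1L
  pct <- 100 * mean(pos)
  its <- if (any(pos)) mean(cat[pos]) else 0
  sc <- pct * its
  data.frame(n_cells = n, percent_positive = pct, intensity = its,
             score = sc, label = label_expression(sc, cut),
             h_score = 100 * mean(cat), valid = TRUE)
}
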