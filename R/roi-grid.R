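#' Analysis configuration for the ROI grid
#'
#' Houses the grid-analysis constants: 1 mm^2 square ROIs, a purity rule
#' (an ROI must contain only tumor-extent or only normal tissue), an
#' exclusive 25% cap on the vessel + necrosis + calcification
#' composition, no background ("air") voxels, a strict 1 mm
#' center-to-edge rule separating peripheral from central tumor ROIs,
#' and the 150-point high/low HIF expression cut.
#'
#' @param roi_side_mm ROI side length in mm.
#' @param composition_threshold Exclusive upper limit on the combined
#'   vessel/necrosis/calcification fraction.
#' @param edge_mm Center-to-tumor-edge distance below which (strictly) a
#'   tumor ROI is peripheral.
#' @param hif_cut High/low HIF expression threshold.
#' @param normal_policy How normal-tissue ROIs enter the analysis:
#'   `"mirror"` keeps only normal ROIs whose mirrored grid cell (across
#'   the mid-sagittal grid axis) is an analyzed tumor ROI, emulating a
#'   contralateral comparison region; `"all"` analyzes every included
#'   normal ROI.
#' @param fit_method IVIM fitting method for the pipeline,
#'   `"segmented"` or `"full"`.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(roi_side_mm = 1,
                            composition_threshold = 0.25,
                            edge_mm = 1,
                            hif_cut = 150,
                            normal_policy = c("mirror", "all"),
                            fit_method = c("segmented", "full")) {
  if (composition_threshold <= 0 || composition_threshold > 1)
    stop("composition threshold must lie in (0, 1]")
  if (edge_mm <= 0 || roi_side_mm <= 0) stop("distances must be > 0")
  structure(list(roi_side_mm = roi_side_mm,
                 composition_threshold = composition_threshold,
                 edge_mm = edge_mm, hif_cut = hif_cut,
                 normal_policy = match.arg(normal_policy),
                 fit_method = match.arg(fit_method)),
            class = "analysis_config")
}

#' Select the largest tumor slice
#'
#' Returns the slice index with the largest in-plane tumor pixel count
#' (tumor extent = tumor plus intratumoral components); ties resolve to
#' the lowest index.
#'
#' @param labels A `tissue_labels` volume.
#' @return Integer slice index.
#' @export
select_largest_tumor_slice <- function(labels) {
  stopifnot(inherits(labels, "tissue_labels"))
  tum <- labels$labels %in% 2:5
  dim(tum) <- dim(labels$labels)
  counts <- apply(tum, 3, sum)
  if (all(counts == 0)) stop("label volume contains no tumor")
  which.max(counts)
}

#' Tessellate a slice into square ROIs
#'
#' Lays an axis-aligned grid of half-open square cells
#' \eqn{[x, x+s) \times [y, y+s)} mm anchored at the image origin over
#' the in-plane field of view. Cells extending past the field of view
#' are dropped; voxels are assigned to cells by voxel-center membership,
#' so every voxel center belongs to exactly one (possibly dropped) cell.
#'
#' @param n_vox Integer vector (nx, ny), in-plane voxel counts.
#' @param voxel_mm In-plane voxel size (mm) per axis.
#' @param side_mm ROI side length; must be >= the voxel size.
#' @return A list of class `roi_grid`: cell counts `nx`, `ny`, the cell
#'   table `cells` (0-based indices `ix`, `iy`, id and center), and the
#'   per-axis voxel-to-cell index maps (`NA` for voxels in dropped
#'   cells).
#' @export
#' @examples
#' g <- tessellate(c(96L, 96L), c(25.6 / 96, 25.6 / 96))
#' g$nx * g$ny  # 625 complete 1 mm^2 cells on a 25.6 mm FOV
tessellate <- function(n_vox, voxel_mm, side_mm = 1) {
  if (side_mm < max(voxel_mm)) stop("ROI side must be >= the voxel size")
  fov <- n_vox * voxel_mm
  nx <- floor(fov[1] / side_mm + 1e-9)
  ny <- floor(fov[2] / side_mm + 1e-9)
  cx <- voxel_centers(n_vox[1], voxel_mm[1])
  cy <- voxel_centers(n_vox[2], voxel_mm[2])
  vx_cell <- floor(cx / side_mm); vx_cell[vx_cell >= nx] <- NA
  vy_cell <- floor(cy / side_mm); vy_cell[vy_cell >= ny] <- NA
  cells <- expand.grid(ix = 0:(nx - 1), iy = 0:(ny - 1))
  cells$roi_id <- sprintf("r%02d_%02d", cells$ix, cells$iy)
  cells$cx_mm <- (cells$ix + 0.5) * side_mm
  cells$cy_mm <- (cells$iy + 0.5) * side_mm
  structure(list(nx = nx, ny = ny, side_mm = side_mm, voxel_mm = voxel_mm,
                 n_vox = n_vox, cells = cells,
                 vx_cell = vx_cell, vy_cell = vy_cell),
            class = "roi_grid")
}

#' Composition fractions of the ROIs on a slice
#'
#' Per grid cell, the fraction of assigned voxels carrying each tissue
#' code; fractions sum to one within every cell.
#'
#' @param labels_slice Integer matrix of tissue codes for one slice.
#' @param grid A [tessellate()] grid matching the slice.
#' @return A data.frame with one row per cell: `roi_id`, `n_vox` and
#'   `frac_background`, `frac_normal`, `frac_tumor`, `frac_vessel`,
#'   `frac_necrosis`, `frac_calcification`.
#' @export
compute_composition <- function(labels_slice, grid) {
  stopifnot(inherits(grid, "roi_grid"),
            identical(dim(labels_slice), as.integer(grid$n_vox)))
  ii <- rep(seq_len(nrow(labels_slice)), times = ncol(labels_slice))
  jj <- rep(seq_len(ncol(labels_slice)), each = nrow(labels_slice))
  cix <- grid$vx_cell[ii]; ciy <- grid$vy_cell[jj]
  ok <- !is.na(cix) & !is.na(ciy)
  cell_lin <- cix[ok] + grid$nx * ciy[ok]
  lab <- as.vector(labels_slice)[ok]
  counts <- table(factor(cell_lin, levels = 0:(grid$nx * grid$ny - 1)),
                  factor(lab, levels = 0:5))
  counts <- matrix(as.integer(counts), nrow = grid$nx * grid$ny)
  n_vox <- rowSums(counts)
  fr <- counts / pmax(n_vox, 1L)
  out <- grid$cells
  out$n_vox <- n_vox[out$ix + grid$nx * out$iy + 1L]
  fr <- fr[out$ix + grid$nx * out$iy + 1L, , drop = FALSE]
  colnames(fr) <- paste0("frac_", names(tissue_codes()))
  cbind(out, as.data.frame(fr))
}

#' Apply the ROI inclusion filters
#'
#' An ROI is included when (a) it contains no background ("air") voxels,
#' (b) its tissue voxels are exclusively tumor extent (tumor plus
#' intratumoral components) or exclusively normal tissue, and (c) the
#' combined vessel + necrosis + calcification fraction is strictly below
#' the composition threshold. Excluded ROIs carry the first failing
#' reason in the fixed order air, mixed, composition.
#'
#' @param comp A data.frame from [compute_composition()].
#' @param cfg An [analysis_config()].
#' @return `comp` with added columns `included` (logical), `reason`
#'   (`NA`, `"air"`, `"mixed"` or `"composition"`) and `tissue`
#'   (`"tumor"`, `"normal"` or `NA` for excluded cells).
#' @export
apply_inclusion_filters <- function(comp, cfg = analysis_config()) {
  tumor_ext <- comp$frac_tumor + comp$frac_vessel + comp$frac_necrosis +
    comp$frac_calcification
  compfr <- comp$frac_vessel + comp$frac_necrosis + comp$frac_calcification
  reason <- rep(NA_character_, nrow(comp))
  reason[comp$frac_background > 0] <- "air"
  mixed <- is.na(reason) & comp$frac_normal > 0 & tumor_ext > 0
  reason[mixed] <- "mixed"
  reason[is.na(reason) & compfr >= cfg$composition_threshold] <- "composition"
  comp$included <- is.na(reason)
  comp$reason <- reason
  comp$tissue <- ifelse(comp$included,
                        ifelse(tumor_ext > 0, "tumor", "normal"),
                        NA_character_)
  comp
}

#' Classify tumor ROIs as central or peripheral
#'
#' For each tumor ROI center, the in-plane Euclidean distance to the
#' nearest tumor boundary pixel center is computed (a boundary pixel is
#' a tumor-extent pixel with at least one 4-neighbour outside the tumor
#' extent, counting the image border as outside). A distance strictly
#' below `edge_mm` marks the ROI peripheral, otherwise central.
#'
#' @param centers_mm Two-column matrix of ROI centers (mm).
#' @param tumor_mask Logical matrix: in-plane tumor extent.
#' @param voxel_mm In-plane voxel size.
#' @param edge_mm Strict distance threshold (mm).
#' @return Character vector `"peripheral"` / `"central"` per row of
#'   `centers_mm`.
#' @export
classify_region <- function(centers_mm, tumor_mask, voxel_mm, edge_mm = 1) {
  if (!any(tumor_mask)) stop("tumor mask is empty")
  d <- dim(tumor_mask)
  pad <- function(by_i, by_j) {
    m <- matrix(FALSE, d[1], d[2])
    src_i <- seq_len(d[1]) + by_i; src_j <- seq_len(d[2]) + by_j
    ok_i <- src_i >= 1 & src_i <= d[1]; ok_j <- src_j >= 1 & src_j <= d[2]
    m[ok_i, ok_j] <- tumor_mask[src_i[ok_i], src_j[ok_j]]
    m
  }
  interior <- tumor_mask & pad(1, 0) & pad(-1, 0) & pad(0, 1) & pad(0, -1)
  boundary <- which(tumor_mask & !interior, arr.ind = TRUE)
  bx <- (boundary[, 1] - 0.5) * voxel_mm[1]
  by <- (boundary[, 2] - 0.5) * voxel_mm[2]
  centers_mm <- matrix(centers_mm, ncol = 2)
  dist <- vapply(seq_len(nrow(centers_mm)), function(k) {
    sqrt(min((bx - centers_mm[k, 1])^2 + (by - centers_mm[k, 2])^2))
  }, numeric(1))
  ifelse(dist < edge_mm, "peripheral", "central")
}

# Mirror a cell index across the mid-grid axis (contralateral cell).
.mirror_ix <- function(ix, nx) nx - 1L - ix

#' Aggregate parameter maps and cells over the ROI grid
#'
#' Builds the per-ROI record table for one analysis slice: composition
#' and inclusion filtering for every complete grid cell,
#' central/peripheral classification of tumor ROIs, arithmetic means of
#' the parameter maps over converged voxels, and the HIF score from the
#' cells falling inside the (optionally rigidly transformed) ROI
#' footprint. Analyzed ROIs with zero converged voxels or an empty cell
#' set are excluded with reasons `"no-map"` / `"no-cells"`.
#'
#' @param labels_slice Integer matrix of tissue codes for the analysis
#'   slice.
#' @param voxel_mm In-plane voxel size (mm).
#' @param maps Named list of 2D parameter matrices (`D`, `Dstar`, `f`,
#'   `perfusion`, `R2star`) plus logical convergence masks `conv_ivim`
#'   and `conv_r2star`; may be `NULL` to aggregate labels and cells
#'   only.
#' @param cells A `cell_table` (or compatible data.frame) for the slice,
#'   in histology coordinates.
#' @param cfg An [analysis_config()].
#' @param analysis_cells Optional character vector of `roi_id`s to
#'   analyze (default: all included cells).
#' @param transform Optional rigid histology-to-MR transform, a list
#'   with `theta` (radians), `tx`, `ty` (mm), applied to cell positions;
#'   default identity (shared coordinate frame).
#' @param dwi,mege Optional raw-signal inputs for ROI-curve fitting:
#'   lists with a `signal` matrix (one row per in-plane voxel, in
#'   column-major slice order) and `bvalues` / `echo_times_s`. When
#'   supplied, the headline ROI parameters are obtained by fitting the
#'   model to the ROI-averaged signal (the normalization SI0 is the
#'   ROI-mean b = 0 signal), which is how the biexponential is posed at
#'   ROI level; the voxel-map means are then reported as
#'   `*_voxmean` columns. Without raw signals the voxel-map means fill
#'   the headline columns.
#' @return A data.frame with one row per complete grid cell (the
#'   `RoiRecord` table).
#' @export
aggregate_roi <- function(labels_slice, voxel_mm, maps = NULL, cells = NULL,
                          cfg = analysis_config(), analysis_cells = NULL,
                          transform = NULL, dwi = NULL, mege = NULL) {
  grid <- tessellate(dim(labels_slice), voxel_mm, cfg$roi_side_mm)
  rec <- apply_inclusion_filters(compute_composition(labels_slice, grid), cfg)

  tumor_mask <- matrix(labels_slice %in% 2:5, nrow = nrow(labels_slice))
  rec$region <- NA_character_
  tum_rows <- which(rec$included & rec$tissue == "tumor")
  if (length(tum_rows))
    rec$region[tum_rows] <- classify_region(
      as.matrix(rec[tum_rows, c("cx_mm", "cy_mm")]),
      tumor_mask, voxel_mm, cfg$edge_mm)
  rec$region[rec$included & rec$tissue == "normal"] <- "normal"

  if (is.null(analysis_cells)) analysis_cells <- rec$roi_id[rec$included]
  rec$analyzed <- rec$included & rec$roi_id %in% analysis_cells

  par_names <- c("D", "Dstar", "f", "perfusion", "R2star")
  for (p in c(par_names, paste0(par_names, "_voxmean"),
              "n_conv_ivim", "n_conv_r2star"))
    rec[[p]] <- NA_real_
  if (!is.null(maps) || !is.null(dwi) || !is.null(mege)) {
    ii <- rep(seq_len(nrow(labels_slice)), times = ncol(labels_slice))
    jj <- rep(seq_len(ncol(labels_slice)), each = nrow(labels_slice))
    cix <- grid$vx_cell[ii]; ciy <- grid$vy_cell[jj]
    vox_roi <- ifelse(is.na(cix) | is.na(ciy), NA,
                      sprintf("r%02d_%02d", cix, ciy))
    tissue_vox <- as.vector(labels_slice) > 0L
    for (r in which(rec$analyzed)) {
      vv <- which(!is.na(vox_roi) & vox_roi == rec$roi_id[r])
      if (!is.null(maps)) {
        civ <- maps$conv_ivim[vv]; cr2 <- maps$conv_r2star[vv]
        civ[is.na(civ)] <- FALSE; cr2[is.na(cr2)] <- FALSE
        rel <- if (is.null(maps$dstar_reliable)) civ else
          maps$dstar_reliable[vv]
        rel[is.na(rel)] <- FALSE
        rec$n_conv_ivim[r] <- sum(civ)
        rec$n_conv_r2star[r] <- sum(cr2)
        if (any(civ)) {
          rec$D_voxmean[r] <- mean(maps$D[vv][civ])
          rec$f_voxmean[r] <- mean(maps$f[vv][civ])
        }
        if (any(rel)) {
          rec$Dstar_voxmean[r] <- mean(maps$Dstar[vv][rel])
          rec$perfusion_voxmean[r] <- mean(maps$perfusion[vv][rel])
        }
        if (any(cr2)) rec$R2star_voxmean[r] <- mean(maps$R2star[vv][cr2])
      }
      tv <- vv[tissue_vox[vv]]
      if (!is.null(dwi) && length(tv)) {
        curve <- colMeans(dwi$signal[tv, , drop = FALSE])
        fit <- fit_ivim_segmented(curve, dwi$bvalues,
                                  dwi$cfg %||% ivim_fit_config())
        if (isTRUE(fit$converged)) {
          rec$D[r] <- fit$D; rec$Dstar[r] <- fit$Dstar
          rec$f[r] <- fit$f; rec$perfusion[r] <- fit$perfusion
        }
      }
      if (!is.null(mege) && length(tv)) {
        curve <- colMeans(mege$signal[tv, , drop = FALSE])
        fit <- fit_r2star(curve, mege$echo_times_s,
                          mege$cfg %||% r2star_fit_config())
        if (isTRUE(fit$converged)) rec$R2star[r] <- fit$R2star
      }
    }
    if (is.null(dwi))
      for (p in c("D", "Dstar", "f", "perfusion"))
        rec[[p]] <- rec[[paste0(p, "_voxmean")]]
    if (is.null(mege)) rec$R2star <- rec$R2star_voxmean
    if (!is.null(maps)) {
      no_map <- rec$analyzed & (rec$n_conv_ivim == 0 | rec$n_conv_r2star == 0)
      rec$included[no_map] <- FALSE
      rec$reason[no_map] <- "no-map"
      rec$analyzed[no_map] <- FALSE
    }
  }

  for (p in c("n_cells", "percent_positive", "intensity", "hif_score",
              "h_score"))
    rec[[p]] <- NA_real_
  rec$hif_label <- NA_character_
  if (!is.null(cells) && nrow(cells)) {
    x <- cells$x_mm; y <- cells$y_mm
    if (!is.null(transform)) {
      th <- transform$theta %||% 0
      xn <- cos(th) * x - sin(th) * y + (transform$tx %||% 0)
      y <- sin(th) * x + cos(th) * y + (transform$ty %||% 0)
      x <- xn
    }
    cell_roi <- sprintf("r%02d_%02d", floor(x / cfg$roi_side_mm),
                        floor(y / cfg$roi_side_mm))
    for (r in which(rec$analyzed)) {
      sc <- score_roi(cells[cell_roi == rec$roi_id[r], , drop = FALSE],
                      cut = cfg$hif_cut)
      rec$n_cells[r] <- sc$n_cells
      if (isTRUE(sc$valid)) {
        rec$percent_positive[r] <- sc$percent_positive
        rec$intensity[r] <- sc$intensity
        rec$hif_score[r] <- sc$score
        rec$h_score[r] <- sc$h_score
        rec$hif_label[r] <- sc$label
      }
    }
    no_cells <- rec$analyzed & rec$n_cells == 0
    rec$included[no_cells] <- FALSE
    rec$reason[no_cells] <- "no-cells"
    rec$analyzed[no_cells] <- FALSE
  }
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a
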