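#' Mann-Whitney U test
#'
#' Rank-sum test for a location difference between two independent
#' samples. The statistic is \eqn{U = \#\{(i, j): x_i > y_j\} + \frac12
#' \#\{x_i = y_j\}}. The two-sided p-value is computed by exhaustive
#' enumeration of all group-label assignments when
#' \eqn{\binom{n_1 + n_2}{n_1} \le 2 \times 10^5} (exact even under
#' ties), and otherwise by the normal approximation with tie-corrected
#' variance and a continuity correction.
#'
#' @param x,y Numeric samples (non-empty).
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return A list of class `mw_test`: `U`, `p`, `n1`, `n2`, `method`,
#'   and `degenerate` (TRUE when all pooled values are identical, where
#'   p = 1).
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p  # exact two-sided 0.1
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty")
  pooled <- c(x, y)
  rk <- rank(pooled)
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  degenerate <- length(unique(pooled)) == 1L
  if (degenerate)
    return(structure(list(U = U, p = 1, n1 = n1, n2 = n2,
                          method = "degenerate", degenerate = TRUE),
                     class = "mw_test"))
  n <- n1 + n2
  has_ties <- anyDuplicated(pooled) > 0
  use_enum <- (mode == "exact" && choose(n, n1) <= 2e5) ||
    (mode == "auto" && choose(n, n1) <= 2e5)
  if (use_enum) {
    splits <- utils::combn(n, n1)
    base <- n1 * (n1 + 1) / 2
    Us <- colSums(matrix(rk[splits], nrow = n1)) - base
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else if (mode == "exact") {
    # Enumeration infeasible: the exact null distribution of U is still
    # available in closed form for tie-free data.
    if (has_ties)
      stop("exact p with ties requires a feasible enumeration; use mode = 'auto'")
    pl <- stats::pwilcox(U, n1, n2)
    pu <- 1 - stats::pwilcox(U - 1, n1, n2)
    p <- min(1, 2 * min(pl, pu))
    method <- "exact"
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sg <- sqrt(n1 * n2 / 12 * (n + 1 - tie_term))
    z <- (abs(U - mu) - 0.5) / sg
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal-approximation"
  }
  structure(list(U = U, p = p, n1 = n1, n2 = n2, method = method,
                 degenerate = FALSE), class = "mw_test")
}

.t_pvalue <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}

#' Spearman rank correlation
#'
#' Mid-ranks are assigned to ties and the coefficient is the Pearson
#' product-moment correlation of the ranks; the p-value uses the
#' t-approximation with n - 2 degrees of freedom.
#'
#' @param x,y Paired numeric vectors (n >= 3 complete pairs).
#' @return A list: `rho`, `p`, `n`, `valid` (FALSE when a rank vector
#'   has zero variance, leaving the coefficient undefined).
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, valid = FALSE))
  rho <- stats::cor(rx, ry)
  list(rho = rho, p = .t_pvalue(rho, n), n = n, valid = TRUE)
}

#' Pearson correlation
#'
#' Standard product-moment coefficient with a t-approximation p-value.
#'
#' @inheritParams spearman_cor
#' @return A list: `r`, `p`, `n`, `valid`.
#' @export
pearson_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, valid = FALSE))
  r <- stats::cor(x, y)
  list(r = r, p = .t_pvalue(r, n), n = n, valid = TRUE)
}

#' Simple linear regression
#'
#' Ordinary least squares of y on x via [stats::lm()].
#'
#' @inheritParams spearman_cor
#' @return A list: `slope`, `intercept`, `r_squared`, `p` (slope test),
#'   `n`.
#' @export
linear_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0) stop("x has zero variance")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p = unname(sm$coefficients[2, 4]),
       n = length(x))
}

# Display scaling: diffusivities in 1e-6 mm^2/s, f in percent.
.report_params <- c("R2star", "D", "Dstar", "f", "perfusion", "hif_score")
.report_scale <- c(R2star = 1, D = 1e6, Dstar = 1e6, f = 100,
                   perfusion = 1e6, hif_score = 1)
.report_units <- c(R2star = "Hz", D = "1e-6 mm^2/s", Dstar = "1e-6 mm^2/s",
                   f = "%", perfusion = "1e-6 mm^2/s", hif_score = "score")

.cmp_block <- function(data, group, g1, g2, params, alpha = 0.05) {
  rows <- lapply(params, function(p) {
    v1 <- data[[p]][data[[group]] == g1] * .report_scale[[p]]
    v2 <- data[[p]][data[[group]] == g2] * .report_scale[[p]]
    v1 <- v1[is.finite(v1)]; v2 <- v2[is.finite(v2)]
    if (length(v1) < 2 || length(v2) < 2) return(NULL)
    mw <- mann_whitney_u(v1, v2)
    data.frame(parameter = p, units = .report_units[[p]],
               group1 = g1, group2 = g2,
               n1 = length(v1), n2 = length(v2),
               mean1 = mean(v1), sd1 = stats::sd(v1),
               mean2 = mean(v2), sd2 = stats::sd(v2),
               U = mw$U, p = mw$p, method = mw$method)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) return(NULL)
  rows$p_holm <- stats::p.adjust(rows$p, method = "holm")
  rows$significant <- rows$p < alpha
  rows
}

#' Build the statistics report from an ROI table
#'
#' Assembles the full comparison and correlation report from a pooled
#' per-ROI record table: (1) tumor vs normal comparison of R2*, D, D*,
#' f, perfusion and HIF score; (2) central vs peripheral comparison
#' within the tumor; (3) high vs low HIF expression comparison of the
#' imaging parameters within the tumor; (4) Spearman and Pearson
#' correlation plus simple linear regression of each imaging parameter
#' against the HIF score across tumor ROIs. Group comparisons use the
#' Mann-Whitney U test; means and SDs are reported alongside even though
#' the tests are rank-based. Spearman is the headline correlation;
#' Pearson is reported next to it. A Holm-adjusted column is emitted for
#' reference but the significance flag uses the unadjusted p at
#' `alpha`, mirroring single-test reporting. Diffusivities are displayed
#' in 1e-6 mm^2/s and f in percent.
#'
#' @param roi_table Pooled ROI record table (from [aggregate_roi()] /
#'   [run_study()]), using only rows with `analyzed = TRUE`.
#' @param alpha Significance level.
#' @return An object of class `hif_report`.
#' @export
build_report <- function(roi_table, alpha = 0.05) {
  d <- roi_table[roi_table$analyzed %in% TRUE, , drop = FALSE]
  if (nrow(d) < 4) stop("too few analyzed ROIs to build a report")
  imaging <- setdiff(.report_params, "hif_score")
  tum <- d[d$tissue == "tumor", , drop = FALSE]

  blocks <- list(
    tumor_vs_normal = .cmp_block(d, "tissue", "tumor", "normal",
                                 .report_params, alpha),
    central_vs_peripheral = .cmp_block(tum, "region", "central",
                                       "peripheral", .report_params, alpha),
    high_vs_low_hif = .cmp_block(tum, "hif_label", "high", "low",
                                 imaging, alpha)
  )
  skipped <- names(blocks)[vapply(blocks, is.null, logical(1))]
  for (s in skipped)
    warning("comparison block skipped (empty group): ", s, call. = FALSE)

  cors <- do.call(rbind, lapply(imaging, function(p) {
    xx <- tum[[p]] * .report_scale[[p]]
    yy <- tum$hif_score
    ok <- is.finite(xx) & is.finite(yy)
    if (sum(ok) < 3) return(NULL)
    sp <- spearman_cor(xx[ok], yy[ok])
    pe <- pearson_cor(xx[ok], yy[ok])
    lf <- linear_fit(xx[ok], yy[ok])
    data.frame(parameter = p, units = .report_units[[p]], n = sp$n,
               spearman_rho = sp$rho, spearman_p = sp$p,
               pearson_r = pe$r, pearson_p = pe$p,
               slope = lf$slope, intercept = lf$intercept,
               r_squared = lf$r_squared,
               significant = is.finite(sp$p) && sp$p < alpha)
  }))

  counts <- list(
    analyzed = nrow(d),
    tumor = sum(d$tissue == "tumor"),
    normal = sum(d$tissue == "normal"),
    central = sum(tum$region == "central"),
    peripheral = sum(tum$region == "peripheral"),
    high_hif = sum(tum$hif_label == "high", na.rm = TRUE),
    low_hif = sum(tum$hif_label == "low", na.rm = TRUE)
  )
  structure(list(comparisons = blocks, correlations = cors,
                 counts = counts, alpha = alpha,
                 notes = paste("Spearman is the headline correlation;",
                               "Pearson is reported alongside for",
                               "comparability.")),
            class = "hif_report")
}

#' @export
print.hif_report <- function(x, ...) {
  cat("<hif_report>\n")
  cat(sprintf("  analyzed ROIs: %d (%d tumor [%d central / %d peripheral / %d high-HIF / %d low-HIF], %d normal)\n",
              x$counts$analyzed, x$counts$tumor, x$counts$central,
              x$counts$peripheral, x$counts$high_hif, x$counts$low_hif,
              x$counts$normal))
  for (nm in names(x$comparisons)) {
    b <- x$comparisons[[nm]]
    if (is.null(b)) next
    cat("\n--", nm, "--\n")
    print(data.frame(parameter = b$parameter,
                     g1 = sprintf("%.2f +/- %.2f (n=%d)", b$mean1, b$sd1, b$n1),
                     g2 = sprintf("%.2f +/- %.2f (n=%d)", b$mean2, b$sd2, b$n2),
                     p = signif(b$p, 3), sig = b$significant),
          row.names = FALSE)
  }
  if (!is.null(x$correlations)) {
    cat("\n-- correlations with HIF score (tumor ROIs) --\n")
    cc <- x$correlations
    print(data.frame(parameter = cc$parameter,
                     rho = round(cc$spearman_rho, 3),
                     p = signif(cc$spearman_p, 3),
                     pearson_r = round(cc$pearson_r, 3),
                     slope = signif(cc$slope, 3),
                     R2 = round(cc$r_squared, 3)),
          row.names = FALSE)
  }
  invisible(x)
}

#' Render a report as Markdown tables
#'
#' @param report An `hif_report`.
#' @return A character vector of Markdown lines.
#' @export
report_to_markdown <- function(report) {
  md <- c("# Statistics report", "",
          sprintf("Analyzed ROIs: %d (%d tumor, %d normal)",
                  report$counts$analyzed, report$counts$tumor,
                  report$counts$normal), "")
  fmt_block <- function(b, title) {
    if (is.null(b)) return(character(0))
    c(sprintf("## %s", title), "",
      sprintf("| Parameter | %s (mean +/- SD) | %s (mean +/- SD) | U | p |",
              b$group1[1], b$group2[1]),
      "|---|---|---|---|---|",
      sprintf("| %s (%s) | %.2f +/- %.2f (n=%d) | %.2f +/- %.2f (n=%d) | %.1f | %.4g%s |",
              b$parameter, b$units, b$mean1, b$sd1, b$n1, b$mean2, b$sd2,
              b$n2, b$U, b$p, ifelse(b$significant, " *", "")),
      "")
  }
  md <- c(md,
          fmt_block(report$comparisons$tumor_vs_normal,
                    "Tumor vs normal brain"),
          fmt_block(report$comparisons$central_vs_peripheral,
                    "Central vs peripheral tumor"),
          fmt_block(report$comparisons$high_vs_low_hif,
                    "High vs low HIF expression"))
  cc <- report$correlations
  if (!is.null(cc)) {
    md <- c(md, "## Correlations with the HIF score (tumor ROIs)", "",
            "| Parameter | n | Spearman rho | p | Pearson r | slope | R^2 |",
            "|---|---|---|---|---|---|---|",
            sprintf("| %s (%s) | %d | %.3f | %.4g | %.3f | %.4g | %.3f |",
                    cc$parameter, cc$units, cc$n, cc$spearman_rho,
                    cc$spearman_p, cc$pearson_r, cc$slope, cc$r_squared),
            "")
  }
  md
}
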