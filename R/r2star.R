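#' Multi-echo gradient-echo signal model
#'
#' Mono-exponential transverse decay \eqn{S(TE) = S_0 e^{-TE \cdot R2^*}}
#' with TE in seconds and R2* in Hz (R2* is the reciprocal of T2*).
#'
#' @param te_s Echo time(s) in seconds, >= 0.
#' @param S0 Signal at TE = 0.
#' @param R2star Effective transverse relaxation rate in Hz, >= 0.
#' @return Signal at the given echo times.
#' @export
#' @examples
#' mege_signal(27.1e-3, S0 = 1, R2star = 36.74)
mege_signal <- function(te_s, S0, R2star) {
  if (any(te_s < 0)) stop("TE must be >= 0")
  if (any(R2star < 0)) stop("R2star must be >= 0")
  S0 * exp(-te_s * R2star)
}

#' R2* fitting configuration
#'
#' @param method `"nls"` (weighted log-linear start refined by bounded
#'   nonlinear least squares, the default) or `"loglin"` (weighted
#'   log-linear only).
#' @param R2_bounds Bounds for R2* in Hz; the lower bound keeps T2*
#'   finite.
#' @param sigma Optional background noise SD (signal units). Echoes with
#'   signal below `2 * sigma` are excluded per voxel before fitting, a
#'   guard against the Rician noise floor.
#' @param min_echoes Minimum usable echoes per voxel; below it the voxel
#'   is flagged.
#' @param max_iter Iteration cap for the nonlinear refinement.
#' @return A list of class `r2star_fit_config`.
#' @export
r2star_fit_config <- function(method = c("nls", "loglin"),
                              R2_bounds = c(0.1, 2000),
                              sigma = NULL, min_echoes = 3L,
                              max_iter = 100L) {
  structure(list(method = match.arg(method), R2_bounds = R2_bounds,
                 sigma = sigma, min_echoes = as.integer(min_echoes),
                 max_iter = as.integer(max_iter)),
            class = "r2star_fit_config")
}

#' Voxelwise R2* estimation
#'
#' Fits the mono-exponential decay to a multi-echo magnitude series.
#' The default pipeline is a log-linear regression of ln S on TE with
#' weights proportional to the squared (fitted) signal - the first-order
#' variance-stabilizing weights for log-transformed data, iterated twice
#' so the weights do not correlate with the noise - refined by bounded
#' Levenberg-Marquardt least squares on the signal scale. Per voxel,
#' non-positive echoes (and echoes below twice the supplied background
#' sigma) are dropped, and when `sigma` is known the retained magnitudes
#' are debiased with the second-moment Rician identity
#' \eqn{s = \sqrt{M^2 - 2\sigma^2}} before fitting. Voxels with fewer
#' than `min_echoes` usable echoes are flagged and excluded rather than
#' imputed.
#'
#' @param signal Numeric matrix (voxels x echoes) or vector (one voxel).
#' @param echo_times_s Echo times in seconds matching the columns.
#' @param cfg An [r2star_fit_config()].
#' @return A data.frame with one row per voxel: `R2star` (Hz), `T2star`
#'   (s, = 1/R2*), `S0`, `rss`, `n_echoes`, `converged`. Voxels clamped
#'   at the R2* lower bound (e.g. a constant series) are flagged
#'   `converged = FALSE`.
#' @export
fit_r2star <- function(signal, echo_times_s, cfg = r2star_fit_config()) {
  if (is.vector(signal)) signal <- matrix(signal, nrow = 1)
  if (ncol(signal) != length(echo_times_s))
    stop("signal columns must match the number of echoes")
  if (length(echo_times_s) < 3)
    stop("need >= 3 echoes")
  n <- nrow(signal)
  out <- data.frame(R2star = rep(NA_real_, n), T2star = NA_real_,
                    S0 = NA_real_, rss = NA_real_, n_echoes = 0L,
                    converged = FALSE)
  floor_lvl <- if (!is.null(cfg$sigma)) 2 * cfg$sigma else 0
  lo <- cfg$R2_bounds[1]; hi <- cfg$R2_bounds[2]
  for (v in seq_len(n)) {
    s <- signal[v, ]
    use <- is.finite(s) & s > 0 & s > floor_lvl
    if (sum(use) < cfg$min_echoes) next
    te <- echo_times_s[use]; su <- s[use]
    # second-moment Rician debias (E[M^2] = s^2 + 2 sigma^2) when the
    # noise level is known
    if (!is.null(cfg$sigma) && cfg$sigma > 0)
      su <- sqrt(pmax(su^2 - 2 * cfg$sigma^2, 1e-12))
    ly <- log(su)
    w <- su^2
    # weighted log-linear fit, with two reweighting passes using fitted
    # signals so the weights are not correlated with the noise
    for (pass in 0:2) {
      wm_t <- sum(w * te) / sum(w)
      wm_y <- sum(w * ly) / sum(w)
      sxx <- sum(w * (te - wm_t)^2)
      slope <- sum(w * (te - wm_t) * (ly - wm_y)) / sxx
      r2 <- -slope
      s0 <- exp(wm_y + r2 * wm_t)
      w <- (s0 * exp(-te * pmax(r2, 0)))^2
    }
    at_bound <- r2 < lo || r2 > hi
    r2 <- clamp(r2, lo, hi)
    conv <- !at_bound
    if (cfg$method == "nls") {
      fit <- try(minpack.lm::nls.lm(
        par = c(s0, r2), lower = c(0, lo), upper = c(Inf, hi),
        fn = function(p, te, s) s - p[1] * exp(-te * p[2]),
        te = te, s = su,
        control = minpack.lm::nls.lm.control(maxiter = cfg$max_iter)),
        silent = TRUE)
      if (!inherits(fit, "try-error")) {
        s0 <- fit$par[1]; r2 <- fit$par[2]
        at_bound <- r2 <= lo * (1 + 1e-9) || r2 >= hi * (1 - 1e-9)
        conv <- fit$info %in% 1:4 && !at_bound
      }
    }
    out$R2star[v] <- r2
    out$T2star[v] <- 1 / r2
    out$S0[v] <- s0
    out$rss[v] <- sum((su - s0 * exp(-te * r2))^2)
    out$n_echoes[v] <- sum(use)
    out$converged[v] <- conv
  }
  out
}
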