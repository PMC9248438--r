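# Shared fixtures: a reduced phantom geometry that keeps every stage fast
# while preserving the anatomy (brain ellipsoid, lateralized tumor).

small_config <- function(seed = 1L, ...) {
  args <- list(shape = c(48L, 48L, 10L), voxel_mm = c(0.5, 0.5, 1),
               brain_semiaxes_mm = c(10, 11, 4.5),
               tumor_center_offset_mm = c(-3, 1, 0),
               tumor_volume_mm3 = 120, seed = seed)
  do.call(phantom_config, utils::modifyList(args, list(...)))
}

# Table-scale tumor reference parameters used across fitting tests.
tumor_pars <- list(D = 419.50e-6, Dstar = 2850.23e-6, f = 0.5109)

protocol_b <- acq_protocol()$bvalues
protocol_te <- acq_protocol()$echo_times_s

# A truth_maps object with constant fields, for direct signal checks.
flat_truth <- function(D = tumor_pars$D, Dstar = tumor_pars$Dstar,
                       f = tumor_pars$f, R2star = 38.24, HIF = 150,
                       S0 = 1000, dim = c(6L, 6L, 2L)) {
  structure(list(D = array(D, dim), Dstar = array(Dstar, dim),
                 f = array(f, dim), R2star = array(R2star, dim),
                 HIF = array(HIF, dim), S0 = array(S0, dim),
                 voxel_mm = c(0.5, 0.5, 1),
                 meta = list(seed = 1L, s0_ref = S0,
                             tumor_center_mm = c(1.5, 1.5, 1))),
            class = "truth_maps")
}

# Independent enumeration oracle for the exact Mann-Whitney p-value:
# brute-force U over every assignment of the pooled values to groups.
mw_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  u_of <- function(xx, yy) sum(outer(xx, yy, ">")) +
    0.5 * sum(outer(xx, yy, "=="))
  mu <- n1 * (n - n1) / 2
  splits <- utils::combn(n, n1)
  us <- apply(splits, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(u_of(x, y) - mu) - 1e-9)
}
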