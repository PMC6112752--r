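# Shared fixtures and independent numerical oracles.
#
# trap_theta is a fixed-grid trapezoid quadrature written directly from the
# kernel formulas (release density g scaled by 1/T_D, activation completion
# f); it shares no code with the package's adaptive path and serves as the
# independent cross-check. The improper last-window integral is truncated
# at T_N + 20 * T_D, where the remaining release mass is (1/2)^400.

ref_params <- rt_params(alpha = 0.15, alpha_beta = 4)
ref_kinetics <- immune_kinetics(t_d = 3, t_ir = 7)

trap_theta <- function(times, i, j, t_d, t_ir, npts = 1e5) {
  n <- length(times)
  lo <- times[j]
  hi <- if (j < n) times[j + 1] else times[n] + 20 * t_d
  t <- seq(lo, hi, length.out = npts)
  u <- (t - times[i]) / t_d
  gx <- ifelse(u < 0, 0, 2 * log(2) * u * 0.5^(u^2)) / t_d
  fx <- if (j < n) {
    v <- (times[j + 1] - t) / t_ir
    ifelse(v < 0, 0, 1 - 0.5^(v^2))
  } else 1
  y <- gx * fx
  (hi - lo) / (npts - 1) * (sum(y) - (y[1] + y[npts]) / 2)
}

# total kill fraction of a schedule, by direct product of LQ survivals
total_kill <- function(sched, params) {
  1 - prod(exp(-params$alpha * sched$dose_gy - params$beta * sched$dose_gy^2))
}

# randomized schedule: N in 2..n_max events, gaps and doses drawn uniformly
random_schedule <- function(n_max = 10, gap_range = c(0.1, 30),
                            dose_range = c(1, 8)) {
  n <- sample(2:n_max, 1)
  times <- cumsum(c(0, stats::runif(n - 1, gap_range[1], gap_range[2])))
  schedule(times, stats::runif(n, dose_range[1], dose_range[2]))
}
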