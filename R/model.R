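#' Antigen-release and immune-activation kernels
#'
#' The model's two kinetic curves in dimensionless time x (an elapsed time
#' divided by T_D or T_IR). `release_cdf` is the cumulative fraction
#' \eqn{f(x) = 1 - (1/2)^{x^2}}: it rises from 0, reaches 1/2 at x = 1 (the
#' "half after T_D / T_IR" semantics) and tends to 1. `release_pdf` is its
#' derivative \eqn{g(x) = 2 \ln 2 \, x \, (1/2)^{x^2}}, the release rate per
#' unit dimensionless time. Both are 0 for x < 0.
#'
#' f describes the completion of immune activation after an antigen release
#' at x = 0; g describes the rate of antigen release after an irradiation at
#' x = 0. Any similarly shaped pair could be substituted without changing
#' the structure of the model.
#'
#' @param x Dimensionless time(s); vectorized.
#' @return Numeric vector: fractions in [0, 1] for `release_cdf`,
#'   non-negative densities for `release_pdf`.
#' @examples
#' release_cdf(1)   # 0.5
#' release_pdf(1)   # log(2)
#' @export
release_cdf <- function(x) {
  out <- 1 - 0.5^(x * x)
  out[x < 0] <- 0
  out
}

#' @rdname release_cdf
#' @export
release_pdf <- function(x) {
  out <- 2 * log(2) * x * 0.5^(x * x)
  out[x < 0] <- 0
  out
}

#' Fraction of cells killed by a dose under the LQ model
#'
#' \eqn{k_D = 1 - e^{-\alpha D - \beta D^2}}.
#'
#' @param dose Dose(s) in Gy, >= 0; vectorized.
#' @param params An [rt_params] object.
#' @return Kill fraction(s) in [0, 1).
#' @examples
#' kill_fraction(8, rt_params(0.15, 4))   # 1 - exp(-3.6)
#' @export
kill_fraction <- function(dose, params = rt_params()) {
  stopifnot(inherits(params, "rt_params"))
  if (!is.numeric(dose) || any(!is.finite(dose)) || any(dose < 0))
    stop("`dose` must be finite and non-negative (Gy)", call. = FALSE)
  -expm1(-params$alpha * dose - params$beta * dose^2)
}

#' Survival weights of a schedule
#'
#' The diagonal of the survival matrix S: element i is the fraction of the
#' initial tumour cell population still alive just before the i-th fraction,
#' \eqn{S_{ii} = \prod_{m<i} (1 - k_{d_m})}. For equal doses this is
#' \eqn{(1-k_D)^{i-1}}.
#'
#' @param x An `rt_schedule`.
#' @param params An [rt_params] object.
#' @return Numeric vector of length N; first element 1.
#' @export
survival_weights <- function(x, params = rt_params()) {
  x <- as_schedule(x)
  k <- kill_fraction(x$dose_gy, params)
  cumprod(c(1, 1 - k[-length(k)]))
}

# integrand of theta_ij in absolute time t: antigen-release density of the
# i-th kill cohort (unit mass in t thanks to the 1/T_D factor) times the
# immune-activation completion reached by the next fraction at T_{j+1}
theta_integrand <- function(t, t_i, t_next, kinetics) {
  release_pdf((t - t_i) / kinetics$t_d) / kinetics$t_d *
    release_cdf((t_next - t) / kinetics$t_ir)
}

#' One entry of the timing matrix
#'
#' \eqn{\theta_{ij}} is the fraction of the antigens from cells killed by
#' fraction i that are released during the window between fractions j and
#' j+1 *and* whose induced immune activation completes before fraction j+1
#' wipes the tumour micro-environment. For \eqn{i \le j < N} it is the
#' integral over \eqn{[T_j, T_{j+1}]} of
#' \eqn{g((t-T_i)/T_D)/T_D \cdot f((T_{j+1}-t)/T_{IR})}; the 1/T_D factor
#' makes the release term a unit probability density in t. For j = N the
#' window is open-ended, f of the improper bound is 1, and the entry has the
#' closed form \eqn{1 - f((T_N - T_i)/T_D)}. Entries with j < i are 0.
#'
#' @param i Index of the killing fraction (1..N).
#' @param j Index of the release window (1..N).
#' @param x An `rt_schedule`.
#' @param kinetics An [immune_kinetics] object.
#' @return A fraction in [0, 1].
#' @export
theta_entry <- function(i, j, x, kinetics = immune_kinetics()) {
  x <- as_schedule(x)
  n <- nrow(x)
  if (i < 1 || i > n || j < 1 || j > n || i != round(i) || j != round(j))
    stop(sprintf("theta indices must be whole numbers in 1..%d", n),
         call. = FALSE)
  if (j < i) return(0)
  tt <- x$time_days
  if (j == n) return(1 - release_cdf((tt[n] - tt[i]) / kinetics$t_d))
  lo <- tt[j]; hi <- tt[j + 1L]
  # split at the release-density mode so adaptive quadrature cannot step
  # over a spike that is narrow relative to a long window
  mode <- tt[i] + kinetics$t_d / sqrt(2 * log(2))
  cuts <- sort(unique(c(lo, hi, if (mode > lo && mode < hi) mode)))
  val <- 0
  for (s in seq_len(length(cuts) - 1L)) {
    val <- val + stats::integrate(theta_integrand, cuts[s], cuts[s + 1L],
                                  t_i = tt[i], t_next = hi, kinetics = kinetics,
                                  abs.tol = 1e-10, rel.tol = 1e-10,
                                  subdivisions = 200L)$value
  }
  val
}

#' The timing matrix of a schedule
#'
#' The upper-triangular N x N matrix of [theta_entry()] values. It depends
#' only on the timing of the fractions and on (T_D, T_IR), never on the
#' doses, and is invariant under a uniform shift of all event times. Row i
#' sums to the fraction of fraction-i antigens that ever reach a completed
#' immune activation; each row sum is at most 1.
#'
#' @inheritParams theta_entry
#' @return An N x N numeric matrix.
#' @examples
#' theta_matrix(schedule_uniform(3, 8), immune_kinetics(3, 7))
#' @export
theta_matrix <- function(x, kinetics = immune_kinetics()) {
  x <- as_schedule(x)
  n <- nrow(x)
  th <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in i:n)
      th[i, j] <- theta_entry(i, j, x, kinetics)
  th
}

#' Per-fraction immunogenic contributions
#'
#' The vector E = S Theta K: component i is the fraction of the initial
#' tumour volume killed by fraction i whose antigens end up driving a
#' completed immune activation,
#' \eqn{E_i = S_{ii} \, (\sum_j \theta_{ij}) \, k_{d_i}}. K generalizes to
#' per-fraction kill fractions for unequal doses; for equal doses this
#' reduces to the constant-k form. The geometric decrease of S makes the
#' earliest fractions the dominant contributors.
#'
#' @param x An `rt_schedule`.
#' @param params An [rt_params] object.
#' @param kinetics An [immune_kinetics] object.
#' @param dose_transform Optional function applied to the dose vector before
#'   the kill fractions are computed (hook for ad-hoc high-dose adjustments;
#'   none is shipped). `NULL` (default) leaves doses unchanged.
#' @return Numeric vector E of length N; all entries >= 0 and their sum < 1.
#' @export
immunogenic_contributions <- function(x, params = rt_params(),
                                      kinetics = immune_kinetics(),
                                      dose_transform = NULL) {
  x <- as_schedule(x)
  doses <- x$dose_gy
  if (!is.null(dose_transform)) {
    stopifnot(is.function(dose_transform))
    doses <- dose_transform(doses)
  }
  k <- kill_fraction(doses, params)
  s <- cumprod(c(1, 1 - k[-length(k)]))
  th <- theta_matrix(x, kinetics)
  as.numeric(s * rowSums(th) * k)
}

#' IED efficacy of a schedule
#'
#' The sum of the components of E: the fraction of the initial tumour volume
#' converted into immunogenic antigens. 1 means the whole tumour volume
#' contributed to the immune response, 0 means none did.
#'
#' @inheritParams immunogenic_contributions
#' @return A fraction in [0, 1).
#' @examples
#' ied_efficacy(schedule_uniform(3, 8))   # about 0.74
#' ied_efficacy(schedule_uniform(5, 6))   # about 0.32
#' @export
ied_efficacy <- function(x, params = rt_params(), kinetics = immune_kinetics(),
                         dose_transform = NULL) {
  sum(immunogenic_contributions(x, params, kinetics, dose_transform))
}

#' Immunologically effective dose
#'
#' The single dose, delivered at infinitely low dose rate (so only the
#' linear term of the LQ model kills), that would convert the same fraction
#' of the tumour volume into immunogenic antigens as the schedule:
#' \eqn{IED = -\ln(1 - \Sigma E)/\alpha}. For a single instantaneous dose D
#' the efficacy equals the kill fraction, giving the closed form
#' \eqn{IED = D + (\beta/\alpha) D^2}.
#'
#' @inheritParams immunogenic_contributions
#' @return Dose in Gy.
#' @examples
#' ied(schedule(0, 8))   # 8 + 0.25 * 64 = 24 Gy
#' @export
ied <- function(x, params = rt_params(), kinetics = immune_kinetics(),
                dose_transform = NULL) {
  eff <- ied_efficacy(x, params, kinetics, dose_transform)
  efficacy_to_ied(eff, params)
}

# back-solve 1 - exp(-alpha * IED) = eff, clamped below 1 to stay in the
# log domain (finite schedules cannot reach 1 exactly)
efficacy_to_ied <- function(eff, params) {
  if (eff >= 1) {
    if (eff > 1 + 1e-9)
      stop("efficacy >= 1: no finite IED exists", call. = FALSE)
    eff <- 1 - 1e-15
  }
  -log1p(-eff) / params$alpha
}

#' Biologically effective dose of a schedule
#'
#' The classic time-free LQ metric \eqn{\sum_i d_i (1 + d_i/(\alpha/\beta))};
#' no repopulation factor is applied.
#'
#' @param x An `rt_schedule`.
#' @param params An [rt_params] object (only `alpha_beta` is used).
#' @return Dose in Gy.
#' @examples
#' bed(schedule_uniform(3, 8), rt_params(0.15, 4))   # 72
#' @export
bed <- function(x, params = rt_params()) {
  x <- as_schedule(x)
  stopifnot(inherits(params, "rt_params"))
  sum(x$dose_gy * (1 + x$dose_gy / params$alpha_beta))
}

#' Equivalent dose in 2 Gy fractions
#'
#' The total dose that would produce the same LQ cell kill if delivered in
#' 2 Gy fractions: \eqn{BED / (1 + 2/(\alpha/\beta))}.
#'
#' @inheritParams bed
#' @return Dose in Gy.
#' @examples
#' eqd2(schedule_uniform(5, 6), rt_params(0.15, 4))   # 50
#' @export
eqd2 <- function(x, params = rt_params()) {
  bed(x, params) / (1 + 2 / params$alpha_beta)
}

#' Evaluate all schedule metrics at once
#'
#' Computes BED, EQD2, the per-fraction immunogenic contributions E, the IED
#' efficacy (sum of E), and the IED, bundled in one result object.
#'
#' @inheritParams immunogenic_contributions
#' @param include_theta Keep the Theta matrix in the result (default TRUE).
#' @return An object of class `ied_result` with fields `efficacy`, `ied_gy`,
#'   `bed_gy`, `eqd2_gy`, `contributions`, `theta` (or NULL), `schedule`,
#'   `params`, `kinetics`.
#' @examples
#' ied_evaluate(schedule_uniform(3, 8))
#' @export
ied_evaluate <- function(x, params = rt_params(), kinetics = immune_kinetics(),
                         dose_transform = NULL, include_theta = TRUE) {
  x <- as_schedule(x)
  th <- if (include_theta) theta_matrix(x, kinetics) else NULL
  doses <- x$dose_gy
  if (!is.null(dose_transform)) doses <- dose_transform(doses)
  k <- kill_fraction(doses, params)
  s <- cumprod(c(1, 1 - k[-length(k)]))
  contrib <- if (is.null(th))
    immunogenic_contributions(x, params, kinetics, dose_transform)
  else as.numeric(s * rowSums(th) * k)
  eff <- sum(contrib)
  structure(
    list(efficacy = eff,
         ied_gy = efficacy_to_ied(eff, params),
         bed_gy = bed(x, params),
         eqd2_gy = eqd2(x, params),
         contributions = contrib,
         theta = th,
         schedule = x, params = params, kinetics = kinetics),
    class = "ied_result"
  )
}

#' @export
print.ied_result <- function(x, ...) {
  n <- nrow(x$schedule)
  cat(sprintf("IED evaluation of a %d-fraction schedule (%g Gy total, span %g d)\n",
              n, sum(x$schedule$dose_gy),
              max(x$schedule$time_days) - min(x$schedule$time_days)))
  cat(sprintf("  alpha = %g Gy^-1, alpha/beta = %g Gy, T_D = %g d, T_IR = %g d\n",
              x$params$alpha, x$params$alpha_beta,
              x$kinetics$t_d, x$kinetics$t_ir))
  cat(sprintf("  BED          %8.2f Gy\n", x$bed_gy))
  cat(sprintf("  EQD2         %8.2f Gy\n", x$eqd2_gy))
  cat(sprintf("  IED          %8.2f Gy\n", x$ied_gy))
  cat(sprintf("  IED efficacy %7.0f%%  (%.4f)\n",
              round(100 * x$efficacy), x$efficacy))
  invisible(x)
}
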