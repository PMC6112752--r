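#' Radiosensitivity parameters of the linear-quadratic model
#'
#' Bundles the linear coefficient \eqn{\alpha} (Gy^-1) and the ratio
#' \eqn{\alpha/\beta} (Gy) of the linear-quadratic (LQ) cell-survival model;
#' the quadratic coefficient \eqn{\beta} (Gy^-2) is derived as
#' \eqn{\alpha / (\alpha/\beta)}. The defaults are the worked-example values
#' used throughout the package: \eqn{\alpha = 0.15} Gy^-1,
#' \eqn{\alpha/\beta = 4} Gy.
#'
#' @param alpha LQ linear coefficient, in Gy^-1. Must be > 0.
#' @param alpha_beta The alpha/beta ratio, in Gy. Must be > 0.
#'
#' @return An object of class `rt_params` with fields `alpha`, `alpha_beta`
#'   and the derived `beta`.
#' @examples
#' rt_params()                 # alpha = 0.15, alpha/beta = 4
#' rt_params(0.35, 10)
#' @export
rt_params <- function(alpha = 0.15, alpha_beta = 4) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("`alpha` must be a single positive number (Gy^-1)", call. = FALSE)
  if (!is.numeric(alpha_beta) || length(alpha_beta) != 1L ||
      !is.finite(alpha_beta) || alpha_beta <= 0)
    stop("`alpha_beta` must be a single positive number (Gy)", call. = FALSE)
  structure(
    list(alpha = as.numeric(alpha), alpha_beta = as.numeric(alpha_beta),
         beta = as.numeric(alpha) / as.numeric(alpha_beta)),
    class = "rt_params"
  )
}

#' @export
print.rt_params <- function(x, ...) {
  cat(sprintf("LQ radiosensitivity: alpha = %g Gy^-1, alpha/beta = %g Gy (beta = %g Gy^-2)\n",
              x$alpha, x$alpha_beta, x$beta))
  invisible(x)
}

#' Immune-kinetics parameters of the IED model
#'
#' The two time scales of the immunogenicity kinetics: `t_d`, the time to
#' death (days), after which half of the tumour antigens of a killed cell
#' cohort have been released; and `t_ir`, the time to immune response (days),
#' after which the immune activation triggered by released antigens is half
#' complete. Defaults are T_D = 3 days and T_IR = 7 days.
#'
#' @param t_d Time to death, days. Must be > 0.
#' @param t_ir Time to immune response, days. Must be > 0.
#'
#' @return An object of class `immune_kinetics` with fields `t_d`, `t_ir`.
#' @examples
#' immune_kinetics()          # T_D = 3 d, T_IR = 7 d
#' immune_kinetics(t_d = 5, t_ir = 10)
#' @export
immune_kinetics <- function(t_d = 3, t_ir = 7) {
  if (!is.numeric(t_d) || length(t_d) != 1L || !is.finite(t_d) || t_d <= 0)
    stop("`t_d` must be a single positive number of days", call. = FALSE)
  if (!is.numeric(t_ir) || length(t_ir) != 1L || !is.finite(t_ir) || t_ir <= 0)
    stop("`t_ir` must be a single positive number of days", call. = FALSE)
  structure(list(t_d = as.numeric(t_d), t_ir = as.numeric(t_ir)),
            class = "immune_kinetics")
}

#' @export
print.immune_kinetics <- function(x, ...) {
  cat(sprintf("Immune kinetics: T_D = %g d (antigen release), T_IR = %g d (immune activation)\n",
              x$t_d, x$t_ir))
  invisible(x)
}

#' Convert a surviving fraction at 2 Gy into LQ parameters
#'
#' SF2, the surviving fraction after a single 2 Gy dose, is a standard
#' radiosensitivity summary. Given an assumed alpha/beta ratio, alpha is
#' recovered from \eqn{SF2 = e^{-2\alpha - 4\beta}} with
#' \eqn{\beta = \alpha/(\alpha/\beta)}.
#'
#' @param sf2 Surviving fraction at 2 Gy, in (0, 1).
#' @param alpha_beta Assumed alpha/beta ratio, Gy (default 4).
#' @return An [rt_params] object.
#' @examples
#' sf2_params(0.43)  # the more radiosensitive setting
#' sf2_params(0.70)  # intermediate radiosensitivity
#' @export
sf2_params <- function(sf2, alpha_beta = 4) {
  if (!is.numeric(sf2) || length(sf2) != 1L || !is.finite(sf2) ||
      sf2 <= 0 || sf2 >= 1)
    stop("`sf2` must be a single number in (0, 1)", call. = FALSE)
  alpha <- -log(sf2) / (2 + 4 / alpha_beta)
  rt_params(alpha = alpha, alpha_beta = alpha_beta)
}
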