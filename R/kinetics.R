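#' Two-compartment kinetic profile
#'
#' Effective (physical x biological) half-lives of the assumed normalized
#' time-activity curves: mono-exponential for the high-uptake compartment
#' and bi-exponential (slow + fast) for the low-uptake compartment. All
#' user-facing parameters are half-lives in hours; mean lives
#' `tau = t_half / ln 2` are internal.
#'
#' Presets:
#' * `"lu177_dotatate"` - PRRT with 177Lu-DOTA-TATE: 69 h (high), 61 h
#'   (low, slow) and 2.4 h (low, fast), weights 1/6 and 5/6.
#' * `"i131"` - radioiodine: 16 h for the high compartment; the low-
#'   compartment half-lives are not part of the preset and must be given
#'   explicitly.
#'
#' @param t_half_M_h High-compartment effective half-life, hours.
#' @param t_half_S_h,t_half_F_h Low-compartment slow/fast effective
#'   half-lives, hours, `t_half_S_h >= t_half_F_h`.
#' @param w_S,w_F Low-compartment weights, non-negative, summing to 1.
#' @param preset Optional preset name; explicit arguments override it.
#' @return An object of class `compartment_kinetics`.
#' @export
compartment_kinetics <- function(t_half_M_h = NULL, t_half_S_h = NULL,
                                 t_half_F_h = NULL, w_S = NULL, w_F = NULL,
                                 preset = NULL) {
  base <- list(w_S = 1 / 6, w_F = 5 / 6)
  if (!is.null(preset)) {
    base <- switch(preset,
      lu177_dotatate = list(t_half_M_h = 69, t_half_S_h = 61,
                            t_half_F_h = 2.4, w_S = 1 / 6, w_F = 5 / 6),
      i131 = list(t_half_M_h = 16, w_S = 1 / 6, w_F = 5 / 6),
      stop("unknown kinetics preset: ", preset))
  }
  k <- utils::modifyList(base, Filter(Negate(is.null),
         list(t_half_M_h = t_half_M_h, t_half_S_h = t_half_S_h,
              t_half_F_h = t_half_F_h, w_S = w_S, w_F = w_F)))
  need <- c("t_half_M_h", "t_half_S_h", "t_half_F_h", "w_S", "w_F")
  miss <- setdiff(need, names(k))
  if (length(miss))
    stop("kinetics parameters missing (no default): ",
         paste(miss, collapse = ", "))
  with(k, {
    if (any(c(t_half_M_h, t_half_S_h, t_half_F_h) <= 0))
      stop("all half-lives must be > 0")
    if (t_half_S_h < t_half_F_h)
      stop("slow half-life must be >= fast half-life")
    if (w_S < 0 || w_F < 0 || abs(w_S + w_F - 1) > 1e-9)
      stop("weights must be non-negative and sum to 1")
  })
  structure(k[need], class = "compartment_kinetics")
}

#' @export
print.compartment_kinetics <- function(x, ...) {
  cat("compartment_kinetics: high t1/2 =", x$t_half_M_h, "h; low =",
      x$w_S, "x", x$t_half_S_h, "h +", x$w_F, "x", x$t_half_F_h, "h\n")
  invisible(x)
}

#' Normalized time-activity curves of the two compartments
#'
#' `u_high(t) = 2^(-t / t_half_M)`;
#' `u_low(t) = w_S 2^(-t / t_half_S) + w_F 2^(-t / t_half_F)`.
#' Both start at 1 and decay monotonically.
#'
#' @param t Time post administration, hours (vectorized, >= 0).
#' @param kinetics A [compartment_kinetics()].
#' @return Dimensionless fraction(s) in `(0, 1]`.
#' @export
u_high <- function(t, kinetics) {
  check_time(t)
  2^(-t / kinetics$t_half_M_h)
}

#' @rdname u_high
#' @export
u_low <- function(t, kinetics) {
  check_time(t)
  kinetics$w_S * 2^(-t / kinetics$t_half_S_h) +
    kinetics$w_F * 2^(-t / kinetics$t_half_F_h)
}

check_time <- function(t) {
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be >= 0")
  invisible(t)
}

#' Solve the single-time-point scale factors
#'
#' Given the administered activity `A0`, the measured high/low counts-per-
#' second ratio `rho` at the observation time, and the assumed kinetics, the
#' two scale factors satisfy the linear system: they sum to `A0`, and the
#' modeled activity ratio at `t_obs` reproduces `rho`:
#' `S_high u_high(t_obs) / (S_low u_low(t_obs)) = rho`.
#' With `q = rho u_low(t_obs) / u_high(t_obs)` the closed-form solution is
#' `S_high = A0 q / (1 + q)`, `S_low = A0 / (1 + q)`.
#'
#' @param A0 Administered activity, MBq (> 0).
#' @param rho Measured cps ratio high/low (>= 0), e.g. [counts_ratio()].
#' @param t_obs Observation time post administration, hours.
#' @param kinetics A [compartment_kinetics()].
#' @return A `scale_factors` object: `S_high_MBq`, `S_low_MBq`, `A0_MBq`,
#'   `t_obs_h`, `rho`.
#' @export
solve_scale_factors <- function(A0, rho, t_obs, kinetics) {
  if (!is_positive_scalar(A0)) stop("A0 must be > 0")
  if (!is.numeric(rho) || length(rho) != 1 || !is.finite(rho) || rho < 0)
    stop("rho must be a non-negative scalar")
  check_time(t_obs)
  q <- rho * u_low(t_obs, kinetics) / u_high(t_obs, kinetics)
  structure(list(S_high_MBq = A0 * q / (1 + q),
                 S_low_MBq = A0 / (1 + q),
                 A0_MBq = A0, t_obs_h = t_obs, rho = rho,
                 kinetics = kinetics),
            class = "scale_factors")
}

#' @export
print.scale_factors <- function(x, ...) {
  cat("scale_factors: S_high =", format(x$S_high_MBq), "MBq, S_low =",
      format(x$S_low_MBq), "MBq (A0 =", x$A0_MBq, "MBq, rho =",
      format(x$rho), "at t =", x$t_obs_h, "h)\n")
  invisible(x)
}

#' Closed-form cumulated activities of the two compartments
#'
#' Time integrals of the scaled curves from 0 to infinity:
#' `A~_high = S_high t_half_M / ln 2` and
#' `A~_low = S_low (w_S t_half_S + w_F t_half_F) / ln 2`, in MBq h.
#'
#' @param scale A `scale_factors` object (or a bare MBq scalar).
#' @param kinetics A [compartment_kinetics()]; defaults to the one stored in
#'   `scale`.
#' @return Cumulated activity, MBq h.
#' @export
cumulated_activity_high <- function(scale, kinetics = NULL) {
  s <- scale_value(scale, "S_high_MBq")
  k <- kinetics %||% scale$kinetics
  s * k$t_half_M_h / log(2)
}

#' @rdname cumulated_activity_high
#' @export
cumulated_activity_low <- function(scale, kinetics = NULL) {
  s <- scale_value(scale, "S_low_MBq")
  k <- kinetics %||% scale$kinetics
  s * (k$w_S * k$t_half_S_h + k$w_F * k$t_half_F_h) / log(2)
}

scale_value <- function(scale, field) {
  if (inherits(scale, "scale_factors")) scale[[field]]
  else if (is.numeric(scale) && length(scale) == 1 && scale >= 0) scale
  else stop("expected a scale_factors object or a non-negative scalar")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cumulated-activity error of the single-time-point approximation
#'
#' The true activity decays as `A(t) = A0 exp(-t / tau_true)` but is modeled
#' as an effective curve `A_eff(t) = S u(t)`, `u(t) = exp(-t / tau_eff)`,
#' scaled so the two agree at the observation time:
#' `S = A0 w(t_obs)` with the weight `w(t) = exp(-t / tau_true) / u(t)`.
#' The error in the total number of decays is
#' `E = A0 (tau_true - tau_eff w(t_obs))`, and
#' `E_rel = E / (A0 tau_true)`.
#'
#' @param tau_true,tau_eff Mean lives (`t_half / ln 2`) of the real and
#'   assumed decays, hours, > 0.
#' @param t_obs Observation time, hours, > 0.
#' @param A0 Activity at t = 0, MBq.
#' @return A `stp_error` object: `E_abs` (MBq h), `E_rel`, the weight
#'   `w_obs` and the echoed inputs.
#' @export
single_timepoint_error <- function(tau_true, tau_eff, t_obs, A0 = 1) {
  stopifnot(tau_true > 0, tau_eff > 0, t_obs > 0, A0 > 0)
  w_obs <- exp(-t_obs / tau_true) / exp(-t_obs / tau_eff)
  e <- A0 * (tau_true - tau_eff * w_obs)
  structure(list(tau_true_h = tau_true, tau_eff_h = tau_eff,
                 t_obs_h = t_obs, A0_MBq = A0, w_obs = w_obs,
                 E_abs = e, E_rel = e / (A0 * tau_true)),
            class = "stp_error")
}

#' @export
print.stp_error <- function(x, ...) {
  cat("single-time-point error: E =", format(x$E_abs), "MBq h (",
      format(round(100 * x$E_rel, 2)), "% of the true cumulated activity)\n")
  invisible(x)
}
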