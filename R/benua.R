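#' Blood / whole-body retention time series
#'
#' Measured retention series for the blood-based reference dosimetry:
#' blood activity concentration as fraction of the administered activity
#' per ml, or whole-body retention as fraction of the administered
#' activity. Times must be strictly increasing; at least 2 points are
#' needed for a mono-exponential fit and 4 for a bi-exponential one.
#'
#' @param time_h Sampling times, hours (>= 0, strictly increasing).
#' @param value Positive measurements.
#' @param kind `"blood_conc_per_ml_fraction_of_A0"` or
#'   `"wholebody_fraction_of_A0"`.
#' @return A `sample_series` data frame.
#' @export
sample_series <- function(time_h, value,
                          kind = c("blood_conc_per_ml_fraction_of_A0",
                                   "wholebody_fraction_of_A0")) {
  kind <- match.arg(kind)
  if (length(time_h) != length(value) || length(time_h) < 2)
    stop("need >= 2 (time, value) pairs of equal length")
  if (any(time_h < 0) || any(diff(time_h) <= 0))
    stop("times must be >= 0 and strictly increasing")
  if (any(value <= 0)) stop("values must be > 0")
  structure(data.frame(time_h = time_h, value = value),
            kind = kind, class = c("sample_series", "data.frame"))
}

#' @rdname sample_series
#' @param path CSV with header `time_h,fraction_of_A0_per_ml` (blood) or
#'   `time_h,fraction_of_A0` (whole body).
#' @export
read_sample_series <- function(path) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2 || names(d)[1] != "time_h")
    stop("expected header time_h,fraction_of_A0_per_ml or ",
         "time_h,fraction_of_A0")
  kind <- switch(names(d)[2],
                 fraction_of_A0_per_ml = "blood_conc_per_ml_fraction_of_A0",
                 fraction_of_A0 = "wholebody_fraction_of_A0",
                 stop("unrecognized value column: ", names(d)[2]))
  sample_series(d[[1]], d[[2]], kind)
}

exp_terms_predict <- function(terms, t) {
  v <- 0
  for (i in seq_len(nrow(terms)))
    v <- v + terms$amplitude[i] * 2^(-t / terms$half_life_h[i])
  v
}

#' Exponential fits of retention curves
#'
#' Least-squares fits in linear space of `sum_i A_i 2^(-t / Th_i)` with one
#' (mono) or two (bi) terms, via Levenberg-Marquardt with positivity
#' bounds. Initialization is deterministic: log-linear regression for the
#' mono fit; curve peeling (log-linear tail for the slow term, peeled
#' residual head for the fast term) for the bi fit. Non-convergence and
#' degenerate solutions are reported through the `converged` flag, never
#' silently.
#'
#' @param series A [sample_series()].
#' @param max_iter Iteration cap for the optimizer.
#' @return An `exp_fit` object: `terms` (data frame `amplitude`,
#'   `half_life_h`, decreasing half-life), `rss`, `converged`, `kind`.
#' @export
fit_monoexponential <- function(series, max_iter = 200) {
  stopifnot(inherits(series, "sample_series"))
  t <- series$time_h; v <- series$value
  lf <- stats::lm(log(v) ~ t)
  a0 <- exp(stats::coef(lf)[[1]])
  th0 <- if (stats::coef(lf)[[2]] < 0) -log(2) / stats::coef(lf)[[2]] else
    max(t)
  fit <- try(minpack.lm::nlsLM(
    v ~ A * 2^(-t / Th), start = list(A = a0, Th = th0),
    lower = c(1e-12, 1e-9), control = minpack.lm::nls.lm.control(
      maxiter = max_iter)), silent = TRUE)
  finish_exp_fit(fit, t, v, 1, fallback = data.frame(
    amplitude = a0, half_life_h = th0), kind = attr(series, "kind"))
}

#' @rdname fit_monoexponential
#' @export
fit_biexponential <- function(series, max_iter = 400) {
  stopifnot(inherits(series, "sample_series"))
  t <- series$time_h; v <- series$value
  if (length(t) < 4) stop("bi-exponential fit needs >= 4 points")
  # peel: slow component from the last half of the samples
  tail_i <- seq.int(ceiling(length(t) / 2), length(t))
  lf_s <- stats::lm(log(v[tail_i]) ~ t[tail_i])
  a_s <- exp(stats::coef(lf_s)[[1]])
  th_s <- if (stats::coef(lf_s)[[2]] < 0) -log(2) / stats::coef(lf_s)[[2]]
          else max(t)
  resid_head <- v - a_s * 2^(-t / th_s)
  head_i <- which(resid_head > 0 & seq_along(t) <= ceiling(length(t) / 2))
  if (length(head_i) >= 2) {
    lf_f <- stats::lm(log(resid_head[head_i]) ~ t[head_i])
    a_f <- exp(stats::coef(lf_f)[[1]])
    th_f <- if (stats::coef(lf_f)[[2]] < 0) -log(2) / stats::coef(lf_f)[[2]]
            else th_s / 10
  } else {
    a_f <- max(v[1] - a_s, 0.1 * a_s)
    th_f <- max(th_s / 20, t[2] / 2)
  }
  th_f <- min(th_f, 0.9 * th_s)
  fit <- try(minpack.lm::nlsLM(
    v ~ As * 2^(-t / Ths) + Af * 2^(-t / Thf),
    start = list(As = a_s, Ths = th_s, Af = a_f, Thf = th_f),
    lower = rep(c(1e-12, 1e-9), 2),
    control = minpack.lm::nls.lm.control(maxiter = max_iter)),
    silent = TRUE)
  finish_exp_fit(fit, t, v, 2, fallback = data.frame(
    amplitude = c(a_s, a_f), half_life_h = c(th_s, th_f)),
    kind = attr(series, "kind"))
}

finish_exp_fit <- function(fit, t, v, n_terms, fallback, kind) {
  if (inherits(fit, "try-error")) {
    terms <- fallback
    converged <- FALSE
    rss <- sum((v - exp_terms_predict(terms, t))^2)
  } else {
    cf <- stats::coef(fit)
    terms <- if (n_terms == 1)
      data.frame(amplitude = cf[["A"]], half_life_h = cf[["Th"]])
    else
      data.frame(amplitude = c(cf[["As"]], cf[["Af"]]),
                 half_life_h = c(cf[["Ths"]], cf[["Thf"]]))
    rss <- sum(stats::resid(fit)^2)
    converged <- isTRUE(fit$convInfo$isConv)
    # a bi-fit collapsing to equal half-lives is unidentifiable
    if (n_terms == 2 &&
        abs(diff(terms$half_life_h)) < 1e-6 * max(terms$half_life_h))
      converged <- FALSE
  }
  terms <- terms[order(-terms$half_life_h), , drop = FALSE]
  rownames(terms) <- NULL
  structure(list(terms = terms, rss = rss, converged = converged,
                 kind = kind),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  cat("exp_fit (", nrow(x$terms), "term(s),",
      if (x$converged) "converged" else "NOT converged", ")\n")
  for (i in seq_len(nrow(x$terms)))
    cat(sprintf("  A = %.6g, t1/2 = %.6g h\n", x$terms$amplitude[i],
                x$terms$half_life_h[i]))
  cat("  rss:", format(x$rss), "\n")
  invisible(x)
}

#' Residence time of a fitted retention curve
#'
#' Analytic time integral of the fitted model in normalized units:
#' `sum_i A_i Th_i / ln 2`, hours (per ml for blood concentration fits).
#'
#' @param fit A converged [fit_monoexponential()]/[fit_biexponential()]
#'   result.
#' @return Residence time, hours.
#' @export
residence_time <- function(fit) {
  stopifnot(inherits(fit, "exp_fit"))
  if (!fit$converged)
    stop("refusing to integrate an unconverged exponential fit")
  sum(fit$terms$amplitude * fit$terms$half_life_h) / log(2)
}

#' Beta self-dose constant of the blood
#'
#' Dose rate per unit activity concentration for complete local absorption
#' of the mean beta energy in one millilitre of blood:
#' `E_keV x 1.602e-16 J/keV / 1e-3 kg`, in Gy ml/(Bq s), and its
#' conversion to Gy ml/(GBq h) (x 1e9 x 3600). For the 187 keV mean beta
#' of 131I this gives 3.0e-11 Gy ml/(Bq s) (one significant figure), i.e.
#' 108 Gy ml/(GBq h).
#'
#' @param E_mean_keV Mean beta energy per decay, keV (> 0).
#' @return List with `Gy_ml_per_Bq_s` and `Gy_ml_per_GBq_h`.
#' @export
beta_self_dose_constant <- function(E_mean_keV) {
  if (E_mean_keV <= 0) stop("E_mean_keV must be > 0")
  per_bq_s <- E_mean_keV * KEV_TO_J / 1e-3
  list(Gy_ml_per_Bq_s = per_bq_s,
       Gy_ml_per_GBq_h = per_bq_s * 1e9 * 3600)
}

#' Benua/Lassmann blood dose
#'
#' `D_blood = 108 A0 tau_blood + (0.0188 / wt^(2/3)) A0 tau_WB` in Gy, with
#' `A0` in GBq, the blood residence time in h (per ml, from the
#' concentration fit), the whole-body residence time in h and the patient
#' weight in kg. The first term is the beta self-dose in blood; the second
#' the photon dose from whole-body retention (the weight term enters as a
#' divisor: the Monte-Carlo-derived replacement of the geometric factor).
#'
#' @param A0_GBq Administered activity, GBq (>= 0).
#' @param tau_blood_h_per_ml Blood residence time, h/ml (>= 0).
#' @param tau_WB_h Whole-body residence time, h (>= 0).
#' @param weight_kg Patient weight, kg (> 0).
#' @return A `benua_result`: inputs plus `D_blood_Gy` and its two
#'   components.
#' @export
benua_blood_dose <- function(A0_GBq, tau_blood_h_per_ml, tau_WB_h,
                             weight_kg) {
  if (A0_GBq < 0 || tau_blood_h_per_ml < 0 || tau_WB_h < 0)
    stop("A0 and residence times must be >= 0")
  if (weight_kg <= 0) stop("weight_kg must be > 0")
  beta <- 108 * A0_GBq * tau_blood_h_per_ml
  gamma <- 0.0188 / weight_kg^(2 / 3) * A0_GBq * tau_WB_h
  structure(list(A0_GBq = A0_GBq,
                 tau_blood_h_per_ml = tau_blood_h_per_ml,
                 tau_WB_h = tau_WB_h, weight_kg = weight_kg,
                 D_beta_Gy = beta, D_gamma_Gy = gamma,
                 D_blood_Gy = beta + gamma),
            class = "benua_result")
}

#' @export
print.benua_result <- function(x, ...) {
  cat("Benua blood dose:", format(signif(x$D_blood_Gy, 4)), "Gy",
      "(beta", format(signif(x$D_beta_Gy, 4)), "+ gamma",
      format(signif(x$D_gamma_Gy, 4)), ")\n")
  invisible(x)
}

#' End-to-end Benua dosimetry from measured series
#'
#' Bi-exponential fit of the blood concentration series, mono-exponential
#' fit of the whole-body retention series, residence times, and the blood
#' dose.
#'
#' @param blood A blood [sample_series()] (fraction of A0 per ml).
#' @param wholebody A whole-body [sample_series()] (fraction of A0).
#' @param A0_GBq Administered activity, GBq.
#' @param weight_kg Patient weight, kg.
#' @return A `benua_result` with the two `exp_fit`s attached.
#' @export
benua_from_series <- function(blood, wholebody, A0_GBq, weight_kg) {
  fb <- fit_biexponential(blood)
  fw <- fit_monoexponential(wholebody)
  res <- benua_blood_dose(A0_GBq, residence_time(fb), residence_time(fw),
                          weight_kg)
  res$blood_fit <- fb
  res$wholebody_fit <- fw
  res
}
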