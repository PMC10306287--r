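#' Reversible-inactivation rate model
#'
#' The temperature optimum model \eqn{v(T) = k_{rxn}(T) / (1 + K_{inact}(T))}:
#' the chemical step accelerates with temperature in Eyring fashion, while a
#' reversible, instantaneously equilibrated inactivation (e.g. rupture of a
#' key enzyme--substrate hydrogen bond) drains the active population at high
#' temperature via the van't Hoff equilibrium
#' \eqn{K_{inact} = \exp(-(\Delta H_{inact} - T\Delta S_{inact})/RT)}.
#' An interior optimum below any melting transition requires
#' \eqn{\Delta H_{inact} > \Delta H_{rxn} + RT}.
#'
#' @param dH_rxn,dS_rxn activation enthalpy (kcal/mol) and entropy
#'   (kcal/(mol K)) of the chemical step. `dS_rxn` is confounded with
#'   `amplitude` in fitting and defaults to 0.
#' @param dH_inact,dS_inact van't Hoff enthalpy and entropy of the
#'   inactivation equilibrium.
#' @param amplitude positive scale factor (absorbance units x s) absorbing
#'   extinction coefficient, path length and enzyme concentration.
#' @param rate_form functional form of \eqn{k_{rxn}}: `"eyring"` (default,
#'   includes the \eqn{k_B T/h} prefactor) or `"exponential"` (pure
#'   Boltzmann factor).
#' @return an `inactivation_model` object.
#' @examples
#' m <- inactivation_model(dH_rxn = 11, dH_inact = 100,
#'                         dS_inact = solve_entropy_for_optimum(11, 100, to_kelvin(45)))
#' velocity(m, to_kelvin(c(25, 45, 65)))
#' @export
inactivation_model <- function(dH_rxn, dS_rxn = 0, dH_inact, dS_inact,
                               amplitude = 1,
                               rate_form = c("eyring", "exponential")) {
  rate_form <- match.arg(rate_form)
  stopifnot(is.finite(dH_rxn), is.finite(dS_rxn), is.finite(dH_inact),
            is.finite(dS_inact), is.finite(amplitude))
  if (amplitude <= 0) stop("amplitude must be positive", call. = FALSE)
  if (dH_inact <= 0) {
    warning("dH_inact <= 0: K_inact decreases with temperature, no interior optimum",
            call. = FALSE)
  }
  structure(list(dH_rxn = dH_rxn, dS_rxn = dS_rxn, dH_inact = dH_inact,
                 dS_inact = dS_inact, amplitude = amplitude,
                 rate_form = rate_form),
            class = "inactivation_model")
}

#' @export
print.inactivation_model <- function(x, ...) {
  cat(sprintf(
    "<inactivation_model> (%s k_rxn)\n  reaction:     dH = %.3f, dS = %.5f\n  inactivation: dH = %.3f, dS = %.5f  (T_half = %.2f K)\n  amplitude = %.4g\n",
    x$rate_form, x$dH_rxn, x$dS_rxn, x$dH_inact, x$dS_inact,
    if (x$dS_inact != 0) x$dH_inact / x$dS_inact else NA, x$amplitude))
  invisible(x)
}

#' Inactivation equilibrium constant
#'
#' @param model an [inactivation_model()].
#' @param T_K temperature(s), Kelvin.
#' @return dimensionless \eqn{K_{inact}(T)}.
#' @export
k_inact <- function(model, T_K) {
  .check_temperature_K(T_K)
  exp(-(model$dH_inact - T_K * model$dS_inact) / (.R_KCAL * T_K))
}

#' Reaction velocity under the reversible-inactivation model
#'
#' @inheritParams k_inact
#' @return velocity, absorbance units / s.
#' @export
velocity <- function(model, T_K) {
  stopifnot(inherits(model, "inactivation_model"))
  .check_temperature_K(T_K)
  dG <- model$dH_rxn - T_K * model$dS_rxn
  krxn <- if (model$rate_form == "eyring") {
    model$amplitude * .KB_OVER_H * T_K * exp(-dG / (.R_KCAL * T_K))
  } else {
    model$amplitude * exp(-dG / (.R_KCAL * T_K))
  }
  krxn / (1 + k_inact(model, T_K))
}

#' Inactivation entropy that places the optimum at a target temperature
#'
#' Closed-form solution of the stationarity condition of \eqn{v(T)}:
#' at the optimum \eqn{K/(1+K) = (\Delta H_{rxn} + RT_{opt})/\Delta H_{inact}}
#' (the \eqn{RT} term drops for the `"exponential"` rate form). Requires
#' \eqn{\Delta H_{inact} > \Delta H_{rxn} + RT_{opt}}, otherwise no interior
#' optimum exists.
#'
#' @param dH_rxn,dH_inact enthalpies, kcal/mol.
#' @param T_opt_K target optimum temperature, Kelvin.
#' @param rate_form see [inactivation_model()].
#' @return the inactivation entropy, kcal/(mol K).
#' @export
solve_entropy_for_optimum <- function(dH_rxn, dH_inact, T_opt_K,
                                      rate_form = c("eyring", "exponential")) {
  rate_form <- match.arg(rate_form)
  .check_temperature_K(T_opt_K)
  f <- if (rate_form == "eyring") {
    (dH_rxn + .R_KCAL * T_opt_K) / dH_inact
  } else {
    dH_rxn / dH_inact
  }
  if (!is.finite(f) || f <= 0 || f >= 1) {
    stop("no interior optimum: need dH_inact > dH_rxn + R*T_opt (both positive)",
         call. = FALSE)
  }
  K <- f / (1 - f)
  (dH_inact + .R_KCAL * T_opt_K * log(K)) / T_opt_K
}

#' Temperature-ramp protocol
#'
#' @param T_start_C starting temperature, Celsius.
#' @param rate_C_per_min ramp gradient (default 10 C/min).
#' @param duration_s total time, s.
#' @param sample_dt_s sampling interval, s.
#' @return a `ramp_protocol` object.
#' @export
ramp_protocol <- function(T_start_C = 10, rate_C_per_min = 10,
                          duration_s = 360, sample_dt_s = 1) {
  stopifnot(duration_s > 0, sample_dt_s > 0)
  structure(list(T_start = to_kelvin(T_start_C), rate = rate_C_per_min,
                 duration = duration_s, dt = sample_dt_s),
            class = "ramp_protocol")
}

# Integrate dA/dt = v(T(t)) with a fixed-step 4th-order scheme at step dt/10.
# The integrand is independent of A, so the classical RK4 update reduces to a
# composite Simpson rule on the fine grid; it is evaluated vectorised.
.integrate_ramp <- function(model, times, T_start_K, rate_K_per_min,
                            substeps = 10) {
  stopifnot(length(times) >= 2, all(diff(times) > 0))
  h <- diff(times) / substeps
  nint <- length(h)
  npt <- 2 * substeps + 1  # half-step points per sample interval
  # fine half-step grid spanning each sample interval (columns = intervals)
  rel <- seq(0, substeps, by = 0.5)
  fine <- rep(times[-length(times)], each = npt) + rel * rep(h, each = npt)
  Tt <- T_start_K + rate_K_per_min / 60 * fine
  v <- matrix(velocity(model, Tt), npt, nint)
  # composite Simpson weights over the 2*substeps half-steps
  w <- c(1, rep(c(4, 2), substeps - 1), 4, 1) / 6
  inc <- h * colSums(v * w)
  c(0, cumsum(inc))
}

#' Simulate a temperature-ramp assay trace
#'
#' Forward-integrates \eqn{dA/dt = v(T(t))} with \eqn{T(t) = T_{start} +
#' (\mathrm{rate}/60)\, t} using a fixed-step 4th-order scheme (step =
#' `sample_dt/10`), then adds optional noise. Deterministic for a given seed.
#'
#' @param model an [inactivation_model()].
#' @param protocol a [ramp_protocol()].
#' @param noise_cv multiplicative Gaussian noise, coefficient of variation.
#' @param noise_sd additive Gaussian noise, absorbance units.
#' @param seed integer seed, or `NULL` to use the session RNG stream.
#' @return tibble `time_s`, `temperature_C`, `absorbance`.
#' @export
simulate_ramp <- function(model, protocol = ramp_protocol(),
                          noise_cv = 0, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(model, "inactivation_model"),
            inherits(protocol, "ramp_protocol"))
  times <- seq(0, protocol$duration, by = protocol$dt)
  A <- .integrate_ramp(model, times, protocol$T_start, protocol$rate)
  Tt <- protocol$T_start + protocol$rate / 60 * times
  .with_seed(seed, {
    if (noise_cv > 0) A <- A * (1 + stats::rnorm(length(A), 0, noise_cv))
    if (noise_sd > 0) A <- A + stats::rnorm(length(A), 0, noise_sd)
    tibble::tibble(time_s = times, temperature_C = to_celsius(Tt),
                   absorbance = A)
  })
}

#' Fit the reversible-inactivation model to a ramp trace
#'
#' Multi-start bounded Levenberg--Marquardt least squares against the
#' forward-integrated model. The fit is parameterised for conditioning as
#' (log reference velocity, \eqn{\Delta H_{rxn}}, \eqn{\Delta H_{inact}},
#' \eqn{T_{half} = \Delta H_{inact}/\Delta S_{inact}}); the reaction entropy
#' is absorbed into the amplitude (they are not separately identifiable).
#' Starts are a seeded Latin hypercube over the bounds.
#'
#' @param trace data frame `time_s`, `temperature_C`, `absorbance` (>= 20
#'   samples spanning >= 20 K).
#' @param n_starts number of multi-start initialisations (default 16).
#' @param seed integer seed for the start design.
#' @param rate_form see [inactivation_model()].
#' @param baseline fit a constant absorbance offset (off by default).
#' @return a `ramp_fit` object with the fitted model, parameter covariance,
#'   `T_opt_K` and `converged` flag.
#' @export
fit_ramp <- function(trace, n_starts = 16, seed = NULL,
                     rate_form = c("eyring", "exponential"),
                     baseline = FALSE) {
  rate_form <- match.arg(rate_form)
  need <- c("time_s", "temperature_C", "absorbance")
  miss <- setdiff(need, names(trace))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (nrow(trace) < 20) stop("insufficient data: need >= 20 samples", call. = FALSE)
  T_K <- to_kelvin(trace$temperature_C)
  if (diff(range(T_K)) < 20) stop("trace must span >= 20 K", call. = FALSE)

  # recover the (assumed linear) protocol from the trace itself
  ramp <- stats::lm(T_K ~ trace$time_s)
  T_start <- unname(stats::coef(ramp)[1])
  rate_K_min <- unname(stats::coef(ramp)[2]) * 60
  times <- trace$time_s
  A_obs <- trace$absorbance
  T_mid <- mean(range(T_K))

  # velocity scale from the trace for the log-v_ref parameter
  v_scale <- max(abs(diff(A_obs)) / diff(times))
  if (!is.finite(v_scale) || v_scale <= 0) v_scale <- 1e-3
  lv0 <- log(v_scale)

  model_from_theta <- function(th) {
    # th = (log v_ref at T_mid, dH_rxn, dH_inact, T_half)
    dH <- th[2]
    prefac <- if (rate_form == "eyring") .KB_OVER_H * T_mid else 1
    amp <- exp(th[1]) / (prefac * exp(-dH / (.R_KCAL * T_mid)))
    inactivation_model(dH_rxn = dH, dS_rxn = 0, dH_inact = th[3],
                       dS_inact = th[3] / th[4], amplitude = amp,
                       rate_form = rate_form)
  }
  predict_theta <- function(th) {
    A <- .integrate_ramp(model_from_theta(th), times, T_start, rate_K_min)
    if (baseline && length(th) >= 5) A <- A + th[5] else A
  }
  resid_fn <- function(th) predict_theta(th) - A_obs

  lower <- c(lv0 - 25, 0, 1e-3, 273)
  upper <- c(lv0 + 25, 300, 300, 373)
  start_lo <- c(lv0 - 3, 2, 30, 300)
  start_hi <- c(lv0 + 3, 40, 220, 360)
  if (baseline) {
    lower <- c(lower, -max(abs(A_obs))); upper <- c(upper, max(abs(A_obs)))
    start_lo <- c(start_lo, 0); start_hi <- c(start_hi, 0)
  }
  npar <- length(lower)

  starts <- .with_seed(seed, lhs::randomLHS(n_starts, npar))
  starts <- sweep(sweep(starts, 2, start_hi - start_lo, "*"), 2, start_lo, "+")

  best <- NULL
  n_used <- 0L
  for (i in seq_len(n_starts)) {
    n_used <- n_used + 1L
    out <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(out)) next
    rss <- sum(out$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(fit = out, rss = rss, theta = out$par,
                   converged = out$info %in% 1:3)
      # an essentially perfect fit need not be re-started
      if (rss < 1e-16 * sum(A_obs^2)) break
    }
  }
  if (is.null(best)) stop("all optimizer starts failed", call. = FALSE)

  theta <- best$theta
  model <- model_from_theta(theta)
  nobs <- length(A_obs)
  sigma2 <- best$rss / max(nobs - npar, 1)
  J <- .num_jacobian(predict_theta, theta)
  vc <- tryCatch(sigma2 * solve(crossprod(J)),
                 error = function(e) matrix(NA_real_, npar, npar))
  pn <- c("log_vref", "dH_rxn", "dH_inact", "T_half",
          if (baseline) "baseline")
  dimnames(vc) <- list(pn, pn)
  names(theta) <- pn

  T_opt <- find_optimum(function(Tk) velocity(model, Tk),
                        min(T_K), max(T_K), resolution_K = 0.01)
  structure(list(
    model = model, theta = theta, vcov = vc,
    T_opt_K = T_opt, converged = best$converged,
    n_starts_used = n_used, rss = best$rss, n = nobs,
    trace = tibble::as_tibble(trace[need]),
    fitted = predict_theta(theta),
    rate_form = rate_form
  ), class = "ramp_fit")
}

.num_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(abs(x[j]), 1)
    xp <- x; xp[j] <- xp[j] + h
    J[, j] <- (f(xp) - f0) / h
  }
  J
}

#' @export
print.ramp_fit <- function(x, ...) {
  cat(sprintf(
    "<ramp_fit> %sconverged (%d starts), rss = %.4g, n = %d\n  dH_rxn = %.3f, dH_inact = %.3f kcal/mol, T_half = %.2f K\n  T_opt = %.2f K (%.2f C)\n",
    if (x$converged) "" else "NOT ", x$n_starts_used, x$rss, x$n,
    x$theta[["dH_rxn"]], x$theta[["dH_inact"]], x$theta[["T_half"]],
    x$T_opt_K, to_celsius(x$T_opt_K)))
  invisible(x)
}

#' Max-normalised fitted velocity curve
#'
#' The relative k_cat(T) implied by a converged ramp fit (the derivative of
#' the fitted product-formation curve, normalised to its maximum).
#'
#' @param fit a converged `ramp_fit`.
#' @param T_grid_C temperature grid, Celsius.
#' @return tibble `temperature_C`, `rel_rate` with max exactly 1.
#' @export
relative_rate_curve <- function(fit, T_grid_C) {
  stopifnot(inherits(fit, "ramp_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  if (length(T_grid_C) == 0) stop("empty temperature grid", call. = FALSE)
  v <- velocity(fit$model, to_kelvin(T_grid_C))
  tibble::tibble(temperature_C = T_grid_C, rel_rate = v / max(v))
}

#' Shift between two fitted temperature optima
#'
#' @param fit_a,fit_b converged `ramp_fit` objects.
#' @return `T_opt(b) - T_opt(a)` in Kelvin (equivalently Celsius degrees).
#' @export
optimum_shift <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "ramp_fit"), inherits(fit_b, "ramp_fit"))
  if (!fit_a$converged || !fit_b$converged) {
    stop("both fits must have converged", call. = FALSE)
  }
  fit_b$T_opt_K - fit_a$T_opt_K
}
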