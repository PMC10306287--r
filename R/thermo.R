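#' Activation parameters of an Eyring barrier
#'
#' Bundles an activation enthalpy and entropy defining the linear model
#' \eqn{\Delta G^\ddagger(T) = \Delta H^\ddagger - T \Delta S^\ddagger}.
#' The entropy may be given either directly (`dS`, kcal/(mol K)) or as the
#' entropic contribution `TdS` (kcal/mol) at the reference temperature,
#' which is how activation parameters are conventionally tabulated.
#'
#' @param dH activation enthalpy, kcal/mol.
#' @param TdS entropy term \eqn{T_{ref}\Delta S^\ddagger} at `Tref_C`, kcal/mol.
#' @param dS activation entropy, kcal/(mol K). Give exactly one of `TdS`, `dS`.
#' @param Tref_C reference temperature in Celsius (default 15, the usual
#'   convention for comparing psychrophilic and mesophilic amylases).
#' @return an object of class `activation_params`.
#' @examples
#' p <- activation_params(dH = 11.0, TdS = -1.7)
#' gibbs_at(p, to_kelvin(15)) # 12.7 kcal/mol
#' @export
activation_params <- function(dH, TdS = NULL, dS = NULL, Tref_C = 15) {
  stopifnot(is.numeric(dH), length(dH) == 1, is.finite(dH))
  Tref <- to_kelvin(Tref_C)
  .check_temperature_K(Tref)
  if (is.null(dS) == is.null(TdS)) {
    stop("give exactly one of `TdS` (kcal/mol at Tref) or `dS` (kcal/(mol K))",
         call. = FALSE)
  }
  if (is.null(dS)) dS <- TdS / Tref
  stopifnot(is.numeric(dS), length(dS) == 1, is.finite(dS))
  structure(list(dH = dH, dS = dS, Tref = Tref), class = "activation_params")
}

#' @export
print.activation_params <- function(x, ...) {
  cat(sprintf(
    "<activation_params> dH = %.3f kcal/mol, TdS(%.2f K) = %.3f kcal/mol, dG = %.3f kcal/mol\n",
    x$dH, x$Tref, x$Tref * x$dS, gibbs_at(x, x$Tref)))
  invisible(x)
}

#' Activation free energy at a temperature
#'
#' @param params an [activation_params()] object.
#' @param T_K temperature(s), Kelvin (must be positive).
#' @return barrier(s) \eqn{\Delta H^\ddagger - T\Delta S^\ddagger}, kcal/mol.
#' @export
gibbs_at <- function(params, T_K) {
  stopifnot(inherits(params, "activation_params"))
  .check_temperature_K(T_K)
  params$dH - T_K * params$dS
}

#' Eyring rate constant from a free-energy barrier
#'
#' \eqn{k = (k_B T / h)\,\exp(-\Delta G^\ddagger / RT)} with transmission
#' coefficient 1. Relative rate curves are insensitive to the prefactor
#' choice because of their max-normalisation.
#'
#' @param barrier activation free energy, kcal/mol.
#' @param T_K temperature, Kelvin.
#' @return rate constant, 1/s.
#' @examples
#' eyring_rate(0, 298.15)      # k_B T / h ~ 6.21e12 s^-1
#' @export
eyring_rate <- function(barrier, T_K) {
  .check_temperature_K(T_K)
  .KB_OVER_H * T_K * exp(-barrier / (.R_KCAL * T_K))
}

#' @rdname eyring_rate
#' @param rate rate constant, 1/s, to invert to a barrier.
#' @export
barrier_from_rate <- function(rate, T_K) {
  .check_temperature_K(T_K)
  stopifnot(all(rate > 0))
  -.R_KCAL * T_K * log(rate / (.KB_OVER_H * T_K))
}

# ---- barrier tables ---------------------------------------------------------

# Normalise a user-supplied barrier table to (T_K, dG_mean, dG_sem, n_replicates).
# Accepts the wide layout `temperature_C, dG_mean[, dG_sem, n_replicates]` or
# the replicate-level layout `temperature_C, replicate, dG`, and Kelvin via a
# `temperature_K` column.
.as_barrier_table <- function(data) {
  stopifnot(is.data.frame(data))
  nm <- names(data)
  if ("temperature_K" %in% nm) {
    data$temperature_C <- to_celsius(data$temperature_K)
  }
  if (!"temperature_C" %in% nm) {
    stop("missing column(s): temperature_C (or temperature_K)", call. = FALSE)
  }
  if ("dG" %in% nm && !"dG_mean" %in% nm) {
    data <- data |>
      dplyr::group_by(.data$temperature_C) |>
      dplyr::summarise(
        dG_mean = mean(.data$dG),
        dG_sem = stats::sd(.data$dG) / sqrt(dplyr::n()),
        n_replicates = dplyr::n(),
        .groups = "drop"
      )
  }
  if (!"dG_mean" %in% nm && !"dG_mean" %in% names(data)) {
    stop("missing column(s): dG_mean (or long-form dG)", call. = FALSE)
  }
  out <- tibble::tibble(
    T_K = to_kelvin(data$temperature_C),
    dG_mean = data$dG_mean,
    dG_sem = if ("dG_sem" %in% names(data)) data$dG_sem else NA_real_,
    n_replicates = if ("n_replicates" %in% names(data)) data$n_replicates else NA_integer_
  )
  .check_temperature_K(out$T_K)
  if (any(!is.na(out$dG_sem) & out$dG_sem < 0)) {
    stop("dG_sem must be non-negative", call. = FALSE)
  }
  dplyr::arrange(out, .data$T_K)
}

# weights policy: 1/sem^2 when SEMs are present (and requested), else OLS
.barrier_weights <- function(tbl, weighted) {
  if (is.null(weighted)) {
    weighted <- all(is.finite(tbl$dG_sem)) && all(tbl$dG_sem >= 0)
    if (weighted && any(tbl$dG_sem == 0)) weighted <- FALSE
  }
  if (!weighted) return(list(weighted = FALSE, w = rep(1, nrow(tbl))))
  if (any(!is.finite(tbl$dG_sem))) {
    stop("weighted fit requested but dG_sem is missing", call. = FALSE)
  }
  if (any(tbl$dG_sem == 0)) {
    stop("weighted fit requested but some dG_sem are zero", call. = FALSE)
  }
  list(weighted = TRUE, w = 1 / tbl$dG_sem^2)
}

#' Fit an Eyring-form Arrhenius plot
#'
#' Regresses \eqn{\Delta G^\ddagger / T} on \eqn{1/T}: the slope is the
#' activation enthalpy and the intercept is \eqn{-\Delta S^\ddagger}. When SEM
#' columns are present the regression is weighted by `1/dG_sem^2` (override
#' with `weighted`).
#'
#' @param data data frame with columns `temperature_C` (or `temperature_K`)
#'   and `dG_mean` (optionally `dG_sem`, `n_replicates`), or replicate-level
#'   `temperature_C, replicate, dG`.
#' @param t_min_C,t_max_C optional Celsius window restricting the fit (the
#'   low-temperature linear regime, e.g. 20--35 C).
#' @param weighted `TRUE`/`FALSE`, or `NULL` to weight whenever SEMs are
#'   available and positive.
#' @param Tref_C reference temperature for reporting the entropy term.
#' @return an `arrhenius_fit` object; see [tidy()][generics::tidy] and
#'   [glance()][generics::glance].
#' @examples
#' p <- activation_params(dH = 11.0, TdS = -1.7)
#' d <- gen_barrier_series(p, temperatures_C = c(20, 25, 30, 35), sem = 0)
#' fit_arrhenius(d)
#' @export
fit_arrhenius <- function(data, t_min_C = NULL, t_max_C = NULL,
                          weighted = NULL, Tref_C = 15) {
  tbl <- .as_barrier_table(data)
  if (!is.null(t_min_C)) tbl <- tbl[tbl$T_K >= to_kelvin(t_min_C) - 1e-9, ]
  if (!is.null(t_max_C)) tbl <- tbl[tbl$T_K <= to_kelvin(t_max_C) + 1e-9, ]
  if (nrow(tbl) < 2) {
    stop("insufficient data: need at least 2 temperatures in the window",
         call. = FALSE)
  }
  wt <- .barrier_weights(tbl, weighted)
  x <- 1 / tbl$T_K
  y <- tbl$dG_mean / tbl$T_K
  fit <- stats::lm(y ~ x, weights = wt$w)
  co <- stats::coef(fit)
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  dH <- unname(co[["x"]])
  dS <- -unname(co[["(Intercept)"]])
  params <- activation_params(dH = dH, dS = dS, Tref_C = Tref_C)
  structure(list(
    params = params,
    weighted = wt$weighted,
    sse = sum(wt$w * stats::resid(fit)^2),
    se_dH = if (nrow(tbl) > 2) unname(se[["x"]]) else NA_real_,
    se_dS = if (nrow(tbl) > 2) unname(se[["(Intercept)"]]) else NA_real_,
    n = nrow(tbl),
    data = tbl,
    lm = fit
  ), class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf(
    "<arrhenius_fit> n = %d (%sweighted)\n  dH = %.3f kcal/mol (se %.3g)\n  TdS(%.2f C) = %.3f kcal/mol\n  sse = %.4g\n",
    x$n, if (x$weighted) "" else "un", x$params$dH,
    x$se_dH, to_celsius(x$params$Tref), x$params$Tref * x$params$dS, x$sse))
  invisible(x)
}

#' Detect a break in an Arrhenius plot
#'
#' Grid search for a continuous-hinge two-segment fit of
#' \eqn{\Delta G^\ddagger/T} versus \eqn{1/T}: segments share the value at the
#' break temperature but change slope (activation enthalpy). A break is
#' reported only if the two-segment model reduces the (weighted) residual sum
#' of squares by at least `min_improvement` *and* an F-style ratio test for
#' the two extra parameters is significant at `alpha` -- a guard against
#' overfitting the typical six-point series.
#'
#' @inheritParams fit_arrhenius
#' @param min_points_per_segment minimum data points strictly on each side of
#'   a candidate break (>= 2).
#' @param min_improvement minimum fractional SSE reduction (default 0.25).
#' @param alpha significance level of the F-style test (default 0.05).
#' @param grid_step_K spacing of the candidate break-temperature grid.
#' @return a `breakpoint_fit` with fields `T_break` (K, `NA` when no break is
#'   supported), `T_break_best` (the grid-optimal hinge regardless of the
#'   significance guard), `left`/`right` segment fits (below/above the break
#'   on the temperature axis), `sse_total`, `sse_single_line`, `p_value`.
#' @export
detect_break <- function(data, min_points_per_segment = 2,
                         min_improvement = 0.25, alpha = 0.05,
                         grid_step_K = 0.1, weighted = NULL, Tref_C = 15) {
  stopifnot(min_points_per_segment >= 2)
  tbl <- .as_barrier_table(data)
  n <- nrow(tbl)
  if (n < 2 * min_points_per_segment) {
    stop("insufficient data: need at least 2*min_points_per_segment temperatures",
         call. = FALSE)
  }
  wt <- .barrier_weights(tbl, weighted)
  x <- 1 / tbl$T_K
  y <- tbl$dG_mean / tbl$T_K
  single <- fit_arrhenius(tbl_to_df(tbl), weighted = wt$weighted, Tref_C = Tref_C)
  sse1 <- single$sse

  cand <- seq(min(tbl$T_K), max(tbl$T_K), by = grid_step_K)
  keep <- vapply(cand, function(tb) {
    sum(tbl$T_K <= tb) >= min_points_per_segment &&
      sum(tbl$T_K > tb) >= min_points_per_segment
  }, logical(1))
  cand <- cand[keep]
  if (length(cand) == 0) {
    stop("no admissible break candidates with this min_points_per_segment",
         call. = FALSE)
  }

  best <- NULL
  for (tb in cand) {
    x0 <- 1 / tb
    z <- pmax(x - x0, 0)
    fit <- stats::lm(y ~ x + z, weights = wt$w)
    sse <- sum(wt$w * stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse - 1e-15) {
      best <- list(T_break = tb, sse = sse, coef = stats::coef(fit))
    }
  }

  # decision rule: relative improvement AND F-style ratio test
  scale <- max(sse1, sum(wt$w * y^2))
  p_value <- NA_real_
  has_break <- FALSE
  if (sse1 > 1e-18 * scale && n > 4) {
    improvement <- 1 - best$sse / sse1
    fstat <- ((sse1 - best$sse) / 2) / (best$sse / (n - 4))
    p_value <- stats::pf(fstat, 2, n - 4, lower.tail = FALSE)
    if (!is.finite(p_value)) p_value <- 0
    has_break <- improvement >= min_improvement && p_value <= alpha
  }

  seg <- .hinge_segments(best$coef, best$T_break, Tref_C)
  structure(list(
    T_break = if (has_break) best$T_break else NA_real_,
    T_break_best = best$T_break,
    left = if (has_break) seg$left else single,
    right = if (has_break) seg$right else single,
    sse_total = best$sse,
    sse_single_line = sse1,
    p_value = p_value,
    single = single,
    weighted = wt$weighted,
    n = n,
    data = tbl
  ), class = "breakpoint_fit")
}

# hinge coefficients -> per-segment activation parameters.
# y = b0 + b1*x + b2*(x - x0)+ with x = 1/T:
#   x > x0 (T below break): slope b1+b2, intercept b0 - b2*x0
#   x < x0 (T above break): slope b1, intercept b0
.hinge_segments <- function(co, T_break, Tref_C) {
  x0 <- 1 / T_break
  b0 <- unname(co[["(Intercept)"]]); b1 <- unname(co[["x"]])
  b2 <- unname(co[["z"]])
  mk <- function(dH, dS) {
    structure(list(
      params = activation_params(dH = dH, dS = dS, Tref_C = Tref_C),
      weighted = NA, sse = NA_real_, se_dH = NA_real_, se_dS = NA_real_,
      n = NA_integer_, data = NULL, lm = NULL
    ), class = "arrhenius_fit")
  }
  list(
    left = mk(dH = b1 + b2, dS = -(b0 - b2 * x0)),
    right = mk(dH = b1, dS = -b0)
  )
}

# re-wrap an internal barrier table in the external column convention
tbl_to_df <- function(tbl) {
  tibble::tibble(
    temperature_C = to_celsius(tbl$T_K),
    dG_mean = tbl$dG_mean,
    dG_sem = tbl$dG_sem,
    n_replicates = tbl$n_replicates
  )
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  if (is.na(x$T_break)) {
    cat("<breakpoint_fit> no break supported\n")
  } else {
    cat(sprintf(
      "<breakpoint_fit> T_break = %.2f K (%.2f C)\n  dH below/above break: %.2f / %.2f kcal/mol\n",
      x$T_break, to_celsius(x$T_break), x$left$params$dH, x$right$params$dH))
  }
  cat(sprintf("  sse two-segment %.4g vs single line %.4g (p = %.3g)\n",
              x$sse_total, x$sse_single_line, x$p_value))
  invisible(x)
}

# barrier at temperature under a (piecewise) linear Eyring model
.barrier_at <- function(object, T_K) {
  if (inherits(object, "activation_params")) return(gibbs_at(object, T_K))
  if (inherits(object, "arrhenius_fit")) return(gibbs_at(object$params, T_K))
  if (inherits(object, "breakpoint_fit")) {
    if (is.na(object$T_break)) return(gibbs_at(object$single$params, T_K))
    ifelse(T_K <= object$T_break,
           gibbs_at(object$left$params, T_K),
           gibbs_at(object$right$params, T_K))
  } else {
    stop("unsupported model object", call. = FALSE)
  }
}

#' Predicted relative rate-constant curve
#'
#' Evaluates the Eyring rate on a temperature grid under a fitted (possibly
#' piecewise) barrier model and normalises to a maximum of exactly 1, the
#' form in which predicted temperature dependences of k_cat are reported.
#'
#' @param object an [activation_params()], `arrhenius_fit` or `breakpoint_fit`.
#' @param T_grid_C temperature grid, Celsius.
#' @return tibble with `temperature_C`, `barrier`, `rel_rate` (max 1).
#' @export
kcat_curve <- function(object, T_grid_C) {
  if (length(T_grid_C) == 0) stop("empty temperature grid", call. = FALSE)
  T_K <- to_kelvin(T_grid_C)
  .check_temperature_K(T_K)
  b <- .barrier_at(object, T_K)
  r <- eyring_rate(b, T_K)
  tibble::tibble(temperature_C = T_grid_C, barrier = b, rel_rate = r / max(r))
}

#' Locate a rate optimum on a temperature grid
#'
#' Argmax of `f` over a uniform Kelvin grid at spacing `resolution_K`;
#' ties break toward the lower temperature for deterministic output.
#'
#' @param f function of temperature (Kelvin) returning a rate.
#' @param lower_K,upper_K window bounds, Kelvin.
#' @param resolution_K grid spacing, Kelvin.
#' @return the optimum temperature, Kelvin.
#' @export
find_optimum <- function(f, lower_K, upper_K, resolution_K = 0.01) {
  stopifnot(resolution_K > 0, upper_K > lower_K)
  grid <- seq(lower_K, upper_K, by = resolution_K)
  if (grid[length(grid)] < upper_K) grid <- c(grid, upper_K)
  v <- f(grid)
  if (any(!is.finite(v))) stop("model returned non-finite rates in window",
                               call. = FALSE)
  grid[which.max(v)]
}
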