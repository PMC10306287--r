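#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods
#'
#' `autoplot()` methods return ggplot objects for each result type: the
#' Eyring-form Arrhenius plot with the fitted line(s), ramp traces with the
#' fitted product-formation curve, Michaelis-Menten saturation curves,
#' distance densities and RMSF profiles.
#'
#' @param object a fitted or estimated object.
#' @param ... unused.
#' @return a ggplot.
#' @name topt-plots
NULL

.arrhenius_points <- function(tbl) {
  tibble::tibble(inv_T = 1 / tbl$T_K, y = tbl$dG_mean / tbl$T_K,
                 sem = tbl$dG_sem / tbl$T_K)
}

#' @rdname topt-plots
#' @method autoplot arrhenius_fit
#' @export
autoplot.arrhenius_fit <- function(object, ...) {
  pts <- .arrhenius_points(object$data)
  line <- tibble::tibble(
    inv_T = seq(min(pts$inv_T), max(pts$inv_T), length.out = 100))
  line$y <- gibbs_at(object$params, 1 / line$inv_T) * line$inv_T
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$inv_T, y = .data$y)) +
    ggplot2::geom_line(data = line, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$y - .data$sem,
                                        ymax = .data$y + .data$sem),
                           width = 0, na.rm = TRUE) +
    ggplot2::labs(x = expression(1 / italic(T) ~ (K^-1)),
                  y = expression(Delta * italic(G)^"‡" / italic(T) ~
                                   (kcal ~ mol^-1 ~ K^-1)))
}

#' @rdname topt-plots
#' @method autoplot breakpoint_fit
#' @export
autoplot.breakpoint_fit <- function(object, ...) {
  pts <- .arrhenius_points(object$data)
  grid_T <- seq(min(object$data$T_K), max(object$data$T_K), length.out = 200)
  line <- tibble::tibble(inv_T = 1 / grid_T,
                         y = .barrier_at(object, grid_T) / grid_T)
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$inv_T, y = .data$y)) +
    ggplot2::geom_line(data = line, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(1 / italic(T) ~ (K^-1)),
                  y = expression(Delta * italic(G)^"‡" / italic(T) ~
                                   (kcal ~ mol^-1 ~ K^-1)))
  if (!is.na(object$T_break)) {
    p <- p + ggplot2::geom_vline(xintercept = 1 / object$T_break,
                                 linetype = "dashed", colour = "firebrick")
  }
  p
}

#' @rdname topt-plots
#' @method autoplot ramp_fit
#' @export
autoplot.ramp_fit <- function(object, ...) {
  d <- object$trace
  d$fitted <- object$fitted
  ggplot2::ggplot(d, ggplot2::aes(x = .data$temperature_C)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$absorbance),
                        size = 0.4, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::geom_vline(xintercept = to_celsius(object$T_opt_K),
                        linetype = "dashed") +
    ggplot2::labs(x = "temperature (°C)", y = "absorbance (A.U.)")
}

#' @rdname topt-plots
#' @method autoplot mm_fit
#' @export
autoplot.mm_fit <- function(object, ...) {
  d <- object$data
  S <- exp(seq(log(min(d$substrate_uM)), log(max(d$substrate_uM)),
               length.out = 200))
  curve <- tibble::tibble(
    substrate_uM = S,
    velocity = object$Vmax * S / (object$KM + S))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$substrate_uM,
                                  y = .data$velocity)) +
    ggplot2::geom_line(data = curve, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "substrate (µM)", y = "initial velocity")
}

#' @rdname topt-plots
#' @method autoplot density_estimate
#' @export
autoplot.density_estimate <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$grid_A, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance (Å)", y = "probability density (1/Å)")
}

#' Plot a relative rate curve
#'
#' @param curve tibble from [kcat_curve()] or [relative_rate_curve()].
#' @return a ggplot.
#' @export
plot_rate_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$temperature_C,
                                      y = .data$rel_rate)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "temperature (°C)",
                  y = expression("relative" ~ italic(k)[cat]))
}

#' Plot one or more RMSF profiles
#'
#' @param ... named RMSF profiles from [rmsf()].
#' @return a ggplot.
#' @export
plot_rmsf <- function(...) {
  profs <- list(...)
  if (is.null(names(profs)) || any(!nzchar(names(profs)))) {
    names(profs) <- paste0("profile", seq_along(profs))
  }
  d <- dplyr::bind_rows(profs, .id = "profile")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$residue, y = .data$rmsf_A,
                                  colour = .data$profile)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "RMSF (Å)", colour = NULL)
}
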