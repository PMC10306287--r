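#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and glance methods for fitted objects
#'
#' `tidy()` returns one row per parameter with estimates and standard errors;
#' `glance()` returns a one-row model summary.
#'
#' @param x a fitted object (`arrhenius_fit`, `breakpoint_fit`, `ramp_fit`
#'   or `mm_fit`).
#' @param ... unused.
#' @return a tibble.
#' @name topt-tidiers
NULL

#' @rdname topt-tidiers
#' @method tidy arrhenius_fit
#' @export
tidy.arrhenius_fit <- function(x, ...) {
  tibble::tibble(
    term = c("dH", "dS", "TdS_ref"),
    estimate = c(x$params$dH, x$params$dS, x$params$Tref * x$params$dS),
    std.error = c(x$se_dH, x$se_dS,
                  if (is.na(x$se_dS)) NA_real_ else x$params$Tref * x$se_dS)
  )
}

#' @rdname topt-tidiers
#' @method glance arrhenius_fit
#' @export
glance.arrhenius_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, n = x$n, weighted = isTRUE(x$weighted),
                 Tref_C = to_celsius(x$params$Tref))
}

#' @rdname topt-tidiers
#' @method tidy breakpoint_fit
#' @export
tidy.breakpoint_fit <- function(x, ...) {
  tibble::tibble(
    segment = c("below_break", "above_break"),
    dH = c(x$left$params$dH, x$right$params$dH),
    dS = c(x$left$params$dS, x$right$params$dS)
  )
}

#' @rdname topt-tidiers
#' @method glance breakpoint_fit
#' @export
glance.breakpoint_fit <- function(x, ...) {
  tibble::tibble(
    T_break_K = x$T_break,
    T_break_C = to_celsius(x$T_break),
    sse_total = x$sse_total,
    sse_single_line = x$sse_single_line,
    p_value = x$p_value,
    n = x$n
  )
}

#' @rdname topt-tidiers
#' @method tidy ramp_fit
#' @export
tidy.ramp_fit <- function(x, ...) {
  se <- sqrt(pmax(diag(x$vcov), 0))
  tibble::tibble(term = names(x$theta), estimate = unname(x$theta),
                 std.error = unname(se))
}

#' @rdname topt-tidiers
#' @method glance ramp_fit
#' @export
glance.ramp_fit <- function(x, ...) {
  tibble::tibble(
    T_opt_K = x$T_opt_K,
    T_opt_C = to_celsius(x$T_opt_K),
    rss = x$rss,
    converged = x$converged,
    n_starts_used = x$n_starts_used,
    n = x$n
  )
}

#' @rdname topt-tidiers
#' @method tidy mm_fit
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kcat", "KM"),
    estimate = c(x$kcat, x$KM),
    std.error = c(x$se_kcat, x$se_KM)
  )
}

#' @rdname topt-tidiers
#' @method glance mm_fit
#' @export
glance.mm_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, n = x$n, E0_nM = x$E0_nM)
}
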