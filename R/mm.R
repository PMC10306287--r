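#' Michaelis-Menten initial velocity
#'
#' \eqn{v = k_{cat} [E]_0 S / (K_M + S)}. With `kcat` in 1/min, `E0_nM` in nM
#' and substrate in uM, the velocity comes out in uM/min.
#'
#' @param kcat turnover number, 1/min.
#' @param KM Michaelis constant, uM.
#' @param E0_nM total enzyme concentration, nM.
#' @param S_uM substrate concentration(s), uM.
#' @return initial velocity, uM/min.
#' @examples
#' mm_velocity(107, 300, 60, 300)  # half-saturation: kcat*E0/2
#' @export
mm_velocity <- function(kcat, KM, E0_nM, S_uM) {
  if (any(c(kcat, KM, E0_nM) <= 0) || any(S_uM <= 0)) {
    stop("kcat, KM, E0 and substrate concentrations must be positive",
         call. = FALSE)
  }
  kcat * (E0_nM / 1000) * S_uM / (KM + S_uM)
}

#' Two-fold substrate dilution series
#'
#' @param top_uM highest substrate concentration, uM.
#' @param n_levels number of two-fold dilutions (13 spans 5000 to ~1.22 uM).
#' @return numeric vector of concentrations, uM, decreasing.
#' @export
mm_dilution_series <- function(top_uM = 5000, n_levels = 13) {
  top_uM / 2^(seq_len(n_levels) - 1)
}

#' Simulate a steady-state kinetics dataset
#'
#' Multiplicative Gaussian noise with coefficient of variation `cv` on exact
#' Michaelis-Menten velocities; deterministic for a given seed.
#'
#' @inheritParams mm_velocity
#' @param S_levels_uM substrate design (default the two-fold series
#'   5000 to 1.22 uM).
#' @param cv coefficient of variation of the velocity noise.
#' @param n_reps replicates per substrate level.
#' @param seed integer seed.
#' @return tibble `substrate_uM`, `velocity` (uM/min), `replicate`.
#' @export
simulate_mm <- function(kcat, KM, E0_nM = 60,
                        S_levels_uM = mm_dilution_series(),
                        cv = 0.02, n_reps = 3, seed = NULL) {
  stopifnot(cv >= 0, n_reps >= 1)
  grid <- tidyr::expand_grid(substrate_uM = S_levels_uM,
                             replicate = seq_len(n_reps))
  v0 <- mm_velocity(kcat, KM, E0_nM, grid$substrate_uM)
  .with_seed(seed, {
    eps <- if (cv > 0) stats::rnorm(nrow(grid), 0, cv) else 0
    tibble::tibble(substrate_uM = grid$substrate_uM,
                   velocity = v0 * (1 + eps),
                   replicate = grid$replicate)
  })
}

#' Fit Michaelis-Menten kinetics
#'
#' Nonlinear least squares of \eqn{v = V_{max} S/(K_M+S)} with robust
#' starting values (\eqn{K_M} = median substrate, \eqn{V_{max}} = max
#' velocity); `kcat` is reported as \eqn{V_{max} \cdot c / [E]_0}, where `c`
#' is a velocity-unit conversion factor (1 when velocities are uM/min).
#'
#' @param data data frame `substrate_uM`, `velocity` (optionally `replicate`).
#' @param E0_nM enzyme concentration, nM.
#' @param conversion multiplicative factor taking the supplied velocity units
#'   to uM/min (default 1; use it when velocities are raw absorbance rates).
#' @return an `mm_fit` with `kcat` (1/min), `KM` (uM), standard errors, `sse`.
#' @export
fit_mm <- function(data, E0_nM = 60, conversion = 1) {
  need <- c("substrate_uM", "velocity")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  S <- data$substrate_uM
  v <- data$velocity
  if (any(S <= 0)) stop("substrate concentrations must be positive", call. = FALSE)
  if (length(unique(S)) < 4) {
    stop("insufficient design: need >= 4 distinct substrate levels", call. = FALSE)
  }
  df <- data.frame(S = S, v = v)
  fit <- minpack.lm::nlsLM(
    v ~ Vmax * S / (KM + S), data = df,
    start = list(Vmax = max(v), KM = stats::median(S)),
    lower = c(Vmax = 1e-12, KM = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14)
  )
  co <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) c(NA, NA))
  E0_uM <- E0_nM / 1000
  scale <- conversion / E0_uM
  if (co[["KM"]] > max(S)) {
    warning("ill-conditioned design: fitted KM exceeds the largest substrate ",
            "concentration; standard errors are inflated", call. = FALSE)
  }
  structure(list(
    kcat = unname(co[["Vmax"]]) * scale,
    KM = unname(co[["KM"]]),
    Vmax = unname(co[["Vmax"]]),
    se_kcat = unname(se[["Vmax"]]) * scale,
    se_KM = unname(se[["KM"]]),
    sse = sum(stats::resid(fit)^2),
    E0_nM = E0_nM,
    n = nrow(df),
    nls = fit,
    data = tibble::as_tibble(data)
  ), class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf(
    "<mm_fit> kcat = %.2f +/- %.2f 1/min, KM = %.1f +/- %.1f uM (E0 = %g nM, n = %d)\n",
    x$kcat, x$se_kcat, x$KM, x$se_KM, x$E0_nM, x$n))
  invisible(x)
}
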