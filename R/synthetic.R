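#' Generate a synthetic per-temperature barrier series
#'
#' Emulates the product of replicated free-energy simulations: at each
#' temperature, `n_replicates` activation free energies are drawn
#' Normal(line value, `sem * sqrt(n_replicates)`), so that the per-temperature
#' mean has standard deviation `sem` and the realised SEM estimates `sem`.
#' A second, steeper segment can be attached with a continuous hinge at
#' `break_at_C` to emulate the onset of inactivation.
#'
#' @param params an [activation_params()] generating the (low-temperature)
#'   line \eqn{\Delta G^\ddagger(T) = \Delta H^\ddagger - T\Delta S^\ddagger}.
#' @param temperatures_C simulation temperatures (default 20--45 C in 5 C
#'   steps, six points).
#' @param sem target standard error of the per-temperature mean, kcal/mol;
#'   scalar or one value per temperature. `sem = 0` puts the means exactly
#'   on the generating line.
#' @param n_replicates replicates per temperature (default 120).
#' @param seed integer seed.
#' @param break_at_C optional hinge temperature (Celsius) above which the
#'   slope changes to `dH_high`.
#' @param dH_high activation enthalpy of the high-temperature segment,
#'   kcal/mol (required with `break_at_C`).
#' @param long return replicate-level rows (`temperature_C, replicate, dG`)
#'   instead of per-temperature summaries.
#' @return tibble `temperature_C, dG_mean, dG_sem, n_replicates` (or the
#'   long form).
#' @examples
#' p <- activation_params(dH = 11.0, TdS = -1.7)
#' gen_barrier_series(p, sem = 0.25, seed = 1)
#' @export
gen_barrier_series <- function(params,
                               temperatures_C = seq(20, 45, by = 5),
                               sem = 0.25, n_replicates = 120, seed = NULL,
                               break_at_C = NULL, dH_high = NULL,
                               long = FALSE) {
  stopifnot(inherits(params, "activation_params"), all(sem >= 0),
            n_replicates >= 1)
  sem <- rep_len(sem, length(temperatures_C))
  T_K <- to_kelvin(temperatures_C)
  line <- gibbs_at(params, T_K)
  if (!is.null(break_at_C)) {
    stopifnot(!is.null(dH_high))
    Tb <- to_kelvin(break_at_C)
    # continuity of dG/T vs 1/T at the hinge: dS_high = dS + (dH_high - dH)/Tb
    dS_high <- params$dS + (dH_high - params$dH) / Tb
    high <- dH_high - T_K * dS_high
    line <- ifelse(T_K <= Tb, line, high)
  }
  .with_seed(seed, {
    reps <- purrr::map2(line, sem, function(mu, s) {
      if (s == 0) rep(mu, n_replicates)
      else stats::rnorm(n_replicates, mu, s * sqrt(n_replicates))
    })
    if (long) {
      tibble::tibble(
        temperature_C = rep(temperatures_C, each = n_replicates),
        replicate = rep(seq_len(n_replicates), length(temperatures_C)),
        dG = unlist(reps)
      )
    } else {
      tibble::tibble(
        temperature_C = temperatures_C,
        dG_mean = vapply(reps, mean, numeric(1)),
        dG_sem = vapply(reps, function(r) stats::sd(r) / sqrt(length(r)),
                        numeric(1)),
        n_replicates = n_replicates
      )
    }
  })
}

# published scenario table: activity optimum (C) and activation enthalpy of
# the chemical step (kcal/mol; tabulated activation parameters where
# available, a fixture choice of 10 for the loop-graft variant)
.RAMP_SCENARIOS <- list(
  aha       = list(t_opt_C = 39, dH_rxn = 8.3),
  loopgraft = list(t_opt_C = 41, dH_rxn = 10.0),
  chimera4  = list(t_opt_C = 45, dH_rxn = 11.0),
  ppa       = list(t_opt_C = 58, dH_rxn = 11.5)
)

#' Generate a named temperature-ramp scenario
#'
#' Builds an [inactivation_model()] whose noiseless velocity argmax sits at
#' the scenario's published activity optimum (via
#' [solve_entropy_for_optimum()]), then simulates a 10 C/min ramp trace from
#' 10 to 70 C at 1 s sampling. Scenarios: `"AHA"` (wild-type psychrophile,
#' optimum 39 C), `"LoopGraft"` (+2 C), `"Chimera4"` (+6 C, optimum 45 C)
#' and `"PPA"` (mesophile, 58 C).
#'
#' @param name scenario name (case-insensitive).
#' @param seed integer seed for the trace noise.
#' @param noise_cv multiplicative trace noise (default 0.5%).
#' @param dH_inact inactivation enthalpy, kcal/mol (default 100, a typical
#'   scale for cooperative conformational equilibria).
#' @param protocol a [ramp_protocol()]; the default covers 10--70 C at
#'   10 C/min.
#' @return list with `model`, `trace`, `t_opt_C` (the placed optimum) and
#'   `name`.
#' @export
gen_ramp_scenario <- function(name = c("AHA", "LoopGraft", "Chimera4", "PPA"),
                              seed = NULL, noise_cv = 0.005, dH_inact = 100,
                              protocol = ramp_protocol(T_start_C = 10,
                                                       rate_C_per_min = 10,
                                                       duration_s = 360,
                                                       sample_dt_s = 1)) {
  key <- tolower(if (length(name) > 1) name[1] else name)
  if (!key %in% names(.RAMP_SCENARIOS)) {
    stop("unknown scenario: ", name, call. = FALSE)
  }
  sc <- .RAMP_SCENARIOS[[key]]
  T_opt <- to_kelvin(sc$t_opt_C)
  dS_inact <- solve_entropy_for_optimum(sc$dH_rxn, dH_inact, T_opt)
  m0 <- inactivation_model(dH_rxn = sc$dH_rxn, dS_rxn = 0,
                           dH_inact = dH_inact, dS_inact = dS_inact,
                           amplitude = 1)
  # scale so the peak velocity is ~5e-3 AU/s (order-1 final absorbance)
  amp <- 5e-3 / velocity(m0, T_opt)
  model <- inactivation_model(dH_rxn = sc$dH_rxn, dS_rxn = 0,
                              dH_inact = dH_inact, dS_inact = dS_inact,
                              amplitude = amp)
  trace <- simulate_ramp(model, protocol, noise_cv = noise_cv, seed = seed)
  list(model = model, trace = trace, t_opt_C = sc$t_opt_C, name = name)
}

#' Generate a two-state hydrogen-bond distance series
#'
#' Gaussian mixture of an intact (active) state at ~2.8 A and a broken
#' (inactive) state, truncated at zero by resampling.
#'
#' @param n number of frames (must be positive).
#' @param fraction_active mixture weight of the active state, in \[0, 1\].
#' @param active_mean_A,inactive_mean_A component means, A.
#' @param active_sd_A,inactive_sd_A component standard deviations, A.
#' @param seed integer seed.
#' @return tibble `frame`, `distance_A`.
#' @export
gen_distance_series <- function(n, fraction_active = 0.5,
                                active_mean_A = 2.8, inactive_mean_A = 5.0,
                                active_sd_A = 0.15, inactive_sd_A = 0.30,
                                seed = NULL) {
  if (!is.numeric(n) || n < 1) stop("n must be a positive count", call. = FALSE)
  stopifnot(fraction_active >= 0, fraction_active <= 1)
  .with_seed(seed, {
    active <- stats::runif(n) < fraction_active
    mu <- ifelse(active, active_mean_A, inactive_mean_A)
    s <- ifelse(active, active_sd_A, inactive_sd_A)
    d <- stats::rnorm(n, mu, s)
    while (any(d <= 0)) {
      bad <- d <= 0
      d[bad] <- stats::rnorm(sum(bad), mu[bad], s[bad])
    }
    tibble::tibble(frame = seq_len(n), distance_A = d)
  })
}

# fixed fold-like backbone scaffold: helical CA trace with offset N, C, O
.scaffold <- function(n_residues) {
  i <- seq_len(n_residues)
  ca <- cbind(2.3 * cos(i * 100 * pi / 180),
              2.3 * sin(i * 100 * pi / 180),
              1.5 * i)
  offs <- list(N = c(-1.2, 0.4, -0.6), CA = c(0, 0, 0),
               C = c(1.2, 0.3, 0.5), O = c(1.6, 1.2, 0.9))
  do.call(rbind, lapply(i, function(r) {
    t(vapply(.BACKBONE, function(a) ca[r, ] + offs[[a]], numeric(3)))
  }))
}

.random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a synthetic backbone trajectory with a prescribed RMSF profile
#'
#' Backbone atoms (N, CA, C, O) of each residue are jittered isotropically
#' about a fixed fold-like scaffold with per-axis standard deviation
#' \eqn{\sigma_r = \mathrm{rmsf}_r / \sqrt{3}}, so that the recovered RMSF
#' equals the prescribed profile. Optional per-frame random rigid-body
#' motion exercises the superposition step.
#'
#' @param rmsf_profile_A per-residue target RMSF, A (positive; its length
#'   sets the number of residues).
#' @param n_frames number of frames (>= 2).
#' @param seed integer seed.
#' @param rigid_motion apply a random global rotation and translation to
#'   each frame.
#' @return long trajectory tibble `frame, atom, residue, name, x, y, z`
#'   (attribute `superposed = FALSE`).
#' @export
gen_trajectory <- function(rmsf_profile_A, n_frames = 200, seed = NULL,
                           rigid_motion = FALSE) {
  stopifnot(all(rmsf_profile_A >= 0), n_frames >= 2)
  nres <- length(rmsf_profile_A)
  base <- .scaffold(nres)
  na <- nrow(base)
  sigma <- rep(rmsf_profile_A, each = length(.BACKBONE)) / sqrt(3)
  .with_seed(seed, {
    # all jitter is drawn before any rigid-body draws, so a given seed yields
    # the same internal structure with and without rigid_motion
    frames <- lapply(seq_len(n_frames), function(f) {
      base + matrix(stats::rnorm(na * 3, 0, sigma), na, 3)
    })
    if (rigid_motion) {
      frames <- lapply(frames, function(xyz) {
        xyz %*% .random_rotation() +
          matrix(stats::runif(3, -5, 5), na, 3, byrow = TRUE)
      })
    }
    out <- tibble::tibble(
      frame = rep(seq_len(n_frames), each = na),
      atom = rep(seq_len(na), n_frames),
      residue = rep(rep(seq_len(nres), each = length(.BACKBONE)), n_frames),
      name = rep(rep(.BACKBONE, nres), n_frames),
      x = unlist(lapply(frames, function(m) m[, 1])),
      y = unlist(lapply(frames, function(m) m[, 2])),
      z = unlist(lapply(frames, function(m) m[, 3]))
    )
    attr(out, "superposed") <- !rigid_motion
    out
  })
}
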