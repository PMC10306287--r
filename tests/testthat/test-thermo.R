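# Eyring/Arrhenius core: barriers, rates, regression

test_that("gibbs_at is the linear enthalpy/entropy decomposition", {
  # tabulated activation parameters: dH, TdS at 15 C -> dG at 15 C
  rows <- list(
    list(dH = 11.0, TdS = -1.7, dG = 12.7),
    list(dH = 11.5, TdS = -2.5, dG = 14.0),
    list(dH = 10.8, TdS = -4.3, dG = 15.1),
    list(dH = 8.3,  TdS = -5.1, dG = 13.4),
    list(dH = 6.5,  TdS = -6.6, dG = 13.1)
  )
  for (r in rows) {
    p <- activation_params(dH = r$dH, TdS = r$TdS)
    expect_equal(gibbs_at(p, to_kelvin(15)), r$dG, tolerance = 1e-12)
  }
  # zero entropy: barrier is temperature-independent
  p0 <- activation_params(dH = 9.3, dS = 0)
  expect_equal(gibbs_at(p0, c(280, 310, 340)), rep(9.3, 3))
  # exact linearity in T
  p <- activation_params(dH = 11, TdS = -1.7)
  Ts <- seq(270, 360, by = 7)
  expect_equal(diff(gibbs_at(p, Ts), differences = 2), rep(0, length(Ts) - 2),
               tolerance = 1e-12)
  expect_error(gibbs_at(p, -5), "positive")
  expect_error(activation_params(dH = 1, TdS = -1, dS = -0.01), "exactly one")
})

test_that("eyring_rate has the k_B T/h prefactor and Boltzmann barrier factor", {
  expect_equal(eyring_rate(0, 298.15), 1.380649e-23 / 6.62607015e-34 * 298.15,
               tolerance = 1e-12)
  expect_equal(eyring_rate(0, 298.15), 6.212e12, tolerance = 1e-4)
  # barriers differing by R T ln 2 -> exact factor of 2
  T <- 310
  b <- 12
  expect_equal(eyring_rate(b, T) / eyring_rate(b + R_KCAL * T * log(2), T), 2,
               tolerance = 1e-12)
  # general ratio identity over random barrier pairs
  set.seed(1)
  for (i in 1:20) {
    b1 <- runif(1, 5, 20); b2 <- runif(1, 5, 20); T <- runif(1, 280, 340)
    expect_equal(eyring_rate(b1, T) / eyring_rate(b2, T),
                 exp((b2 - b1) / (R_KCAL * T)), tolerance = 1e-10)
  }
  expect_error(eyring_rate(10, 0), "positive")
  # inverse round trip
  expect_equal(barrier_from_rate(eyring_rate(13.1, 288.15), 288.15), 13.1,
               tolerance = 1e-10)
})

test_that("fit_arrhenius recovers generating parameters from noiseless data", {
  p <- activation_params(dH = 11.0, TdS = -1.7)
  d <- gen_barrier_series(p, temperatures_C = c(20, 25, 30, 35), sem = 0)
  fit <- fit_arrhenius(d)
  expect_equal(fit$params$dH, 11.0, tolerance = 1e-9)
  expect_equal(fit$params$Tref * fit$params$dS, -1.7, tolerance = 1e-9)
  expect_lt(fit$sse, 1e-20)
  # arbitrary generating parameters round-trip the same way
  p2 <- activation_params(dH = 6.5, TdS = -6.6)
  d2 <- gen_barrier_series(p2, temperatures_C = seq(5, 45, 10), sem = 0)
  f2 <- fit_arrhenius(d2)
  expect_equal(f2$params$dH, 6.5, tolerance = 1e-9)
  expect_equal(f2$params$Tref * f2$params$dS, -6.6, tolerance = 1e-9)
})

test_that("two points give the exact interpolating line", {
  p <- activation_params(dH = 8, TdS = -3)
  d <- gen_barrier_series(p, temperatures_C = c(10, 50), sem = 0)
  fit <- fit_arrhenius(d)
  expect_equal(fit$sse, 0, tolerance = 1e-25)
  expect_equal(fit$params$dH, 8, tolerance = 1e-9)
  expect_error(fit_arrhenius(d[1, ]), "insufficient")
})

test_that("equal SEMs reproduce the unweighted estimates; zero SEM weighting errors", {
  p <- activation_params(dH = 11.0, TdS = -1.7)
  d <- gen_barrier_series(p, temperatures_C = seq(20, 45, 5), sem = 0.2, seed = 4)
  d$dG_sem <- 0.2 # exactly constant
  fw <- fit_arrhenius(d, weighted = TRUE)
  fu <- fit_arrhenius(d, weighted = FALSE)
  expect_equal(fw$params$dH, fu$params$dH, tolerance = 1e-10)
  expect_equal(fw$params$dS, fu$params$dS, tolerance = 1e-10)
  d$dG_sem[2] <- 0
  expect_error(fit_arrhenius(d, weighted = TRUE), "zero")
})

test_that("replicate-level input matches precomputed summaries", {
  p <- activation_params(dH = 11.0, TdS = -1.7)
  long <- gen_barrier_series(p, temperatures_C = c(20, 30, 40), sem = 0.2,
                             n_replicates = 50, seed = 8, long = TRUE)
  wide <- long |>
    dplyr::group_by(temperature_C) |>
    dplyr::summarise(dG_mean = mean(dG), dG_sem = sd(dG) / sqrt(dplyr::n()),
                     n_replicates = dplyr::n(), .groups = "drop")
  f1 <- fit_arrhenius(long)
  f2 <- fit_arrhenius(wide)
  expect_equal(f1$params$dH, f2$params$dH, tolerance = 1e-12)
})

test_that("mean fitted enthalpy is unbiased over many noisy series", {
  p <- activation_params(dH = 11.0, TdS = -1.7)
  dh <- vapply(1:200, function(s) {
    d <- gen_barrier_series(p, temperatures_C = c(20, 25, 30, 35), sem = 0.2,
                            seed = s)
    fit_arrhenius(d)$params$dH
  }, numeric(1))
  mc_se <- sd(dh) / sqrt(length(dh))
  expect_lt(abs(mean(dh) - 11.0), 3 * mc_se)
})

test_that("kcat_curve is max-normalised and piecewise-consistent", {
  p <- activation_params(dH = 11.0, TdS = -1.7)
  cv <- kcat_curve(p, seq(5, 45, 5))
  expect_equal(max(cv$rel_rate), 1)
  expect_true(all(cv$rel_rate > 0 & cv$rel_rate <= 1))
  # positive dH: monotone increasing, max at the highest grid temperature
  expect_true(all(diff(cv$rel_rate) > 0))
  expect_equal(which.max(cv$rel_rate), nrow(cv))
  # grid of one -> exactly 1
  expect_equal(kcat_curve(p, 25)$rel_rate, 1)
  expect_error(kcat_curve(p, numeric(0)), "empty")
  # two-segment model with steep second segment: interior max at the hinge
  d2 <- gen_barrier_series(p, sem = 0.02, seed = 3, break_at_C = 40,
                           dH_high = -60)
  bk <- detect_break(d2)
  grid <- seq(20, 45, by = 0.5)
  cv2 <- kcat_curve(bk, grid)
  # independent grid-argmax oracle: direct Eyring rates on the piecewise model
  oracle <- eyring_rate(ifelse(to_kelvin(grid) <= bk$T_break,
                               gibbs_at(bk$left$params, to_kelvin(grid)),
                               gibbs_at(bk$right$params, to_kelvin(grid))),
                        to_kelvin(grid))
  expect_equal(cv2$rel_rate, oracle / max(oracle), tolerance = 1e-12)
  expect_equal(grid[which.max(cv2$rel_rate)], to_celsius(bk$T_break),
               tolerance = 1)
  # shifting every barrier by a constant rescales rates but the curve stays
  # max-normalised at exactly 1
  shifted <- kcat_curve(activation_params(dH = 11 + 3, TdS = -1.7), seq(5, 45, 5))
  expect_equal(max(shifted$rel_rate), 1)
})

test_that("find_optimum locates grid maxima with low-T tie-breaking", {
  # quadratic with known maximum
  f <- function(T) -(T - 310)^2 + 5
  expect_equal(find_optimum(f, 280, 340, 0.01), 310, tolerance = 0.011)
  # strictly increasing -> upper bound
  expect_equal(find_optimum(function(T) T, 280, 340, 0.5), 340)
  # plateau ties break toward the lower temperature
  expect_equal(find_optimum(function(T) pmin(T, 300), 280, 340, 1), 300)
  expect_error(find_optimum(function(T) rep(NaN, length(T)), 280, 340, 1),
               "non-finite")
})
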