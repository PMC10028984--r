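test_that("light-to-ERK map saturates and is monotone", {
  p <- circuit_params()
  expect_equal(erk_from_light(0, 1, p), 0)
  expect_gt(erk_from_light(1e6, 1, p), 0.999)          # saturation limit
  doses <- c(0.05, 0.125, 0.3, 0.6, 1, 2)
  E <- erk_from_light(doses, 1, p)
  expect_true(all(diff(E) > 0))
  expect_true(all(E >= 0 & E < 1))
  # an 8-fold intensity difference maps to a sub-8-fold ERK difference
  expect_lt(erk_from_light(1, 1, p) / erk_from_light(0.125, 1, p), 8)
  # monotone in the embryo-specific scale too
  expect_gt(erk_from_light(0.5, 1.3, p), erk_from_light(0.5, 1, p))
  expect_error(erk_from_light(-0.1, 1, p), "intensity")
})

test_that("onset_time matches the constant-input closed form", {
  p <- flat_params()
  sch <- flat_schedule()
  t <- seq(0, 200, 0.1)
  for (A in c(0.2, 0.5, 0.9)) {
    for (theta in c(1, 7, 19)) {
      on <- onset_time(rep(A, length(t)), t, theta, sch, p)
      expect_equal(on, theta / A + p$tau_latency, tolerance = 1e-6)
    }
  }
  # zero threshold: onset at first interphase time + latency
  expect_equal(onset_time(rep(0.5, length(t)), t, 0, sch, p),
               p$tau_latency)
  # null input never crosses
  expect_identical(onset_time(rep(0, length(t)), t, 1, sch, p), Inf)
})

test_that("onset snaps forward through mitosis and respects the NC14 window", {
  p <- circuit_params()
  sch <- nc_schedule()
  t <- seq(0, 93, 0.1)
  # crossing during NC10->NC11 mitosis snaps to the NC11 start
  A <- 1 / 2  # theta_tll/A + latency lands in the 2.5-7 min gap
  on <- onset_time(rep(A, length(t)), t, p$theta_tll, sch, p)
  expect_equal(on, interphase_bounds(sch, 11)[1])
  # a crossing after window close is "never"
  A_slow <- p$theta_hkb / 70
  expect_identical(onset_time(rep(A_slow, length(t)), t, p$theta_hkb, sch, p),
                   Inf)
})

test_that("cumulative dose is exchange-symmetric for (A,T) <-> (A/2, 2T)", {
  p <- flat_params()
  sch <- flat_schedule()
  t <- seq(0, 200, 0.1)
  # grid-aligned steps with the midpoint value at the jump, so the
  # trapezoidal dose equals the continuous integral exactly
  step_input <- function(A, Tdur) {
    E <- ifelse(t < Tdur, A, 0)
    E[abs(t - Tdur) < 1e-9] <- A / 2
    E
  }
  trapz_total <- function(E) sum((E[-1] + E[-length(E)]) / 2 * 0.1)
  for (seed in 1:5) {
    withr::with_seed(seed, {
      A <- stats::runif(1, 0.3, 1)
      Tdur <- round(stats::runif(1, 20, 60), 1)
    })
    E1 <- step_input(A, Tdur)
    E2 <- step_input(A / 2, 2 * Tdur)
    expect_equal(trapz_total(E1), A * Tdur, tolerance = 1e-9)
    expect_equal(trapz_total(E1), trapz_total(E2), tolerance = 1e-9)
    # the crossing happens at the same cumulative dose under both inputs,
    # so raw onsets scale exactly as 1/amplitude
    theta <- 0.8 * A * Tdur
    o1 <- onset_time(E1, t, theta, sch, p)
    o2 <- onset_time(E2, t, theta, sch, p)
    expect_true(is.finite(o1) && is.finite(o2))
    expect_equal(o2 - p$tau_latency, 2 * (o1 - p$tau_latency),
                 tolerance = 1e-6)
    # an unattainable dose is unattainable under both
    theta_hi <- 1.2 * A * Tdur
    expect_identical(is.finite(onset_time(E1, t, theta_hi, sch, p)),
                     is.finite(onset_time(E2, t, theta_hi, sch, p)))
  }
})

test_that("repressor onset is monotone in amplitude and never precedes the activator", {
  sch <- nc_schedule()
  p <- circuit_params()
  withr::with_seed(7, {
    for (i in 1:5) {
      amps <- sort(stats::runif(8, 0.05, 1), decreasing = TRUE)
      cv <- hkb_delay_curve(amps, sch, p)
      fin <- cv$hkb_onset[is.finite(cv$hkb_onset)]
      expect_true(all(diff(fin) >= -1e-9))  # non-decreasing as amplitude falls
      expect_true(all(cv$tll_onset <= cv$hkb_onset))
      fin_t <- cv$tll_onset[is.finite(cv$tll_onset)]
      expect_true(all(diff(fin_t) >= -1e-9))
    }
  })
})

test_that("threshold is recoverable from the onset-vs-1/amplitude slope", {
  sch <- nc_schedule()
  p <- circuit_params()
  curve <- hkb_delay_curve(amplitude_sweep(p), sch, p)
  fit <- stats::lm(hkb_onset ~ I(1 / amplitude),
                   data = curve[is.finite(curve$hkb_onset), ])
  slope <- stats::coef(fit)[["I(1/amplitude)"]]
  expect_lt(abs(slope - p$theta_hkb) / p$theta_hkb, 0.1)
})

test_that("simulated scenarios reproduce the transient/sustained dichotomy", {
  sch <- nc_schedule()
  p <- circuit_params()
  hi <- simulate_embryo(build_scenario("high_continuous", sch), params = p)
  lo <- simulate_embryo(build_scenario("low_continuous", sch), params = p)
  c_hi <- classify_byn_dynamics(hi, sch)
  c_lo <- classify_byn_dynamics(lo, sch)
  expect_identical(c_hi$class, "transient")
  expect_identical(c_lo$class, "sustained")
  expect_gte(c_lo$duration, 25)
  expect_lte(c_hi$duration, 15)
  # under high light the output is one contiguous NC14 interval
  b14 <- interphase_bounds(sch, 14)
  on14 <- hi$x_byn[hi$t >= b14[1] & hi$t < b14[2]]
  runs <- rle(on14)
  expect_equal(sum(runs$values == 1), 1)
  expect_equal(hi$t[which(hi$x_byn == 1 & hi$t >= b14[1])[1]], b14[1])
})

test_that("the dark scenario is fully silent", {
  sch <- nc_schedule()
  tr <- simulate_embryo(build_scenario("dark", sch), params = circuit_params())
  expect_true(all(tr$x_tll == 0 & tr$x_hkb == 0 & tr$x_byn == 0))
  expect_true(all(tr$P_T == 0 & tr$P_H == 0))
  expect_true(all(tr$E == 0 & tr$W == 0))
})

test_that("trajectory invariants: dose never decreases, gates hold pointwise", {
  sch <- nc_schedule()
  p <- circuit_params()
  for (nm in c("high_continuous", "low_continuous", "high_pulse_NC10_13",
               "high_from_NC13")) {
    tr <- simulate_embryo(build_scenario(nm, sch), params = p)
    expect_true(all(diff(tr$W) >= -1e-12))
    expect_true(all(tr$P_T >= 0 & tr$P_H >= 0))
    # indicators silent during mitosis and after the sensitivity window
    mitosis <- !in_interphase(tr$t, sch)
    expect_true(all(tr$x_tll[mitosis] == 0 & tr$x_hkb[mitosis] == 0))
    late <- tr$t > interphase_bounds(sch, 14)[1] + p$window_close
    expect_true(all(tr$x_tll[late] == 0 & tr$x_hkb[late] == 0))
    # byn gate: on implies activator above and repressor below threshold
    on <- tr$x_byn == 1
    expect_true(all(tr$P_T[on] > p$theta_T_on))
    expect_true(all(tr$P_H[on] < p$theta_H_off))
  }
})

test_that("ERK relaxes off within 3 tau_cic of light removal", {
  sch <- nc_schedule()
  p <- circuit_params()
  tr <- simulate_embryo(build_scenario("high_pulse_NC10_13", sch), params = p)
  off_t <- 45
  E_lit <- tr$E[which.min(abs(tr$t - off_t))]
  E_after <- tr$E[which.min(abs(tr$t - (off_t + 3 * p$tau_cic)))]
  expect_lt(E_after, 0.05 * E_lit)
  # first-order decay matches the closed form on the grid
  idx <- tr$t > off_t & tr$t < off_t + 2
  pred <- E_lit * exp(-(tr$t[idx] - off_t) / p$tau_cic)
  expect_equal(tr$E[idx], pred, tolerance = 1e-6)
})

test_that("the NC10-13 pulse freezes the dose and de-represses the output", {
  sch <- nc_schedule()
  p <- circuit_params()
  tr <- simulate_embryo(build_scenario("high_pulse_NC10_13", sch), params = p)
  W45 <- tr$W[which.min(abs(tr$t - 45))]
  W_end <- max(tr$W)
  expect_lt(W_end - W45, p$tau_cic * 1.1)  # only the relaxation tail accrues
  # repressor protein stops accumulating at light-off, so byn persists
  expect_lt(max(tr$P_H), p$theta_H_off)
  b14 <- interphase_bounds(sch, 14)
  expect_true(all(tr$x_byn[tr$t >= b14[1] &
                             tr$t < sch$gastrulation_time] == 1))
})

test_that("late-start stimuli separate dose-delay from a developmental timer", {
  sch <- nc_schedule()
  p <- circuit_params()
  n13 <- simulate_embryo(build_scenario("high_from_NC13", sch), params = p)
  n14 <- simulate_embryo(build_scenario("high_from_NC14", sch), params = p)
  expect_true(is.finite(attr(n13, "onset_hkb")))
  expect_true(attr(n13, "onset_hkb") >= interphase_bounds(sch, 14)[1])
  expect_identical(attr(n14, "onset_hkb"), Inf)
  # the activator still responds promptly to the NC14-start stimulus
  expect_lt(attr(n14, "onset_tll") - 48, 4)
})

test_that("too-coarse integration steps are refused", {
  expect_error(simulate_embryo(build_scenario("dark"), dt = 0.5), "0.25")
})

test_that("parameter validation enforces the threshold ordering", {
  expect_error(circuit_params(theta_tll = 5, theta_hkb = 4), "theta_hkb")
  expect_error(circuit_params(k_dec_T = -1), ">= 0")
})
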