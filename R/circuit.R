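#' Parameters of the cumulative-dose incoherent feedforward loop
#'
#' The circuit converts a light input into an ERK amplitude through a
#' saturating (Hill) map, integrates ERK over time into a cumulative dose,
#' and switches on transcription of the activating branch (tll) and the
#' repressing branch (hkb) when the dose crosses gene-specific thresholds.
#' Because the repressor threshold is much larger, its onset time scales as
#' `theta_hkb / amplitude`: the circuit converts amplitude differences into a
#' dose-dependent transcriptional delay. Proteins accumulate from the
#' transcription indicators with first-order kinetics, and the output gene
#' (byn) transcribes whenever activator protein is present and repressor
#' protein is still below its effective level.
#'
#' Default values are the output of [calibrate_circuit()] against the
#' printed timing anchors of the study (see the methods vignette); they are
#' also shipped in `inst/extdata/calibration.json`.
#'
#' @param K_sat light-to-ERK half-saturation, relative light units.
#' @param hill Hill exponent of the light-to-ERK map.
#' @param tau_cic time constant (min) of ERK/Cic relief and restoration:
#'   ERK follows the light input as a first-order process, and repression is
#'   restored within minutes of light-off.
#' @param theta_tll,theta_hkb cumulative-dose thresholds (ERK x min) for
#'   tll and hkb transcription onset; `theta_hkb > theta_tll`.
#' @param tau_latency transcription-initiation latency (min) after a
#'   threshold crossing.
#' @param k_prod_T,k_prod_H protein production rates (a.u./min) while the
#'   corresponding indicator is on.
#' @param k_dec_T,k_dec_H protein decay rates (1/min). The repressor default
#'   is 0: Hkb protein is treated as stable over the 90-min window, so its
#'   repression of byn, once established, persists.
#' @param theta_T_on activator protein level (a.u.) required for byn.
#' @param theta_H_off repressor protein level (a.u.) sufficient to silence byn.
#' @param window_close minutes into NC14 after which tll and hkb lose input
#'   sensitivity (their indicators are forced off).
#' @param e_maint minimum instantaneous ERK needed to maintain tll/hkb
#'   transcription; models the rapid restoration of Cic repression when the
#'   input is removed.
#' @return list of class `circuit_params`.
#' @export
circuit_params <- function(K_sat = 0.2,
                           hill = 3,
                           tau_cic = 0.3,
                           theta_tll = 2.2,
                           theta_hkb = 19,
                           tau_latency = 0.8,
                           k_prod_T = 1,
                           k_dec_T = 0.02,
                           k_prod_H = 1,
                           k_dec_H = 0,
                           theta_T_on = 5,
                           theta_H_off = 33.5,
                           window_close = 15,
                           e_maint = 0.02) {
  p <- list(K_sat = K_sat, hill = hill, tau_cic = tau_cic,
            theta_tll = theta_tll, theta_hkb = theta_hkb,
            tau_latency = tau_latency,
            k_prod_T = k_prod_T, k_dec_T = k_dec_T,
            k_prod_H = k_prod_H, k_dec_H = k_dec_H,
            theta_T_on = theta_T_on, theta_H_off = theta_H_off,
            window_close = window_close, e_maint = e_maint)
  num <- unlist(p)
  if (any(num < 0)) stop("all circuit parameters must be >= 0")
  if (theta_hkb <= theta_tll) {
    stop("theta_hkb must exceed theta_tll (the repressor needs a larger cumulative dose)")
  }
  structure(p, class = "circuit_params")
}

#' Saturating light-to-ERK map
#'
#' `E = (s I)^h / ((s I)^h + K_sat^h)`, monotone in both the nominal
#' intensity `I` and the embryo-specific multiplier `s`, with `E` in `[0, 1)`.
#'
#' @param intensity relative light dose(s), >= 0.
#' @param sos_scale embryo-specific dose multiplier (> 0).
#' @param params a [circuit_params()].
#' @return ERK amplitude(s) in `[0, 1)`.
#' @export
erk_from_light <- function(intensity, sos_scale = 1, params = circuit_params()) {
  if (any(intensity < 0)) stop("intensity must be >= 0")
  if (any(sos_scale <= 0)) stop("sos_scale must be > 0")
  u <- (sos_scale * intensity)^params$hill
  u / (u + params$K_sat^params$hill)
}

#' ERK activity time series for a light protocol
#'
#' ERK relaxes toward the instantaneous light-determined amplitude with a
#' first-order time constant `tau_cic` (relief of Capicua repression when the
#' light turns on; restoration when it turns off).
#'
#' @param protocol a [light_protocol()].
#' @param t time grid (min), uniformly spaced.
#' @param sos_scale embryo dose multiplier.
#' @param params a [circuit_params()].
#' @return numeric vector `E(t)` on the grid.
#' @export
erk_series <- function(protocol, t, sos_scale = 1, params = circuit_params()) {
  target <- erk_from_light(protocol$intensity * light_on(t, protocol),
                           sos_scale, params)
  E <- numeric(length(t))
  if (length(t) < 2) return(target)
  dt <- t[2] - t[1]
  decay <- exp(-dt / params$tau_cic)
  E[1] <- 0
  for (i in seq_len(length(t) - 1)) {
    E[i + 1] <- target[i] + (E[i] - target[i]) * decay
  }
  E
}

cumulative_dose <- function(E, t) {
  # trapezoidal cumulative integral of E over t
  n <- length(t)
  c(0, cumsum((E[-1] + E[-n]) / 2 * diff(t)))
}

#' Transcription onset time from a cumulative-dose threshold
#'
#' The cumulative dose `W(t)` (integral of ERK activity) is compared against
#' a threshold; the crossing time (linearly interpolated) plus the initiation
#' latency gives the raw onset, which is snapped forward to the first
#' interphase time, since transcription cannot initiate during mitosis.
#' Returns `Inf` ("never") if the snapped onset falls after the NC14
#' sensitivity window closes, or if the threshold is not reached before
#' gastrulation.
#'
#' @param E ERK activity on the grid `t` (or a data frame with columns `t`, `E`).
#' @param t time grid (min); ignored when `E` is a data frame.
#' @param theta cumulative-dose threshold (ERK x min).
#' @param schedule an [nc_schedule()].
#' @param params a [circuit_params()].
#' @return onset time in minutes, or `Inf` if transcription never initiates.
#' @export
onset_time <- function(E, t = NULL, theta, schedule = nc_schedule(),
                       params = circuit_params()) {
  if (is.data.frame(E)) {
    t <- E$t
    E <- E$E
  }
  W <- cumulative_dose(E, t)
  if (theta <= 0) {
    t_cross <- t[1]
  } else {
    idx <- which(W >= theta)[1]
    if (is.na(idx)) return(Inf)
    if (idx == 1) {
      t_cross <- t[1]
    } else {
      # linear interpolation within the crossing step
      w0 <- W[idx - 1]; w1 <- W[idx]
      t_cross <- t[idx - 1] + (theta - w0) / (w1 - w0) * (t[idx] - t[idx - 1])
    }
  }
  raw <- t_cross + params$tau_latency
  onset <- snap_to_interphase(raw, schedule)
  close_time <- interphase_bounds(schedule, 14)[1] + params$window_close
  if (onset > close_time) return(Inf)
  onset
}

#' Simulate the circuit for one embryo (zero-dimensional)
#'
#' Integrates the full loop on a fixed time grid: ERK follows the light with
#' first-order relief; the cumulative dose accrues continuously (signalling
#' is not assumed silenced by mitosis); tll and hkb indicators switch on at
#' their threshold onsets and stay on during interphase while ERK persists,
#' until the NC14 sensitivity window closes; proteins follow
#' `dP/dt = k_prod x - k_dec P` (integrated exactly per step); and the output
#' gate is `x_byn = 1` iff `P_T > theta_T_on`, `P_H < theta_H_off`, the time
#' is in interphase, and gastrulation has not occurred.
#'
#' @param protocol a [light_protocol()] (or a `scenario`, whose protocol and
#'   schedule are then used).
#' @param schedule an [nc_schedule()].
#' @param embryo one row of [sample_embryo_cohort()] or a list with
#'   `sos_scale`; default `sos_scale = 1`.
#' @param params a [circuit_params()].
#' @param dt integration step (min), must be <= 0.25.
#' @return tibble of class `circuit_trajectory` with columns `t, E, W, x_tll,
#'   x_hkb, x_byn, P_T, P_H`; attributes `onset_tll`, `onset_hkb`, `params`,
#'   `schedule`.
#' @export
simulate_embryo <- function(protocol, schedule = nc_schedule(),
                            embryo = list(sos_scale = 1),
                            params = circuit_params(), dt = 0.1) {
  if (inherits(protocol, "scenario")) {
    schedule <- protocol$schedule
    protocol <- protocol$protocol
  }
  if (dt > 0.25) stop("integration step dt must be <= 0.25 min")
  s <- embryo$sos_scale
  g <- schedule$gastrulation_time
  t <- seq(0, g, by = dt)
  E <- erk_series(protocol, t, sos_scale = s, params = params)
  W <- cumulative_dose(E, t)
  onset_tll <- onset_time(E, t, params$theta_tll, schedule, params)
  onset_hkb <- onset_time(E, t, params$theta_hkb, schedule, params)
  close_time <- interphase_bounds(schedule, 14)[1] + params$window_close
  interph <- in_interphase(t, schedule)
  competent <- interph & (t < close_time) & (E >= params$e_maint)
  x_tll <- as.integer(t >= onset_tll & competent)
  x_hkb <- as.integer(t >= onset_hkb & competent)

  P_T <- protein_series(x_tll, dt, params$k_prod_T, params$k_dec_T)
  P_H <- protein_series(x_hkb, dt, params$k_prod_H, params$k_dec_H)

  x_byn <- as.integer(P_T > params$theta_T_on & P_H < params$theta_H_off &
                        interph & t < g)
  out <- tibble::tibble(t = t, E = E, W = W, x_tll = x_tll, x_hkb = x_hkb,
                        x_byn = x_byn, P_T = P_T, P_H = P_H)
  attr(out, "onset_tll") <- onset_tll
  attr(out, "onset_hkb") <- onset_hkb
  attr(out, "params") <- params
  attr(out, "schedule") <- schedule
  class(out) <- c("circuit_trajectory", class(out))
  out
}

# exact per-step update of dP/dt = k_prod * x - k_dec * P with x piecewise
# constant on each step; handles k_dec = 0 (pure accumulation)
protein_series <- function(x, dt, k_prod, k_dec) {
  n <- length(x)
  P <- numeric(n)
  if (k_dec > 0) {
    decay <- exp(-k_dec * dt)
    gain <- k_prod / k_dec * (1 - decay)
    for (i in seq_len(n - 1)) P[i + 1] <- P[i] * decay + gain * x[i]
  } else {
    P <- c(0, cumsum(k_prod * x[-n] * dt))
  }
  P
}

#' Classify output-gene dynamics within NC14
#'
#' Measures the total time with `x_byn = 1` inside NC14 and classifies it:
#' absent (0), transient (at most 15 min), sustained (at least 25 min), or
#' intermediate.
#'
#' @param traj a `circuit_trajectory` from [simulate_embryo()].
#' @param schedule an [nc_schedule()]; defaults to the trajectory's.
#' @return list with `class` (character) and `duration` (min).
#' @export
classify_byn_dynamics <- function(traj, schedule = attr(traj, "schedule")) {
  b14 <- interphase_bounds(schedule, 14)
  dt <- traj$t[2] - traj$t[1]
  sel <- traj$t >= b14[1] & traj$t < min(b14[2], schedule$gastrulation_time)
  duration <- sum(traj$x_byn[sel]) * dt
  cls <- if (duration == 0) "absent"
  else if (duration <= 15) "transient"
  else if (duration >= 25) "sustained"
  else "intermediate"
  list(class = cls, duration = duration)
}

#' Onset-delay curve over a range of ERK amplitudes
#'
#' For each amplitude, a constant-target input (light on for the whole
#' experiment, producing that ERK amplitude after first-order relief) is
#' integrated and the tll and hkb onset times computed. Onset of the
#' repressor is approximately `theta_hkb / amplitude` plus the latency,
#' so it is strictly decreasing in amplitude wherever finite; the activator
#' onset is weakly decreasing and never later than the repressor's.
#'
#' @param amplitudes ERK amplitudes in (0, 1].
#' @param schedule an [nc_schedule()].
#' @param params a [circuit_params()].
#' @param dt integration step (min).
#' @return tibble with columns `amplitude`, `tll_onset`, `hkb_onset`
#'   (minutes; `Inf` = never).
#' @export
hkb_delay_curve <- function(amplitudes, schedule = nc_schedule(),
                            params = circuit_params(), dt = 0.1) {
  if (any(amplitudes <= 0) || any(amplitudes > 1)) {
    stop("amplitudes must lie in (0, 1]")
  }
  t <- seq(0, schedule$gastrulation_time, by = dt)
  decay <- exp(-dt / params$tau_cic)
  rows <- purrr::map(amplitudes, function(A) {
    E <- A * (1 - decay^(seq_along(t) - 1))  # first-order rise to A
    tibble::tibble(
      amplitude = A,
      tll_onset = onset_time(E, t, params$theta_tll, schedule, params),
      hkb_onset = onset_time(E, t, params$theta_hkb, schedule, params)
    )
  })
  dplyr::bind_rows(rows)
}

#' Export a trajectory as tidy CSV
#'
#' @param traj a `circuit_trajectory`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  names(df)[1] <- "t_min"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
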