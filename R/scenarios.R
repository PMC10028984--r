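#' Nuclear-cycle schedule for the syncytial blastoderm
#'
#' Interphase intervals for nuclear cycles 10 through 14 plus the time of
#' gastrulation, all in minutes since the start of NC10 (which is also the
#' start of illumination for stimuli that begin in NC10). Mitoses occupy the
#' gaps between consecutive interphases; NC14 ends at gastrulation with no
#' following mitosis.
#'
#' The default anchors follow the biology of the pre-gastrulation embryo at
#' imaging temperature: the NC10-13 epoch lasts roughly 45 min, NC14 roughly
#' another 45 min, and the whole illuminated window roughly 90 min. The very
#' short NC10 interphase reflects that surface nuclei are scored only in the
#' closing minutes of cycle 10; cycle lengths then grow with each division.
#'
#' @param interphases data frame with columns `cycle`, `start`, `end`
#'   (minutes). Defaults to the calibrated schedule.
#' @param gastrulation_time minutes at which gastrulation ends the experiment.
#' @return An object of class `nc_schedule`: a list with `cycles` (tibble) and
#'   `gastrulation_time`.
#' @export
nc_schedule <- function(interphases = NULL, gastrulation_time = 93) {
  if (is.null(interphases)) {
    interphases <- tibble::tibble(
      cycle = 10:14,
      start = c(0, 7, 18, 32, 48),
      end   = c(2.5, 16, 30, 45, 93)
    )
  }
  interphases <- tibble::as_tibble(interphases)
  stopifnot(all(c("cycle", "start", "end") %in% names(interphases)))
  interphases <- dplyr::arrange(interphases, .data$cycle)
  if (any(interphases$end <= interphases$start)) {
    stop("each interphase must have end > start")
  }
  if (any(diff(as.vector(rbind(interphases$start, interphases$end))) < 0)) {
    stop("interphase intervals must be ordered and disjoint")
  }
  if (gastrulation_time < max(interphases$end)) {
    stop("gastrulation_time must not precede the end of the last interphase")
  }
  structure(
    list(cycles = interphases, gastrulation_time = gastrulation_time),
    class = "nc_schedule"
  )
}

#' @export
print.nc_schedule <- function(x, ...) {
  cat("Nuclear-cycle schedule (min since NC10 start):\n")
  print(x$cycles)
  cat("Gastrulation at", x$gastrulation_time, "min\n")
  invisible(x)
}

#' Interphase start and end of one nuclear cycle
#' @param schedule an [nc_schedule()].
#' @param cycle cycle index (10-14).
#' @return numeric `c(start, end)` in minutes.
#' @export
interphase_bounds <- function(schedule, cycle) {
  row <- schedule$cycles[schedule$cycles$cycle == cycle, ]
  if (nrow(row) == 0) stop("no such cycle: ", cycle)
  c(row$start, row$end)
}

#' Is a time point inside interphase?
#'
#' @param t numeric vector of times (min).
#' @param schedule an [nc_schedule()].
#' @return logical vector; `TRUE` where `t` lies inside some interphase
#'   (half-open intervals `[start, end)`).
#' @export
in_interphase <- function(t, schedule) {
  out <- rep(FALSE, length(t))
  for (i in seq_len(nrow(schedule$cycles))) {
    out <- out | (t >= schedule$cycles$start[i] & t < schedule$cycles$end[i])
  }
  out
}

#' Cycle index at each time point (NA during mitosis)
#' @inheritParams in_interphase
#' @return integer vector of cycle indices, `NA` outside interphase.
#' @export
cycle_at <- function(t, schedule) {
  out <- rep(NA_integer_, length(t))
  for (i in seq_len(nrow(schedule$cycles))) {
    sel <- t >= schedule$cycles$start[i] & t < schedule$cycles$end[i]
    out[sel] <- as.integer(schedule$cycles$cycle[i])
  }
  out
}

#' Snap a time to the first interphase time at or after it
#'
#' @param t numeric scalar (min).
#' @param schedule an [nc_schedule()].
#' @return the first time `>= t` that lies in interphase, or `Inf` if none
#'   exists before gastrulation.
#' @keywords internal
snap_to_interphase <- function(t, schedule) {
  if (!is.finite(t)) return(Inf)
  if (in_interphase(t, schedule)) return(t)
  starts <- schedule$cycles$start
  nxt <- starts[starts >= t]
  if (length(nxt) == 0) return(Inf)
  min(nxt)
}

#' Optogenetic light protocol
#'
#' A stimulus is described by a relative intensity (high light = 1), a set of
#' temporal on-intervals, and a 1-D spatial mask along the axis perpendicular
#' to the illumination boundary. The physical stimulus is pulsed (0.6 s of
#' blue light every 30 s) but is treated as a continuous input of the same
#' average dose.
#'
#' @param intensity relative light dose, >= 0; high = 1, low = 1/8.
#' @param on_intervals two-column matrix or list of `c(start, end)` pairs in
#'   minutes since NC10 start; sorted and non-overlapping.
#' @param mask two-column matrix of illuminated x-intervals in micrometres
#'   (use `-Inf`/`Inf` for half-planes). Default: everywhere lit.
#' @param pulse_cadence metadata string describing the physical pulsing.
#' @param gastrulation_time used to validate interval bounds.
#' @return object of class `light_protocol`.
#' @export
light_protocol <- function(intensity,
                           on_intervals,
                           mask = matrix(c(-Inf, Inf), ncol = 2),
                           pulse_cadence = "0.6 s every 30 s, treated as continuous",
                           gastrulation_time = 93) {
  if (intensity < 0) stop("intensity must be >= 0")
  if (is.list(on_intervals)) {
    on_intervals <- do.call(rbind, on_intervals)
  }
  on_intervals <- matrix(as.numeric(on_intervals), ncol = 2)
  if (nrow(on_intervals) > 0) {
    if (any(on_intervals[, 2] <= on_intervals[, 1])) {
      stop("each on-interval must have end > start")
    }
    o <- order(on_intervals[, 1])
    on_intervals <- on_intervals[o, , drop = FALSE]
    if (nrow(on_intervals) > 1 &&
        any(on_intervals[-1, 1] < on_intervals[-nrow(on_intervals), 2])) {
      stop("on-intervals must not overlap")
    }
    if (any(on_intervals[, 1] < 0) || any(on_intervals[, 2] > gastrulation_time)) {
      stop("on-intervals must lie within [0, gastrulation_time]")
    }
  }
  mask <- matrix(as.numeric(mask), ncol = 2)
  structure(
    list(intensity = intensity, on_intervals = on_intervals, mask = mask,
         pulse_cadence = pulse_cadence),
    class = "light_protocol"
  )
}

#' @export
print.light_protocol <- function(x, ...) {
  cat("Light protocol: intensity", x$intensity, "\n")
  if (nrow(x$on_intervals) == 0) {
    cat("  always dark\n")
  } else {
    apply(x$on_intervals, 1, function(r) cat("  on", r[1], "-", r[2], "min\n"))
  }
  cat("  mask:", paste(apply(x$mask, 1, function(r)
    sprintf("[%g, %g] um", r[1], r[2])), collapse = ", "), "\n")
  invisible(x)
}

#' Is the light on at time t?
#' @param t numeric vector of times (min).
#' @param protocol a [light_protocol()].
#' @return logical vector.
#' @export
light_on <- function(t, protocol) {
  out <- rep(FALSE, length(t))
  iv <- protocol$on_intervals
  if (nrow(iv) == 0) return(out)
  for (i in seq_len(nrow(iv))) out <- out | (t >= iv[i, 1] & t < iv[i, 2])
  out
}

#' Is position x inside the illuminated mask?
#' @param x numeric vector of positions (um).
#' @param protocol a [light_protocol()].
#' @return logical vector.
#' @export
in_mask <- function(x, protocol) {
  out <- rep(FALSE, length(x))
  for (i in seq_len(nrow(protocol$mask))) {
    out <- out | (x >= protocol$mask[i, 1] & x < protocol$mask[i, 2])
  }
  out
}

#' Named experimental scenarios
#'
#' Encodes the stimulus protocols used throughout: continuous high or low
#' light from NC10, a high pulse covering NC10-13 only, high light starting at
#' NC13 or NC14, darkness, half-plane boundary stimuli at both intensities,
#' and the posterior-pole rescue geometry (terminal 60 um illuminated).
#'
#' Intensities are relative: high scenarios use 1.0 and low scenarios 0.125
#' (an 8-fold lower dose). Boundary masks illuminate x < 0 with x in
#' micrometres increasing into the unilluminated region.
#'
#' @param name one of `"high_continuous"`, `"low_continuous"`,
#'   `"high_pulse_NC10_13"`, `"high_from_NC13"`, `"high_from_NC14"`,
#'   `"dark"`, `"boundary_high"`, `"boundary_low"`, `"pole_rescue"`.
#' @param schedule an [nc_schedule()]; scenario timing is derived from it.
#' @return list with elements `protocol` ([light_protocol()]) and `schedule`,
#'   of class `scenario`.
#' @export
build_scenario <- function(name, schedule = nc_schedule()) {
  valid <- c("high_continuous", "low_continuous", "high_pulse_NC10_13",
             "high_from_NC13", "high_from_NC14", "dark",
             "boundary_high", "boundary_low", "pole_rescue")
  if (!is.character(name) || length(name) != 1 || !(name %in% valid)) {
    stop("unknown scenario '", name, "'; valid names are: ",
         paste(valid, collapse = ", "))
  }
  g <- schedule$gastrulation_time
  everywhere <- matrix(c(-Inf, Inf), ncol = 2)
  half_plane <- matrix(c(-Inf, 0), ncol = 2)
  protocol <- switch(
    name,
    high_continuous = light_protocol(1.0, rbind(c(0, g)), everywhere,
                                     gastrulation_time = g),
    low_continuous = light_protocol(0.125, rbind(c(0, g)), everywhere,
                                    gastrulation_time = g),
    high_pulse_NC10_13 = light_protocol(
      1.0, rbind(c(0, interphase_bounds(schedule, 13)[2])), everywhere,
      gastrulation_time = g),
    high_from_NC13 = light_protocol(
      1.0, rbind(c(interphase_bounds(schedule, 13)[1], g)), everywhere,
      gastrulation_time = g),
    high_from_NC14 = light_protocol(
      1.0, rbind(c(interphase_bounds(schedule, 14)[1], g)), everywhere,
      gastrulation_time = g),
    dark = light_protocol(0, matrix(numeric(0), ncol = 2), everywhere,
                          gastrulation_time = g),
    boundary_high = light_protocol(1.0, rbind(c(0, g)), half_plane,
                                   gastrulation_time = g),
    boundary_low = light_protocol(0.125, rbind(c(0, g)), half_plane,
                                  gastrulation_time = g),
    # pole-rescue geometry: x = 0 at the posterior tip, terminal 60 um lit
    pole_rescue = light_protocol(1.0, rbind(c(0, g)),
                                 matrix(c(0, 60), ncol = 2),
                                 gastrulation_time = g)
  )
  structure(list(name = name, protocol = protocol, schedule = schedule),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("Scenario:", x$name, "\n")
  print(x$protocol)
  invisible(x)
}

#' Sample embryo-to-embryo stimulus variability
#'
#' OptoSOS expression varies between embryos (Gal4/UAS variability), so one
#' nominal light dose produces a distribution of effective stimuli. The
#' effective dose multiplier `sos_scale` is drawn from a log-normal
#' distribution with median 1 and the requested coefficient of variation.
#'
#' @param n number of embryos (>= 1).
#' @param cv coefficient of variation of `sos_scale` (>= 0).
#' @param seed integer seed; sampling is bit-reproducible for a given seed.
#' @return tibble with columns `embryo_id`, `sos_scale`.
#' @export
sample_embryo_cohort <- function(n, cv = 0.3, seed = 1) {
  if (n < 1) stop("n must be >= 1")
  if (cv < 0) stop("cv must be >= 0")
  if (cv == 0) {
    scales <- rep(1, n)
  } else {
    sdlog <- sqrt(log(1 + cv^2))
    scales <- withr::with_seed(seed, stats::rlnorm(n, meanlog = 0, sdlog = sdlog))
  }
  tibble::tibble(embryo_id = seq_len(n), sos_scale = scales)
}

#' Write / read a scenario configuration file
#'
#' Scenarios round-trip through a small JSON dialect with keys `intensity`,
#' `on_intervals`, `mask` and `schedule` (times in minutes, lengths in um).
#' A JSON-schema document describing the format ships in
#' `inst/extdata/scenario-schema.json`.
#'
#' @param scenario a `scenario` object from [build_scenario()].
#' @param path file path.
#' @return `write_scenario` returns `path` invisibly; `read_scenario` returns
#'   a `scenario` object.
#' @export
write_scenario <- function(scenario, path) {
  cfg <- list(
    name = scenario$name,
    intensity = scenario$protocol$intensity,
    on_intervals = unname(apply(scenario$protocol$on_intervals, 1,
                                function(r) c(r[1], r[2]), simplify = FALSE)),
    mask = unname(apply(scenario$protocol$mask, 1,
                        function(r) c(r[1], r[2]), simplify = FALSE)),
    pulse_cadence = scenario$protocol$pulse_cadence,
    schedule = list(
      cycles = as.data.frame(scenario$schedule$cycles),
      gastrulation_time = scenario$schedule$gastrulation_time
    )
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  schedule <- nc_schedule(cfg$schedule$cycles,
                          gastrulation_time = cfg$schedule$gastrulation_time)
  ivs <- cfg$on_intervals
  if (is.list(ivs)) ivs <- do.call(rbind, ivs)
  if (is.null(ivs) || length(ivs) == 0) ivs <- matrix(numeric(0), ncol = 2)
  msk <- cfg$mask
  if (is.list(msk)) msk <- do.call(rbind, msk)
  protocol <- light_protocol(cfg$intensity, ivs, msk,
                             pulse_cadence = cfg$pulse_cadence,
                             gastrulation_time = schedule$gastrulation_time)
  structure(list(name = cfg$name, protocol = protocol, schedule = schedule),
            class = "scenario")
}
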