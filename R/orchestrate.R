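#' Run one named experiment end to end
#'
#' Chains scenario construction, circuit (or stripe) simulation, optional
#' movie rendering, quantification and reporting. When `out_dir` is given,
#' writes the scenario config snapshot, trajectory/field CSVs, the movie as
#' multi-page TIFF with truth CSVs, the burst table, a statistics JSON and a
#' manifest recording the package version, scenario and seed, so a run is
#' reproducible from its manifest alone.
#'
#' @param name scenario id (see [build_scenario()]).
#' @param seed integer seed for rendering and any cohort sampling.
#' @param out_dir optional output directory (created if needed).
#' @param gene which gene's transcription to image/quantify.
#' @param render render and quantify a synthetic movie (slower).
#' @param schedule,params,spatial,imaging component parameter objects.
#' @return list with `scenario`, `trajectory` (or `stripe`), `movie`
#'   (optional), `quant` (optional), `stats`, `manifest`, invisibly when
#'   `out_dir` is set.
#' @export
run_experiment <- function(name, seed = 1, out_dir = NULL, gene = "byn",
                           render = FALSE,
                           schedule = nc_schedule(),
                           params = circuit_params(),
                           spatial = spatial_params(),
                           imaging = imaging_params()) {
  scenario <- build_scenario(name, schedule)
  is_spatial <- name %in% c("boundary_high", "boundary_low", "pole_rescue")
  stats <- list(scenario = name, seed = seed)
  movie <- NULL; quant <- NULL

  if (is_spatial) {
    sim <- if (name == "pole_rescue") {
      simulate_pole_rescue(schedule, params)
    } else {
      simulate_stripe(scenario, params = params, spatial = spatial)
    }
    stats$stripe_summary <- sim$summary
    if (render) {
      movie <- render_boundary_movie(sim, gene = gene,
                                     protocol = scenario$protocol,
                                     imaging = imaging, seed = seed)
      quant <- quantify_movie(movie)
      stats$duration_nc14 <- quant$stats$duration_nc14
      stats$time_to_half <- quant$stats$time_to_half
    }
  } else {
    sim <- simulate_embryo(scenario, params = params)
    cls <- classify_byn_dynamics(sim, schedule)
    stats$byn_class <- cls$class
    stats$byn_nc14_duration <- cls$duration
    stats$onset_tll <- attr(sim, "onset_tll")
    stats$onset_hkb <- attr(sim, "onset_hkb")
    if (render) {
      movie <- render_movie(sim, gene = gene, protocol = scenario$protocol,
                            schedule = schedule, imaging = imaging,
                            seed = seed)
      quant <- quantify_movie(movie)
      stats$duration_nc14 <- quant$stats$duration_nc14
      stats$time_to_half <- quant$stats$time_to_half
    }
  }

  manifest <- list(
    package = "stripedyn",
    version = as.character(utils::packageVersion("stripedyn")),
    scenario = name, gene = gene, seed = seed,
    rendered = render,
    params = unclass(params),
    spatial = unclass(spatial)[c("D", "alpha", "beta")]
  )
  out <- list(scenario = scenario,
              trajectory = if (!is_spatial) sim else NULL,
              stripe = if (is_spatial) sim else NULL,
              movie = movie, quant = quant, stats = stats,
              manifest = manifest)

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) {
      ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      if (!ok) stop("cannot create output directory: ", out_dir)
    }
    write_scenario(scenario, file.path(out_dir, "scenario.json"))
    if (!is_spatial) {
      write_trajectory(sim, file.path(out_dir, "trajectory.csv"))
    } else {
      write_field(sim$field, file.path(out_dir, "erk_field.csv"), "E")
      jsonlite::write_json(sim$summary,
                           file.path(out_dir, "stripe_summary.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
    }
    if (!is.null(movie)) {
      write_movie(movie, file.path(out_dir, "movie.tif"))
      utils::write.csv(as.data.frame(quant$table),
                       file.path(out_dir, "burst_table.csv"),
                       row.names = FALSE)
    }
    stats_json <- stats
    stats_json$proportions <- NULL
    jsonlite::write_json(stats_json, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}

#' Default calibration constraints: the printed timing/length anchors
#'
#' Each row is one anchor the calibrated model must reproduce: a quantity
#' computed from the simulated scenarios and the admissible interval for it
#' (one-sided bounds use -Inf/Inf).
#'
#' @return tibble with columns `id`, `description`, `determinism`, `lower`,
#'   `upper`.
#' @export
calibration_constraints <- function() {
  tibble::tribble(
    ~id, ~description, ~determinism, ~lower, ~upper,
    "byn_high_duration", "NC14 byn duration, continuous high light (min)",
    "deterministic", 10, 15,
    "byn_low_duration", "NC14 byn duration, continuous low light (min)",
    "deterministic", 25, Inf,
    "hkb_onset_min", "min finite hkb onset across the dose sweep (min)",
    "deterministic", 20, Inf,
    "hkb_onset_max", "max finite hkb onset across the dose sweep (min)",
    "deterministic", -Inf, 60,
    "tll_latency_nc14", "tll onset latency, light from NC14 start (min)",
    "deterministic", -Inf, 4,
    "byn_pulse_duration", "NC14 byn duration after the NC10-13 pulse (min)",
    "deterministic", 25, Inf,
    "hkb_tll_gap", "hkb minus tll onset, continuous high light (min)",
    "deterministic", 6, 14,
    "late_start_dichotomy",
    "hkb finite from NC13 start (1) and never from NC14 start (1)",
    "deterministic", 1, 1
  )
}

# evaluate every anchor for one parameter set; returns named numeric
evaluate_anchors <- function(params, schedule, sweep_bottom = 0.3525) {
  hi <- simulate_embryo(build_scenario("high_continuous", schedule),
                        params = params)
  lo <- simulate_embryo(build_scenario("low_continuous", schedule),
                        params = params)
  pu <- simulate_embryo(build_scenario("high_pulse_NC10_13", schedule),
                        params = params)
  n13 <- simulate_embryo(build_scenario("high_from_NC13", schedule),
                         params = params)
  n14 <- simulate_embryo(build_scenario("high_from_NC14", schedule),
                         params = params)
  e_high <- erk_from_light(1, 1, params)
  amps <- exp(seq(log(e_high), log(sweep_bottom), length.out = 6))
  curve <- hkb_delay_curve(amps, schedule, params)
  finite <- curve$hkb_onset[is.finite(curve$hkb_onset)]
  light_on_14 <- interphase_bounds(schedule, 14)[1]
  c(
    byn_high_duration = classify_byn_dynamics(hi, schedule)$duration,
    byn_low_duration = classify_byn_dynamics(lo, schedule)$duration,
    hkb_onset_min = if (length(finite) > 0) min(finite) else Inf,
    hkb_onset_max = if (length(finite) > 0) max(finite) else Inf,
    tll_latency_nc14 = attr(n14, "onset_tll") - light_on_14,
    byn_pulse_duration = classify_byn_dynamics(pu, schedule)$duration,
    hkb_tll_gap = attr(hi, "onset_hkb") - attr(hi, "onset_tll"),
    late_start_dichotomy = as.numeric(
      is.finite(attr(n13, "onset_hkb")) && !is.finite(attr(n14, "onset_hkb")))
  )
}

#' Calibrate circuit parameters against the timing anchors
#'
#' Deterministic coarse grid search: every combination in `grid` is
#' evaluated against the [calibration_constraints()] and the first parameter
#' set satisfying all of them is returned together with a residual table.
#' The shipped defaults of [circuit_params()] are the output of this search
#' on the default grid.
#'
#' @param grid named list of parameter vectors to cross (values not listed
#'   keep their [circuit_params()] defaults). The default grid brackets the
#'   shipped defaults.
#' @param constraints tibble as returned by [calibration_constraints()].
#' @param schedule an [nc_schedule()].
#' @return object of class `circuit_calibration`: list with `params`, the
#'   per-anchor `residuals` tibble, and search metadata. Errors with
#'   per-constraint feasibility diagnostics if no grid point satisfies all
#'   constraints.
#' @export
calibrate_circuit <- function(grid = NULL,
                              constraints = calibration_constraints(),
                              schedule = nc_schedule()) {
  if (any(constraints$lower >= constraints$upper &
            constraints$determinism == "stochastic")) {
    stop("stochastic anchors need tolerance > 0; widen lower/upper")
  }
  if (is.null(grid)) {
    grid <- list(theta_tll = c(2.2, 1.8, 2.6),
                 theta_hkb = c(19, 17, 21),
                 theta_H_off = c(33.5, 30, 37))
  }
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  n_checked <- 0L
  best <- NULL; best_params <- NULL; best_n_ok <- -1L
  feasibility <- stats::setNames(integer(nrow(constraints)), constraints$id)
  for (i in seq_len(nrow(combos))) {
    args <- as.list(combos[i, , drop = FALSE])
    params <- tryCatch(do.call(circuit_params, args), error = function(e) NULL)
    if (is.null(params)) next  # e.g. theta_hkb <= theta_tll
    n_checked <- n_checked + 1L
    vals <- evaluate_anchors(params, schedule)
    vals <- vals[constraints$id]
    ok <- vals >= constraints$lower & vals <= constraints$upper
    feasibility <- feasibility + as.integer(ok)
    if (sum(ok) > best_n_ok) {
      best_n_ok <- sum(ok); best <- vals; best_params <- params
    }
    if (all(ok)) {
      residuals <- dplyr::mutate(constraints, value = unname(vals),
                                 satisfied = unname(ok))
      return(structure(list(params = params, residuals = residuals,
                            n_grid = nrow(combos), n_checked = n_checked,
                            feasible = TRUE),
                       class = "circuit_calibration"))
    }
  }
  if (n_checked == 0L) {
    stop("no valid parameter set on the grid ",
         "(every combination violates a type invariant, ",
         "e.g. theta_hkb <= theta_tll)")
  }
  diag <- paste(sprintf("%s satisfied at %d/%d grid points",
                        names(feasibility), feasibility, n_checked),
                collapse = "; ")
  stop("no feasible point on the calibration grid. ", diag)
}

#' @export
print.circuit_calibration <- function(x, ...) {
  cat("Circuit calibration:", if (x$feasible) "feasible" else "infeasible",
      sprintf("(%d/%d grid points evaluated)\n", x$n_checked, x$n_grid))
  print(x$residuals)
  invisible(x)
}

#' Broom-style tidiers for calibration results
#'
#' `tidy()` returns the per-anchor residual table; `glance()` a one-row
#' summary of the search.
#'
#' @param x a `circuit_calibration`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.circuit_calibration <- function(x, ...) x$residuals

#' @rdname tidy.circuit_calibration
#' @export
glance.circuit_calibration <- function(x, ...) {
  tibble::tibble(feasible = x$feasible, n_grid = x$n_grid,
                 n_checked = x$n_checked,
                 n_satisfied = sum(x$residuals$satisfied),
                 n_constraints = nrow(x$residuals))
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Write / read the calibration config
#'
#' The shipped config (`inst/extdata/calibration.json`) records the
#' calibrated circuit parameters, the spatial parameters and the dose sweep
#' used for the delay-curve anchors.
#'
#' @param params a [circuit_params()].
#' @param spatial a [spatial_params()].
#' @param path file path.
#' @param sweep_bottom lowest repressor-expressing amplitude of the sweep.
#' @return `path` invisibly, or for the reader a list with `params`,
#'   `spatial`, `sweep_bottom`.
#' @export
write_calibration <- function(params, spatial, path, sweep_bottom = 0.3525) {
  jsonlite::write_json(
    list(circuit = unclass(params),
         spatial = unclass(spatial)[c("D", "alpha", "beta", "dx", "safety")],
         sweep_bottom = sweep_bottom,
         note = paste("Defaults produced by calibrate_circuit() on the",
                      "default grid; integrator state persists through",
                      "mitosis (no reset).")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path = system.file("extdata", "calibration.json",
                                                package = "stripedyn")) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  circ <- cfg$circuit
  list(params = do.call(circuit_params, circ),
       spatial = do.call(spatial_params, as.list(cfg$spatial)),
       sweep_bottom = cfg$sweep_bottom)
}

#' The calibrated amplitude sweep for the repressor delay curve
#'
#' Six doses spaced geometrically from the continuous-high ERK amplitude down
#' to the lowest amplitude at which the repressor is expressed at all.
#'
#' @param params a [circuit_params()].
#' @param sweep_bottom lowest amplitude.
#' @return numeric vector of 6 amplitudes, decreasing.
#' @export
amplitude_sweep <- function(params = circuit_params(), sweep_bottom = 0.3525) {
  e_high <- erk_from_light(1, 1, params)
  exp(seq(log(e_high), log(sweep_bottom), length.out = 6))
}
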