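#' Spatial model parameters
#'
#' An activated intracellular species C is produced inside the illuminated
#' mask, diffuses along the axis perpendicular to the illumination boundary,
#' and decays everywhere: `dC/dt = D d2C/dx2 + alpha I mask(x) lit(t) - beta C`
#' with no-flux ends. At steady state a half-plane source yields a plateau
#' `alpha I / beta` deep inside the mask, half the plateau exactly at the
#' boundary, and an `exp(-x / lambda)` tail with `lambda = sqrt(D / beta)`.
#' ERK at each position is the circuit's saturating map applied to the
#' light-equivalent dose `C beta / alpha` (so deep inside the mask the
#' spatial model reproduces the zero-dimensional model exactly at steady
#' state).
#'
#' Defaults give `lambda = 25` um, placing graded responses out to roughly
#' 50 um from the boundary, and a rise time `1/beta = 5` min.
#'
#' @param D diffusion coefficient, um^2/min.
#' @param alpha activation rate, light-equivalent a.u./min.
#' @param beta decay rate, 1/min.
#' @param xmin,xmax,dx spatial grid (um).
#' @param safety explicit-scheme safety factor applied to the stability limit
#'   `dx^2 / (2 D)`.
#' @return list of class `spatial_params`.
#' @export
spatial_params <- function(D = 125, alpha = 0.8, beta = 0.2,
                           xmin = -150, xmax = 150, dx = 1, safety = 0.4) {
  if (D <= 0 || alpha <= 0 || beta < 0) stop("D, alpha must be > 0; beta >= 0")
  if (dx <= 0) stop("dx must be > 0")
  structure(list(D = D, alpha = alpha, beta = beta,
                 xmin = xmin, xmax = xmax, dx = dx, safety = safety),
            class = "spatial_params")
}

#' Decay length of the activated species
#' @param spatial a [spatial_params()].
#' @return `sqrt(D / beta)` in um.
#' @export
decay_length <- function(spatial) sqrt(spatial$D / spatial$beta)

# one explicit diffusion-reaction run; returns list(x, t, C) with C a
# [time x position] matrix sampled every dt_out
diffuse_field <- function(source_x, lit_fun, spatial, t_end, dt_out = 0.1,
                          C0 = NULL, dt = NULL) {
  x <- seq(spatial$xmin, spatial$xmax, by = spatial$dx)
  nx <- length(x)
  limit <- spatial$dx^2 / (2 * spatial$D)
  if (is.null(dt)) {
    dt <- spatial$safety * limit
  } else if (dt > limit) {
    stop(sprintf(
      "explicit scheme unstable: dt = %g exceeds the stability limit dx^2/(2D) = %g",
      dt, limit))
  }
  n_sub <- max(1L, ceiling(dt_out / dt))
  dt <- dt_out / n_sub
  t_out <- seq(0, t_end, by = dt_out)
  C <- matrix(0, nrow = length(t_out), ncol = nx)
  cur <- if (is.null(C0)) numeric(nx) else as.numeric(C0)
  C[1, ] <- cur
  r <- spatial$D * dt / spatial$dx^2
  for (k in seq_len(length(t_out) - 1)) {
    t_now <- t_out[k]
    for (s in seq_len(n_sub)) {
      lit <- lit_fun(t_now + (s - 1) * dt)
      # no-flux ends via mirrored ghost cells
      lap <- c(cur[2] - cur[1], diff(cur, differences = 2),
               cur[nx - 1] - cur[nx])
      cur <- cur + r * lap + dt * (source_x * lit - spatial$beta * cur)
    }
    C[k + 1, ] <- cur
  }
  list(x = x, t = t_out, C = C)
}

#' Simulate the activated-species and ERK fields for a masked light protocol
#'
#' @param protocol a [light_protocol()] (or `scenario`) whose `mask` defines
#'   the source region.
#' @param spatial a [spatial_params()].
#' @param t_end end of simulation (min); defaults to gastrulation when a
#'   scenario is supplied, else 93.
#' @param params a [circuit_params()] used for the dose-to-ERK map.
#' @param sos_scale embryo dose multiplier.
#' @param dt_out sampling interval of the returned fields (min).
#' @param dt optional inner time step; must respect the explicit stability
#'   limit `dx^2/(2D)` or an error naming the limit is raised.
#' @return list of class `spatial_field` with `x`, `t`, `C` (time x position)
#'   and `E` (ERK field via the saturating map).
#' @export
simulate_activity_field <- function(protocol, spatial = spatial_params(),
                                    t_end = NULL, params = circuit_params(),
                                    sos_scale = 1, dt_out = 0.1, dt = NULL) {
  if (inherits(protocol, "scenario")) {
    if (is.null(t_end)) t_end <- protocol$schedule$gastrulation_time
    protocol <- protocol$protocol
  }
  if (is.null(t_end)) t_end <- 93
  x <- seq(spatial$xmin, spatial$xmax, by = spatial$dx)
  source_x <- spatial$alpha * protocol$intensity *
    mask_fraction(x, spatial$dx, protocol)
  fld <- diffuse_field(source_x, function(tt) as.numeric(light_on(tt, protocol)),
                       spatial, t_end, dt_out = dt_out, dt = dt)
  I_eq <- fld$C * spatial$beta / spatial$alpha
  E <- erk_from_light(I_eq, sos_scale = sos_scale, params = params)
  structure(list(x = fld$x, t = fld$t, C = fld$C, E = E), class = "spatial_field")
}

# vectorised circuit across positions given an ERK field E [time x position]
circuit_on_field <- function(field, schedule, params) {
  t <- field$t
  x <- field$x
  dt <- t[2] - t[1]
  E <- field$E
  nt <- length(t); nx <- length(x)
  onsets_tll <- vapply(seq_len(nx), function(j)
    onset_time(E[, j], t, params$theta_tll, schedule, params), numeric(1))
  onsets_hkb <- vapply(seq_len(nx), function(j)
    onset_time(E[, j], t, params$theta_hkb, schedule, params), numeric(1))
  close_time <- interphase_bounds(schedule, 14)[1] + params$window_close
  interph <- in_interphase(t, schedule)
  competent <- (E >= params$e_maint) & interph & (t < close_time)
  x_tll <- competent & outer(t, onsets_tll, ">=")
  x_hkb <- competent & outer(t, onsets_hkb, ">=")

  P_T <- protein_field(x_tll, dt, params$k_prod_T, params$k_dec_T)
  P_H <- protein_field(x_hkb, dt, params$k_prod_H, params$k_dec_H)
  g <- schedule$gastrulation_time
  x_byn <- (P_T > params$theta_T_on) & (P_H < params$theta_H_off) &
    interph & (t < g)
  list(t = t, x = x, E = E, x_tll = x_tll, x_hkb = x_hkb, x_byn = x_byn,
       P_T = P_T, P_H = P_H, onset_tll = onsets_tll, onset_hkb = onsets_hkb)
}

protein_field <- function(xind, dt, k_prod, k_dec) {
  nt <- nrow(xind); nx <- ncol(xind)
  P <- matrix(0, nt, nx)
  if (k_dec > 0) {
    decay <- exp(-k_dec * dt)
    gain <- k_prod / k_dec * (1 - decay)
    for (i in seq_len(nt - 1)) P[i + 1, ] <- P[i, ] * decay + gain * xind[i, ]
  } else {
    P[-1, ] <- apply(xind[-nt, , drop = FALSE] * k_prod * dt, 2, cumsum)
  }
  P
}

# fraction of the finite-volume cell [x - dx/2, x + dx/2] covered by the
# mask; keeps the effective source boundary second-order accurate
mask_fraction <- function(x, dx, protocol) {
  lo <- x - dx / 2
  hi <- x + dx / 2
  frac <- numeric(length(x))
  for (i in seq_len(nrow(protocol$mask))) {
    a <- pmax(lo, protocol$mask[i, 1])
    b <- pmin(hi, protocol$mask[i, 2])
    frac <- frac + pmax(0, b - a) / dx
  }
  pmin(frac, 1)
}

# boundary between lit and unlit sides: the finite mask edge
mask_boundary <- function(protocol) {
  edges <- as.vector(protocol$mask)
  edges <- edges[is.finite(edges)]
  if (length(edges) == 0) stop("protocol mask has no finite boundary")
  max(edges)
}

#' Simulate the full stripe: per-position circuit dynamics under a masked input
#'
#' Runs the reaction-diffusion field, then the circuit at every grid position
#' with its local ERK time series, and summarises the output-gene pattern:
#' when transcription is lost in the illuminated region, how far into the
#' unilluminated region transcription reaches early in NC14, and the band of
#' positions with sustained transcription late in NC14.
#'
#' @param scenario a `scenario` (e.g. `build_scenario("boundary_high")`), or a
#'   [light_protocol()] plus explicit `schedule`.
#' @param schedule an [nc_schedule()] (taken from the scenario if given).
#' @param params a [circuit_params()].
#' @param spatial a [spatial_params()]; the domain must extend >= 100 um on
#'   each side of the mask boundary.
#' @param early_window minutes into NC14 defining "early" for the extent
#'   measurement.
#' @param sustained_at minutes into NC14 at which the sustained band is read.
#' @return list of class `stripe_sim` with the field and indicator matrices,
#'   a per-position tibble `positions` (onsets, burst times, class), and
#'   `summary`: `illum_shutoff_nc14` (min into NC14 when the illuminated
#'   region last bursts; `Inf` if bursting persists to gastrulation, `NA` if
#'   it never bursts in NC14), `extent_um` (farthest distance from the
#'   boundary with early-NC14 bursting), and `band_um` (range of
#'   distance-from-boundary with bursting at `sustained_at`).
#' @export
simulate_stripe <- function(scenario, schedule = NULL,
                            params = circuit_params(),
                            spatial = spatial_params(),
                            early_window = 10, sustained_at = 20) {
  if (inherits(scenario, "scenario")) {
    schedule <- scenario$schedule
    protocol <- scenario$protocol
  } else {
    protocol <- scenario
    if (is.null(schedule)) schedule <- nc_schedule()
  }
  bd <- mask_boundary(protocol)
  if (bd - spatial$xmin < 100 || spatial$xmax - bd < 100) {
    stop("spatial domain must span >= 100 um on each side of the mask boundary")
  }
  field <- simulate_activity_field(protocol, spatial,
                                   t_end = schedule$gastrulation_time,
                                   params = params)
  circ <- circuit_on_field(field, schedule, params)
  res <- summarise_stripe(circ, protocol, schedule,
                          early_window = early_window,
                          sustained_at = sustained_at)
  res$field <- field
  res
}

#' Photoconversion control: pure diffusion of a step pattern
#'
#' A sharp pattern of photoconverted protein (1 for `x < 0`, 0 for `x > 0`)
#' spreads by diffusion alone. In the syncytium the profile after time `t` is
#' `0.5 erfc(x / sqrt(4 D t))`; after cellularization membranes block mixing,
#' modelled as `D = 0`, and the step is frozen.
#'
#' @param D diffusion coefficient, um^2/min.
#' @param t_obs observation time (min).
#' @param cellularized if `TRUE`, diffusion is disabled and the initial step
#'   is returned unchanged.
#' @param L half-width of the domain (um).
#' @param dx grid spacing (um).
#' @return tibble with columns `x`, `value`.
#' @export
simulate_photoconversion <- function(D = 125, t_obs = 10, cellularized = FALSE,
                                     L = 250, dx = 1) {
  if (t_obs < 0) stop("t_obs must be >= 0")
  x <- seq(-L, L, by = dx)
  step <- as.numeric(x < 0)
  step[x == 0] <- 0.5  # cell-centred step: the boundary cell is half converted
  if (cellularized || t_obs == 0 || D == 0) {
    return(tibble::tibble(x = x, value = step))
  }
  sp <- spatial_params(D = D, alpha = 1, beta = 0, xmin = -L, xmax = L, dx = dx)
  fld <- diffuse_field(source_x = numeric(length(x)),
                       lit_fun = function(tt) 0,
                       spatial = sp, t_end = t_obs,
                       dt_out = t_obs, C0 = step)
  tibble::tibble(x = x, value = fld$C[nrow(fld$C), ])
}

#' Profile width between the 25% and 75% crossings
#' @param profile tibble from [simulate_photoconversion()].
#' @return width in um.
#' @export
profile_width <- function(profile) {
  # profile decreases from ~1 to ~0; interpolate crossing positions
  xs <- profile$x
  v <- profile$value
  cross <- function(level) {
    idx <- which(v <= level)[1]
    if (is.na(idx) || idx == 1) return(NA_real_)
    x0 <- xs[idx - 1]; x1 <- xs[idx]
    v0 <- v[idx - 1]; v1 <- v[idx]
    x0 + (level - v0) / (v1 - v0) * (x1 - x0)
  }
  cross(0.25) - cross(0.75)
}

#' Pole-rescue geometry: stimulus confined to the terminal 60 um
#'
#' Same machinery as [simulate_stripe()] on an embryo-end domain: `x = 0` is
#' the posterior tip, the mask covers `[0, 60]` um, and the summary triple is
#' computed relative to the mask edge at 60 um.
#'
#' @param schedule an [nc_schedule()].
#' @param params a [circuit_params()].
#' @param spatial a [spatial_params()]; defaults to a `[0, 250]` um domain.
#' @param protocol optional custom protocol (default: the `pole_rescue`
#'   scenario's, i.e. high light in the terminal 60 um).
#' @return a `stripe_sim` (see [simulate_stripe()]).
#' @export
simulate_pole_rescue <- function(schedule = nc_schedule(),
                                 params = circuit_params(),
                                 spatial = NULL,
                                 protocol = NULL) {
  if (is.null(spatial)) {
    base <- spatial_params()
    spatial <- spatial_params(D = base$D, alpha = base$alpha, beta = base$beta,
                              xmin = 0, xmax = 250, dx = base$dx,
                              safety = base$safety)
  }
  if (is.null(protocol)) {
    protocol <- build_scenario("pole_rescue", schedule)$protocol
  }
  # degenerate geometries (mask covering the whole domain) are allowed and
  # simply yield no unilluminated stripe
  field <- simulate_activity_field(protocol, spatial,
                                   t_end = schedule$gastrulation_time,
                                   params = params)
  circ <- circuit_on_field(field, schedule, params)
  res <- summarise_stripe(circ, protocol, schedule)
  res$field <- field
  res
}

# shared summary construction for stripe-style simulations
summarise_stripe <- function(circ, protocol, schedule,
                             early_window = 10, sustained_at = 20) {
  t <- circ$t; x <- circ$x
  dt <- t[2] - t[1]
  bd <- mask_boundary(protocol)
  lit <- in_mask(x, protocol)
  nc14 <- interphase_bounds(schedule, 14)
  in14 <- t >= nc14[1] & t < nc14[2]
  burst14 <- circ$x_byn & in14
  lit14 <- burst14[, lit, drop = FALSE]
  if (!any(lit14)) {
    shutoff <- NA_real_
  } else {
    last_idx <- max(which(rowSums(lit14) > 0))
    shutoff <- if (t[last_idx] >= max(t[in14])) Inf else t[last_idx] + dt - nc14[1]
  }
  early <- burst14 & (t < nc14[1] + early_window)
  unlit_early <- which(colSums(early) > 0 & !lit)
  extent <- if (length(unlit_early) == 0) NA_real_ else max(x[unlit_early] - bd)
  i_sus <- which.min(abs(t - (nc14[1] + sustained_at)))
  sus_pos <- which(circ$x_byn[i_sus, ])
  band <- if (length(sus_pos) == 0) c(NA_real_, NA_real_) else
    range(x[sus_pos] - bd)
  positions <- tibble::tibble(
    x = x, distance = x - bd, illuminated = lit,
    onset_tll = circ$onset_tll, onset_hkb = circ$onset_hkb,
    byn_nc14_min = colSums(burst14) * dt
  )
  positions$class <- dplyr::case_when(
    positions$byn_nc14_min == 0 ~ "absent",
    positions$byn_nc14_min <= 15 ~ "transient",
    positions$byn_nc14_min >= 25 ~ "sustained",
    TRUE ~ "intermediate"
  )
  structure(list(field = NULL, circuit = circ, positions = positions,
                 boundary = bd, schedule = schedule,
                 summary = list(illum_shutoff_nc14 = shutoff,
                                extent_um = extent, band_um = band)),
            class = "stripe_sim")
}

#' Export a field as a CSV matrix (rows = time, columns = position)
#' @param field a `spatial_field`.
#' @param path output file.
#' @param what `"E"` or `"C"`.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path, what = c("E", "C")) {
  what <- match.arg(what)
  m <- field[[what]]
  df <- as.data.frame(m)
  names(df) <- sprintf("x_%g", field$x)
  df <- cbind(t_min = field$t, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
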