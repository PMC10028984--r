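#' Imaging parameters for synthetic two-channel movies
#'
#' Controls the renderer that turns circuit/stripe simulations into
#' time-lapse movies emulating live MS2/MCP imaging: channel 1 carries
#' punctate transcription foci inside nuclei, channel 2 the membrane signal
#' showing OptoSOS recruitment in the illuminated region. Intensities are
#' arbitrary units in [0, 1] before 16-bit quantisation; defaults give a
#' focus signal-to-noise ratio of about 10.
#'
#' @param pixel_size um per pixel.
#' @param frame_interval minutes between frames.
#' @param nucleus_radii radii (um) of nuclei for NC10-14.
#' @param nc14_spacing mean nearest-neighbour spacing (um) of NC14 nuclei;
#'   sets the density, which halves with each earlier cycle.
#' @param nuc_level nuclear fill intensity in the MCP channel.
#' @param focus_intensity mean peak amplitude of an MS2 focus.
#' @param focus_sigma Gaussian radius of a focus (um).
#' @param focus_cv frame-to-frame lognormal fluctuation of focus amplitude.
#' @param dropout probability that a focus is invisible in a frame despite
#'   the nucleus being in a burst (exercises first-to-last-focus bridging).
#' @param jitter_sd per-nucleus onset jitter (min) applied to burst starts.
#' @param membrane_base,membrane_amplitude membrane-channel baseline and
#'   light-induced recruitment amplitude (channel 2).
#' @param membrane_sigma Gaussian blur (um) of the recruitment boundary.
#' @param background_level,background_gradient smooth background: constant
#'   plus a linear ramp across the field.
#' @param noise_sd additive Gaussian noise, both channels.
#' @return list of class `imaging_params`.
#' @export
imaging_params <- function(pixel_size = 0.5,
                           frame_interval = 0.5,
                           nucleus_radii = c(`10` = 6, `11` = 5, `12` = 4.5,
                                             `13` = 4, `14` = 3.5),
                           nc14_spacing = 11,
                           nuc_level = 0.12,
                           focus_intensity = 0.5,
                           focus_sigma = 0.6,
                           focus_cv = 0.2,
                           dropout = 0.15,
                           jitter_sd = 1.5,
                           membrane_base = 0.05,
                           membrane_amplitude = 0.3,
                           membrane_sigma = 3,
                           background_level = 0.08,
                           background_gradient = 0.02,
                           noise_sd = 0.04) {
  structure(list(pixel_size = pixel_size, frame_interval = frame_interval,
                 nucleus_radii = nucleus_radii, nc14_spacing = nc14_spacing,
                 nuc_level = nuc_level, focus_intensity = focus_intensity,
                 focus_sigma = focus_sigma, focus_cv = focus_cv,
                 dropout = dropout, jitter_sd = jitter_sd,
                 membrane_base = membrane_base,
                 membrane_amplitude = membrane_amplitude,
                 membrane_sigma = membrane_sigma,
                 background_level = background_level,
                 background_gradient = background_gradient,
                 noise_sd = noise_sd),
            class = "imaging_params")
}

# Poisson-disk (dart-throwing) placement of n nuclei of radius r in the
# window; centres at least sep apart (no overlap). Errors if the density is
# infeasible.
place_nuclei <- function(n, r, window_x, window_y, sep = NULL,
                         max_tries = 20000) {
  if (is.null(sep)) sep <- 2.2 * r
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0
  while (length(xs) < n) {
    tries <- tries + 1
    if (tries > max_tries) {
      stop(sprintf(
        "nucleus packing failure: placed %d of %d nuclei of radius %g",
        length(xs), n, r))
    }
    cx <- stats::runif(1, window_x[1] + r, window_x[2] - r)
    cy <- stats::runif(1, window_y[1] + r, window_y[2] - r)
    if (length(xs) == 0 || all((xs - cx)^2 + (ys - cy)^2 >= sep^2)) {
      xs <- c(xs, cx); ys <- c(ys, cy)
    }
  }
  tibble::tibble(x = xs, y = ys)
}

# per-cycle contiguous on-intervals of a 0/1 indicator on grid t
indicator_intervals <- function(xind, t, schedule) {
  cyc <- cycle_at(t, schedule)
  out <- list()
  for (cc in unique(stats::na.omit(cyc))) {
    sel <- which(cyc == cc & xind == 1)
    if (length(sel) > 0) {
      out[[as.character(cc)]] <- c(t[min(sel)], t[max(sel)])
    }
  }
  out
}

# smoothed recruitment profile: mask convolved with a Gaussian of sd sigma
recruitment_profile <- function(x, protocol, sigma) {
  out <- numeric(length(x))
  for (i in seq_len(nrow(protocol$mask))) {
    a <- protocol$mask[i, 1]; b <- protocol$mask[i, 2]
    out <- out + stats::pnorm((b - x) / sigma) - stats::pnorm((a - x) / sigma)
  }
  pmin(out, 1)
}

add_spot <- function(img, cx, cy, amp, sigma_px) {
  ny <- nrow(img); nx <- ncol(img)
  w <- ceiling(3 * sigma_px)
  ix <- max(1, round(cx) - w):min(nx, round(cx) + w)
  iy <- max(1, round(cy) - w):min(ny, round(cy) + w)
  gx <- exp(-((ix - cx)^2) / (2 * sigma_px^2))
  gy <- exp(-((iy - cy)^2) / (2 * sigma_px^2))
  img[iy, ix] <- img[iy, ix] + amp * outer(gy, gx)
  img
}

#' Render a synthetic two-channel movie from circuit dynamics
#'
#' Nuclei are drawn as packed disks, re-seeded with doubled count at each
#' nuclear-cycle transition and absent during mitosis. While a nucleus is in
#' its (per-nucleus jittered) bursting interval, an MS2 focus — a small
#' Gaussian spot with frame-to-frame intensity fluctuation and intermittent
#' dropout — is placed inside it in channel 1. Channel 2 shows membrane
#' OptoSOS recruitment: elevated non-nuclear intensity inside the illuminated
#' mask, with a Gaussian-blurred edge. Smooth background and additive
#' Gaussian noise degrade both channels; all ground truth (nuclei, burst
#' intervals, rendered foci) is recorded before degradation.
#'
#' @param traj either a `circuit_trajectory` (uniform-field movie: every
#'   nucleus follows it) or a `stripe_sim` (each nucleus follows the
#'   trajectory of its nearest spatial grid position).
#' @param gene which transcription indicator to image: `"byn"`, `"tll"` or
#'   `"hkb"`.
#' @param protocol the [light_protocol()] (needed for the membrane channel);
#'   defaults to an always-lit uniform field.
#' @param schedule an [nc_schedule()]; defaults to the trajectory's.
#' @param imaging an [imaging_params()].
#' @param window_x,window_y field of view (um). For stripe movies, x is the
#'   spatial coordinate (0 = illumination boundary).
#' @param seed integer; rendering is bit-reproducible given the seed.
#' @return object of class `synthetic_movie`: list with `frames` (array
#'   `[ny, nx, 2, n_frames]`), `frame_times`, `truth_nuclei`, `truth_bursts`,
#'   `truth_foci`, `pixel_size`, `window_x`, `window_y`, `metadata`.
#' @export
render_movie <- function(traj, gene = c("byn", "tll", "hkb"),
                         protocol = NULL,
                         schedule = NULL,
                         imaging = imaging_params(),
                         window_x = c(-32, 32), window_y = c(-32, 32),
                         seed = 1) {
  gene <- match.arg(gene)
  is_stripe <- inherits(traj, "stripe_sim")
  if (is.null(schedule)) {
    schedule <- if (is_stripe) traj$schedule else attr(traj, "schedule")
  }
  if (is.null(protocol)) {
    g <- schedule$gastrulation_time
    protocol <- light_protocol(1, rbind(c(0, g)), gastrulation_time = g)
  }
  g <- schedule$gastrulation_time
  frame_times <- seq(0, g - imaging$frame_interval, by = imaging$frame_interval)
  px <- imaging$pixel_size
  xpix <- seq(window_x[1] + px / 2, window_x[2] - px / 2, by = px)
  ypix <- seq(window_y[1] + px / 2, window_y[2] - px / 2, by = px)
  nx <- length(xpix); ny <- length(ypix)

  # counts double exactly at each transition
  area <- diff(window_x) * diff(window_y)
  n10 <- max(1, floor(area / imaging$nc14_spacing^2 / 16))
  counts <- stats::setNames(n10 * 2^(0:4), as.character(10:14))

  gene_col <- paste0("x_", gene)
  withr::with_seed(seed, {
    # --- nuclei and per-nucleus truth ------------------------------------
    nuclei <- list(); bursts <- list()
    for (cc in schedule$cycles$cycle) {
      key <- as.character(cc)
      r <- imaging$nucleus_radii[[key]]
      pos <- place_nuclei(counts[[key]], r, window_x, window_y)
      pos$nucleus_id <- cc * 1000 + seq_len(nrow(pos))
      pos$cycle <- cc
      pos$r <- r
      nuclei[[key]] <- pos
      bounds <- interphase_bounds(schedule, cc)
      for (i in seq_len(nrow(pos))) {
        iv <- nucleus_interval(traj, gene_col, cc, schedule, pos$x[i])
        if (is.null(iv)) next
        t_on <- iv[1] + stats::rnorm(1, 0, imaging$jitter_sd)
        t_on <- min(max(t_on, bounds[1]), iv[2])
        bursts[[length(bursts) + 1]] <- tibble::tibble(
          nucleus_id = pos$nucleus_id[i], cycle = cc,
          x = pos$x[i], y = pos$y[i],
          t_on = t_on, t_off = iv[2])
      }
    }
    truth_nuclei <- dplyr::bind_rows(nuclei)
    truth_bursts <- if (length(bursts) > 0) dplyr::bind_rows(bursts) else
      tibble::tibble(nucleus_id = integer(0), cycle = integer(0),
                     x = numeric(0), y = numeric(0),
                     t_on = numeric(0), t_off = numeric(0))

    # --- rendering -------------------------------------------------------
    recruit_x <- recruitment_profile(xpix, protocol, imaging$membrane_sigma)
    recruit_img <- matrix(recruit_x, ny, nx, byrow = TRUE)
    bg_img <- imaging$background_level +
      imaging$background_gradient * matrix(ypix - window_y[1], ny, nx) /
        diff(window_y)
    frames <- array(0, dim = c(ny, nx, 2, length(frame_times)))
    foci_log <- list()
    for (fi in seq_along(frame_times)) {
      tt <- frame_times[fi]
      cyc <- cycle_at(tt, schedule)
      mcp <- bg_img
      mem <- matrix(imaging$membrane_base, ny, nx)
      if (!is.na(cyc)) {
        pos <- nuclei[[as.character(cyc)]]
        nmask <- nucleus_mask(pos, xpix, ypix)
        mcp <- mcp + imaging$nuc_level * (nmask > 0)
        amp_mem <- imaging$membrane_amplitude * protocol$intensity *
          as.numeric(light_on(tt, protocol))
        mem <- mem + amp_mem * recruit_img * (nmask == 0)
        bb <- truth_bursts[truth_bursts$cycle == cyc &
                             truth_bursts$t_on <= tt &
                             truth_bursts$t_off >= tt, , drop = FALSE]
        if (nrow(bb) > 0) {
          visible <- stats::runif(nrow(bb)) >= imaging$dropout
          for (i in which(visible)) {
            j <- match(bb$nucleus_id[i], pos$nucleus_id)
            off_r <- stats::runif(1, 0, 0.5 * pos$r[j])
            off_a <- stats::runif(1, 0, 2 * pi)
            fx <- pos$x[j] + off_r * cos(off_a)
            fy <- pos$y[j] + off_r * sin(off_a)
            amp <- imaging$focus_intensity *
              exp(stats::rnorm(1, -imaging$focus_cv^2 / 2, imaging$focus_cv))
            cx <- (fx - window_x[1]) / px + 0.5
            cy <- (fy - window_y[1]) / px + 0.5
            mcp <- add_spot(mcp, cx, cy, amp, imaging$focus_sigma / px)
            foci_log[[length(foci_log) + 1]] <- tibble::tibble(
              frame = fi, t = tt, nucleus_id = bb$nucleus_id[i],
              x = fx, y = fy, amplitude = amp)
          }
        }
      }
      if (imaging$noise_sd > 0) {
        mcp <- mcp + matrix(stats::rnorm(ny * nx, 0, imaging$noise_sd), ny, nx)
        mem <- mem + matrix(stats::rnorm(ny * nx, 0, imaging$noise_sd), ny, nx)
      }
      frames[, , 1, fi] <- mcp
      frames[, , 2, fi] <- mem
    }
    truth_foci <- if (length(foci_log) > 0) dplyr::bind_rows(foci_log) else
      tibble::tibble(frame = integer(0), t = numeric(0),
                     nucleus_id = integer(0), x = numeric(0), y = numeric(0),
                     amplitude = numeric(0))
    structure(list(
      frames = frames, frame_times = frame_times,
      truth_nuclei = truth_nuclei, truth_bursts = truth_bursts,
      truth_foci = truth_foci,
      pixel_size = px, window_x = window_x, window_y = window_y,
      metadata = list(gene = gene, seed = seed, schedule = schedule,
                      protocol = protocol, imaging = imaging)
    ), class = "synthetic_movie")
  })
}

# the bursting interval a nucleus at position x would follow, for one cycle
nucleus_interval <- function(traj, gene_col, cc, schedule, x_um) {
  if (inherits(traj, "stripe_sim")) {
    j <- which.min(abs(traj$circuit$x - x_um))
    xind <- traj$circuit[[gene_col]][, j]
    tt <- traj$circuit$t
  } else {
    xind <- traj[[gene_col]]
    tt <- traj$t
  }
  ivs <- indicator_intervals(xind, tt, schedule)
  ivs[[as.character(cc)]]
}

# labeled nucleus image (0 = background, otherwise nucleus_id)
nucleus_mask <- function(pos, xpix, ypix) {
  ny <- length(ypix); nx <- length(xpix)
  lab <- matrix(0L, ny, nx)
  for (i in seq_len(nrow(pos))) {
    ix <- which(abs(xpix - pos$x[i]) <= pos$r[i])
    iy <- which(abs(ypix - pos$y[i]) <= pos$r[i])
    if (length(ix) == 0 || length(iy) == 0) next
    d2 <- outer((ypix[iy] - pos$y[i])^2, (xpix[ix] - pos$x[i])^2, "+")
    sub <- lab[iy, ix, drop = FALSE]
    sub[d2 <= pos$r[i]^2] <- as.integer(pos$nucleus_id[i])
    lab[iy, ix] <- sub
  }
  lab
}

#' Render a boundary (or pole) movie from a stripe simulation
#'
#' Convenience wrapper around [render_movie()] with a viewing window that
#' extends from the illuminated region across the boundary into the
#' unilluminated region; each nucleus follows the trajectory of its nearest
#' spatial grid position, and the membrane channel follows the blurred mask
#' profile.
#'
#' @param stripe a `stripe_sim` from [simulate_stripe()].
#' @param gene indicator to image.
#' @param protocol the masked [light_protocol()] (defaults to metadata-free
#'   half-plane high light; pass the scenario's protocol).
#' @param imaging an [imaging_params()].
#' @param window_x,window_y field of view (um).
#' @param seed integer seed.
#' @return a `synthetic_movie`.
#' @export
render_boundary_movie <- function(stripe, gene = "byn", protocol = NULL,
                                  imaging = imaging_params(),
                                  window_x = c(-30, 66),
                                  window_y = c(-40, 40),
                                  seed = 1) {
  if (is.null(protocol)) {
    g <- stripe$schedule$gastrulation_time
    protocol <- light_protocol(1, rbind(c(0, g)),
                               matrix(c(-Inf, stripe$boundary), ncol = 2),
                               gastrulation_time = g)
  }
  rng <- range(stripe$circuit$x)
  if (window_x[1] < rng[1] || window_x[2] > rng[2]) {
    stop("viewing window exceeds the simulated spatial grid")
  }
  render_movie(stripe, gene = gene, protocol = protocol,
               schedule = stripe$schedule, imaging = imaging,
               window_x = window_x, window_y = window_y, seed = seed)
}

#' Write / read a synthetic movie as multi-page TIFF
#'
#' Pages are channel-interleaved (ch1 frame 1, ch2 frame 1, ch1 frame 2, ...)
#' and stored as 16-bit. Intensities are clipped to [0, 1] on write. Truth
#' tables are written alongside as CSV when `truth = TRUE`.
#'
#' @param movie a `synthetic_movie`.
#' @param path TIFF file path.
#' @param truth also write `<path>_nuclei.csv` and `<path>_bursts.csv`.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, truth = TRUE) {
  nt <- dim(movie$frames)[4]
  pages <- vector("list", 2 * nt)
  for (fi in seq_len(nt)) {
    pages[[2 * fi - 1]] <- pmin(pmax(movie$frames[, , 1, fi], 0), 1)
    pages[[2 * fi]] <- pmin(pmax(movie$frames[, , 2, fi], 0), 1)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  if (truth) {
    base <- sub("\\.tiff?$", "", path)
    utils::write.csv(movie$truth_nuclei, paste0(base, "_nuclei.csv"),
                     row.names = FALSE)
    utils::write.csv(movie$truth_bursts, paste0(base, "_bursts.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_movie
#' @param frame_interval,pixel_size acquisition metadata for the reader.
#' @export
read_movie_frames <- function(path, frame_interval = 0.5, pixel_size = 0.5) {
  pages <- tiff::readTIFF(path, all = TRUE)
  nt <- length(pages) / 2
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  frames <- array(0, dim = c(ny, nx, 2, nt))
  for (fi in seq_len(nt)) {
    frames[, , 1, fi] <- pages[[2 * fi - 1]]
    frames[, , 2, fi] <- pages[[2 * fi]]
  }
  list(frames = frames,
       frame_times = seq(0, by = frame_interval, length.out = nt),
       pixel_size = pixel_size)
}
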