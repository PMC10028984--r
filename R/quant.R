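#' Background subtraction and projection
#'
#' Rolling-ball-style background removal implemented as a grayscale
#' morphological opening with a disc structuring element of the given radius,
#' subtracted from each frame, followed by a maximum projection across
#' z-planes. Synthetic movies are single-plane, so the projection stage is
#' the identity; it is kept so the pipeline's interface matches multi-plane
#' acquisitions.
#'
#' @param frames a 2-D matrix (one frame), a 3-D array `[ny, nx, n_frames]`,
#'   or a list of z-planes (each a 2-D matrix or 3-D stack) to be projected.
#' @param radius rolling-ball radius in pixels (> 0).
#' @return same shape as the input frames, background subtracted (and
#'   z-projected when a list is given).
#' @export
preprocess <- function(frames, radius = 50) {
  if (radius <= 0) stop("radius must be > 0")
  if (is.list(frames)) {
    planes <- lapply(frames, preprocess, radius = radius)
    out <- planes[[1]]
    for (p in planes[-1]) out <- pmax(out, p)
    return(out)
  }
  sub1 <- function(img) {
    d <- 2 * min(radius, floor((min(dim(img)) - 1) / 2)) + 1
    brush <- EBImage::makeBrush(d, shape = "disc")
    bg <- EBImage::opening(img, brush)
    img - bg
  }
  if (is.matrix(frames)) return(sub1(frames))
  out <- frames
  for (fi in seq_len(dim(frames)[3])) out[, , fi] <- sub1(frames[, , fi])
  out
}

# labeled nucleus masks for every frame of a movie, from ground truth
truth_mask_stack <- function(movie) {
  sch <- movie$metadata$schedule
  px <- movie$pixel_size
  xpix <- seq(movie$window_x[1] + px / 2, movie$window_x[2] - px / 2, by = px)
  ypix <- seq(movie$window_y[1] + px / 2, movie$window_y[2] - px / 2, by = px)
  cycles <- cycle_at(movie$frame_times, sch)
  per_cycle <- list()
  for (cc in unique(stats::na.omit(cycles))) {
    pos <- movie$truth_nuclei[movie$truth_nuclei$cycle == cc, ]
    per_cycle[[as.character(cc)]] <- nucleus_mask(pos, xpix, ypix)
  }
  lapply(seq_along(movie$frame_times), function(fi) {
    cc <- cycles[fi]
    if (is.na(cc)) matrix(0L, length(ypix), length(xpix))
    else per_cycle[[as.character(cc)]]
  })
}

#' Segment nuclei by thresholding (fallback when no truth masks exist)
#'
#' Adaptive Otsu threshold on a lightly smoothed frame followed by connected
#' component labelling and a size filter.
#'
#' @param frame 2-D matrix (MCP channel, background subtracted).
#' @param min_area minimum object area in pixels.
#' @return integer label matrix.
#' @export
segment_nuclei <- function(frame, min_area = 20) {
  img <- EBImage::gblur(frame, sigma = 2)
  thr <- EBImage::otsu(EBImage::Image(pmin(pmax(img, 0), 1)))
  lab <- EBImage::bwlabel(img > thr)
  tab <- table(lab[lab > 0])
  keep <- as.integer(names(tab)[tab >= min_area])
  lab[!(lab %in% keep)] <- 0L
  EBImage::imageData(EBImage::bwlabel(lab > 0))
}

#' Detect MS2 foci and assign them to nuclei
#'
#' A pixel is called a focus candidate if it is a local maximum (strictly
#' greater than its 8 neighbours), lies inside a nucleus mask, and rises
#' above that nucleus's fill level by more than k times the robust noise:
#' `intensity > median(nucleus pixels) + k * MAD(non-nuclear background)`.
#' At most one focus per nucleus per frame is kept (the brightest). This is
#' the automated stand-in for the manual "visible focus" call: prominence
#' above the nuclear fill, judged against the image noise.
#'
#' @param frames processed MCP stack `[ny, nx, n_frames]` (see [preprocess()]),
#'   or a `synthetic_movie` (its channel 1 is preprocessed automatically).
#' @param masks list of per-frame labeled nucleus masks; defaults to the
#'   ground-truth masks when `frames` is a `synthetic_movie`.
#' @param k MAD multiplier of the detection threshold.
#' @param frame_times frame times (min); taken from the movie when available.
#' @param pixel_size um per pixel, for reporting focus coordinates.
#' @param window_x,window_y field origin, for reporting focus coordinates.
#' @param radius rolling-ball radius passed to [preprocess()].
#' @return tibble with columns `frame`, `t`, `nucleus_id`, `x`, `y`,
#'   `intensity`.
#' @export
detect_foci <- function(frames, masks = NULL, k = 5, frame_times = NULL,
                        pixel_size = 0.5, window_x = c(0, 0),
                        window_y = c(0, 0), radius = 50) {
  if (inherits(frames, "synthetic_movie")) {
    movie <- frames
    if (is.null(masks)) masks <- truth_mask_stack(movie)
    frame_times <- movie$frame_times
    pixel_size <- movie$pixel_size
    window_x <- movie$window_x
    window_y <- movie$window_y
    frames <- preprocess(movie$frames[, , 1, ], radius = radius)
  }
  if (is.null(masks) || length(masks) == 0) {
    stop("detect_foci requires nucleus masks (truth or segmented)")
  }
  nt <- dim(frames)[3]
  if (is.null(frame_times)) frame_times <- seq_len(nt)
  out <- list()
  for (fi in seq_len(nt)) {
    img <- frames[, , fi]
    lab <- masks[[fi]]
    if (all(lab == 0)) next
    bg <- img[lab == 0]
    if (length(bg) == 0) stop("frame is fully nuclear; no background pixels")
    noise <- k * stats::mad(bg)
    fill <- tapply(img[lab > 0], lab[lab > 0], stats::median)
    mx <- local_maxima(img)
    cand <- which(mx & lab > 0, arr.ind = TRUE)
    if (nrow(cand) == 0) next
    vals <- img[cand]
    ids <- lab[cand]
    keep <- vals > fill[as.character(ids)] + noise
    cand <- cand[keep, , drop = FALSE]
    if (nrow(cand) == 0) next
    vals <- vals[keep]
    ids <- ids[keep]
    df <- data.frame(row = cand[, 1], col = cand[, 2],
                     intensity = vals, nucleus_id = ids)
    df <- df[order(df$nucleus_id, -df$intensity), ]
    df <- df[!duplicated(df$nucleus_id), ]
    out[[length(out) + 1]] <- tibble::tibble(
      frame = fi, t = frame_times[fi],
      nucleus_id = df$nucleus_id,
      x = window_x[1] + (df$col - 0.5) * pixel_size,
      y = window_y[1] + (df$row - 0.5) * pixel_size,
      intensity = df$intensity)
  }
  if (length(out) == 0) {
    return(tibble::tibble(frame = integer(0), t = numeric(0),
                          nucleus_id = integer(0), x = numeric(0),
                          y = numeric(0), intensity = numeric(0)))
  }
  dplyr::bind_rows(out)
}

# strict 8-neighbour local maxima (borders excluded)
local_maxima <- function(img) {
  ny <- nrow(img); nx <- ncol(img)
  out <- matrix(FALSE, ny, nx)
  ci <- 2:(ny - 1); cj <- 2:(nx - 1)
  m <- img[ci, cj]
  out[ci, cj] <-
    m > img[ci - 1, cj] & m > img[ci + 1, cj] &
    m > img[ci, cj - 1] & m > img[ci, cj + 1] &
    m > img[ci - 1, cj - 1] & m > img[ci - 1, cj + 1] &
    m > img[ci + 1, cj - 1] & m > img[ci + 1, cj + 1]
  out
}

#' Quantification boxes
#'
#' Fixed-size regions used to standardise which nuclei are quantified:
#' `anterior_extent_50x45` (50 x 45 um, leading edge at the most anterior
#' extent of NC14 transcription) and `boundary_shift_30x75` (30 x 75 um in
#' the unilluminated region, far edge at the farthest NC14 transcription from
#' the boundary; when the extent is within 30 um of the boundary the box
#' abuts the boundary). Boxes are half-open on their trailing (x) and top (y)
#' edges so adjacent boxes never double-count a nucleus.
#'
#' @param foci focus-call tibble from [detect_foci()] (NC14 calls are used).
#' @param kind `"anterior_extent_50x45"` or `"boundary_shift_30x75"`.
#' @param boundary x coordinate (um) of the illumination boundary.
#' @param center_y vertical centre (um) of the box.
#' @param nc14_start start of NC14 (min), to select NC14 calls.
#' @return list of class `quant_box`: `kind`, `xlim`, `ylim`.
#' @export
place_box <- function(foci, kind = c("anterior_extent_50x45",
                                     "boundary_shift_30x75"),
                      boundary = 0, center_y = 0, nc14_start = 48) {
  kind <- match.arg(kind)
  f14 <- foci[foci$t >= nc14_start, , drop = FALSE]
  if (nrow(f14) == 0) {
    stop("no NC14 transcription detected anywhere; ",
         "fall back to a mask-anchored default box")
  }
  if (kind == "anterior_extent_50x45") {
    lead <- min(f14$x)
    xlim <- c(lead, lead + 50)
    ylim <- c(center_y - 45 / 2, center_y + 45 / 2)
  } else {
    beyond <- f14$x[f14$x > boundary]
    far <- if (length(beyond) == 0) boundary else max(beyond)
    far <- max(far, boundary + 30)  # abut the boundary for small extents
    xlim <- c(far - 30, far)
    ylim <- c(center_y - 75 / 2, center_y + 75 / 2)
  }
  structure(list(kind = kind, xlim = xlim, ylim = ylim), class = "quant_box")
}

in_box <- function(x, y, box) {
  x >= box$xlim[1] & x < box$xlim[2] & y >= box$ylim[1] & y < box$ylim[2]
}

#' Annotate per-nucleus bursting states
#'
#' Each nuclear cycle is analysed independently. The start of a cycle is the
#' time when reformed nuclei are first visible within the quantified region
#' (not the global schedule). Per nucleus and cycle, the bursting interval
#' runs from the first to the last detected focus, and the nucleus is in the
#' bursting state at every time point inside it, even where no focus was
#' detected (dropout bridging). A nucleus with a single-frame focus gets a
#' one-frame-interval burst.
#'
#' @param foci tibble from [detect_foci()].
#' @param nuclei per-cycle nucleus table (columns `nucleus_id`, `cycle`, `x`,
#'   `y`), e.g. `movie$truth_nuclei`; defines the denominator.
#' @param frame_times all frame times of the movie (min).
#' @param schedule an [nc_schedule()] (used to map frames to cycles for the
#'   appearance rule).
#' @param region optional `quant_box`; nuclei outside it are excluded.
#' @param frame_interval minutes per frame (for one-frame burst durations).
#' @param appearance optional named numeric vector of per-cycle first
#'   appearance times in the region (minutes), overriding the schedule-based
#'   default; use when the mitotic wave reaches the region late.
#' @return a `burst_table`: tibble with one row per (nucleus, cycle) in the
#'   region — `nucleus_id`, `cycle`, `x`, `y`, `first_focus`, `last_focus`,
#'   `duration`, `bursting` — with attributes `cycle_starts` (per-cycle first
#'   appearance in the region) and `frame_interval`.
#' @export
annotate_bursting <- function(foci, nuclei, frame_times,
                              schedule = nc_schedule(), region = NULL,
                              frame_interval = NULL, appearance = NULL) {
  if (is.null(frame_interval)) {
    frame_interval <- if (length(frame_times) > 1) diff(frame_times[1:2]) else 0.5
  }
  if (!is.null(region)) {
    nuclei <- nuclei[in_box(nuclei$x, nuclei$y, region), , drop = FALSE]
    foci <- foci[foci$nucleus_id %in% nuclei$nucleus_id, , drop = FALSE]
  }
  if (nrow(nuclei) == 0) stop("no nuclei in the quantified region")
  cycles_present <- sort(unique(nuclei$cycle))
  frame_cycles <- cycle_at(frame_times, schedule)
  cycle_starts <- vapply(cycles_present, function(cc) {
    idx <- which(frame_cycles == cc)
    if (length(idx) == 0) NA_real_ else frame_times[min(idx)]
  }, numeric(1))
  names(cycle_starts) <- cycles_present
  if (!is.null(appearance)) {
    cycle_starts[names(appearance)] <- appearance
  }

  if (nrow(foci) > 0) {
    rows <- dplyr::group_by(foci, .data$nucleus_id)
    rows <- dplyr::summarise(rows, first_focus = min(.data$t),
                             last_focus = max(.data$t), .groups = "drop")
  } else {
    rows <- tibble::tibble(nucleus_id = integer(0), first_focus = numeric(0),
                           last_focus = numeric(0))
  }
  tab <- dplyr::left_join(nuclei, rows, by = "nucleus_id")
  # duration = last - first focus time; a single-frame focus counts one
  # frame interval
  tab$duration <- ifelse(
    is.na(tab$first_focus), 0,
    pmax(tab$last_focus - tab$first_focus, frame_interval))
  tab$bursting <- tab$duration > 0
  tab <- tibble::as_tibble(tab[, c("nucleus_id", "cycle", "x", "y",
                                   "first_focus", "last_focus", "duration",
                                   "bursting")])
  attr(tab, "cycle_starts") <- cycle_starts
  attr(tab, "frame_interval") <- frame_interval
  class(tab) <- c("burst_table", class(tab))
  tab
}

#' Is each nucleus in the bursting state at time t?
#' @param table a `burst_table`.
#' @param t a single time (min).
#' @return logical vector along the rows of `table`.
#' @export
in_bursting_state <- function(table, t) {
  !is.na(table$first_focus) & t >= table$first_focus & t <= table$last_focus
}

#' Proportion of nuclei in the bursting state
#'
#' Denominators are all nuclei of the cycle within the quantified region,
#' whether or not they ever burst.
#'
#' @param table a `burst_table`.
#' @param by `"cycle"` (fraction ever bursting per cycle) or `"timepoint"`
#'   (fraction in the bursting state at each requested time).
#' @param times time grid for `by = "timepoint"`.
#' @return tibble: `cycle`, `n`, `proportion` — or `t`, `cycle`, `n`,
#'   `proportion`.
#' @export
proportion_bursting <- function(table, by = c("cycle", "timepoint"),
                                times = NULL) {
  by <- match.arg(by)
  if (nrow(table) == 0) stop("empty burst table")
  if (by == "cycle") {
    out <- dplyr::summarise(
      dplyr::group_by(tibble::as_tibble(table), .data$cycle),
      n = dplyr::n(), proportion = mean(.data$bursting), .groups = "drop")
    return(out)
  }
  if (is.null(times)) stop("supply `times` for by = \"timepoint\"")
  starts <- attr(table, "cycle_starts")
  purrr::map_dfr(times, function(tt) {
    # the cycle whose observation window contains tt
    cyc_keys <- as.integer(names(starts))
    active <- cyc_keys[!is.na(starts) & starts <= tt]
    if (length(active) == 0) return(NULL)
    cc <- max(active)
    rows <- table[table$cycle == cc, , drop = FALSE]
    tibble::tibble(t = tt, cycle = cc, n = nrow(rows),
                   proportion = mean(in_bursting_state(rows, tt)))
  })
}

#' Time to 50% of nuclei in the bursting state
#'
#' Two-step rule: find the first nuclear cycle in which at least 50% of
#' nuclei are in a bursting state and at least 50% remain bursting in every
#' subsequent cycle; within that cycle, report the time (minutes since
#' illumination onset) at which the ceiling(n/2)-th nucleus entered the
#' bursting state. Returns `Inf` ("never") if no cycle qualifies.
#'
#' @param table a `burst_table` spanning one or more cycles.
#' @param t_light_on time illumination began (min).
#' @return minutes since illumination onset, or `Inf`.
#' @export
time_to_half <- function(table, t_light_on = 0) {
  props <- proportion_bursting(table, by = "cycle")
  props <- props[order(props$cycle), ]
  ok <- props$proportion >= 0.5
  qualifying <- which(ok & rev(cumprod(rev(ok))) == 1)
  if (length(qualifying) == 0) return(Inf)
  cc <- props$cycle[min(qualifying)]
  rows <- table[table$cycle == cc & table$bursting, , drop = FALSE]
  n <- sum(table$cycle == cc)
  m <- ceiling(n / 2)
  entries <- sort(rows$first_focus)
  if (length(entries) < m) return(Inf)
  entries[m] - t_light_on
}

#' Membrane OptoSOS enrichment
#'
#' Difference in mean membrane-channel intensity between the illuminated and
#' an unilluminated region at the same position, using only non-nuclear
#' pixels (in NC14 there is little free cytoplasm, so every non-nuclear pixel
#' is included).
#'
#' @param movie a `synthetic_movie` (channel 2 is used), or a 3-D membrane
#'   stack plus explicit `masks`.
#' @param boundary x coordinate (um) of the illumination boundary.
#' @param frames which frame indices to average (default: NC14 frames).
#' @param masks optional list of per-frame label matrices.
#' @return mean enrichment (illuminated minus unilluminated), a.u.
#' @export
membrane_enrichment <- function(movie, boundary = 0, frames = NULL,
                                masks = NULL) {
  sch <- movie$metadata$schedule
  if (is.null(frames)) {
    b14 <- interphase_bounds(sch, 14)
    frames <- which(movie$frame_times >= b14[1] & movie$frame_times < b14[2])
  }
  if (is.null(masks)) masks <- truth_mask_stack(movie)
  px <- movie$pixel_size
  xpix <- seq(movie$window_x[1] + px / 2, movie$window_x[2] - px / 2, by = px)
  lit_col <- xpix < boundary
  vals <- vapply(frames, function(fi) {
    img <- movie$frames[, , 2, fi]
    nonnuc <- masks[[fi]] == 0
    lit_px <- nonnuc & matrix(lit_col, nrow(img), ncol(img), byrow = TRUE)
    unlit_px <- nonnuc & !matrix(lit_col, nrow(img), ncol(img), byrow = TRUE)
    if (!any(lit_px) || !any(unlit_px)) {
      stop("a region is fully nuclear; cannot measure membrane enrichment")
    }
    mean(img[lit_px]) - mean(img[unlit_px])
  }, numeric(1))
  mean(vals)
}

#' Membrane intensity profile vs distance from the boundary
#'
#' Median non-nuclear membrane-channel intensity at each pixel column over
#' the requested frames (nuclei are segmented out, as for the enrichment
#' measurement), as a function of signed distance from the illumination
#' boundary, normalised so the maximum is exactly 1.
#'
#' @inheritParams membrane_enrichment
#' @return tibble with `distance` (um, positive into the unilluminated
#'   region) and `intensity` (max-normalised).
#' @export
boundary_profile <- function(movie, boundary = 0, frames = NULL,
                             masks = NULL) {
  sch <- movie$metadata$schedule
  if (is.null(frames)) {
    b14 <- interphase_bounds(sch, 14)
    frames <- which(movie$frame_times >= b14[1] & movie$frame_times < b14[2])
  }
  if (is.null(masks)) masks <- truth_mask_stack(movie)
  px <- movie$pixel_size
  xpix <- seq(movie$window_x[1] + px / 2, movie$window_x[2] - px / 2, by = px)
  med <- vapply(seq_along(xpix), function(j) {
    vals <- unlist(lapply(frames, function(fi) {
      col <- movie$frames[, j, 2, fi]
      col[masks[[fi]][, j] == 0]
    }))
    stats::median(vals)
  }, numeric(1))
  tibble::tibble(distance = xpix - boundary, intensity = med / max(med))
}

#' Quantify a synthetic movie end to end
#'
#' Preprocess, detect foci (truth or segmented masks), annotate bursting and
#' compute the summary statistics of the study: per-cycle and NC14 bursting
#' proportions, mean NC14 bursting duration, and the time-to-50% statistic.
#'
#' @param movie a `synthetic_movie`.
#' @param region optional `quant_box`.
#' @param k detection threshold multiplier.
#' @param mode `"truth-masks"` (ground-truth nucleus masks) or `"segment"`.
#' @param t_light_on illumination start (min).
#' @param radius background-subtraction radius (px).
#' @return list with `foci`, `table`, and `stats` (list: `duration_nc14`,
#'   `time_to_half`, `proportions`).
#' @export
quantify_movie <- function(movie, region = NULL, k = 5,
                           mode = c("truth-masks", "segment"),
                           t_light_on = 0, radius = 50) {
  mode <- match.arg(mode)
  sch <- movie$metadata$schedule
  processed <- preprocess(movie$frames[, , 1, ], radius = radius)
  masks <- if (mode == "truth-masks") {
    truth_mask_stack(movie)
  } else {
    lapply(seq_len(dim(processed)[3]), function(fi)
      segment_nuclei(processed[, , fi]))
  }
  foci <- detect_foci(processed, masks, k = k,
                      frame_times = movie$frame_times,
                      pixel_size = movie$pixel_size,
                      window_x = movie$window_x, window_y = movie$window_y)
  table <- annotate_bursting(foci, movie$truth_nuclei, movie$frame_times,
                             schedule = sch, region = region)
  rows14 <- table[table$cycle == 14, , drop = FALSE]
  stats <- list(
    duration_nc14 = if (nrow(rows14) > 0) mean(rows14$duration) else 0,
    time_to_half = time_to_half(table, t_light_on = t_light_on),
    proportions = proportion_bursting(table, by = "cycle")
  )
  list(foci = foci, table = table, stats = stats)
}
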