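# shared fixtures and independent oracles

# a single uninterrupted interphase: no mitosis, no snapping
flat_schedule <- function(t_end = 200) {
  nc_schedule(data.frame(cycle = 14, start = 0, end = t_end),
              gastrulation_time = t_end)
}

# parameters with the NC14 sensitivity window pushed out of the way, for
# closed-form onset oracles on the flat schedule
flat_params <- function(...) circuit_params(window_close = 1e6, ...)

# independent brute-force implementation of the two-step time-to-50% rule,
# written directly from the verbal definition (loops, no shared code)
tth_oracle <- function(tab, t_light_on = 0) {
  cycles <- sort(unique(tab$cycle))
  props <- vapply(cycles, function(cc) mean(tab$bursting[tab$cycle == cc]),
                  numeric(1))
  for (i in seq_along(cycles)) {
    if (all(props[i:length(cycles)] >= 0.5)) {
      cc <- cycles[i]
      n <- sum(tab$cycle == cc)
      ent <- sort(tab$first_focus[tab$cycle == cc & tab$bursting])
      m <- ceiling(n / 2)
      if (length(ent) < m) return(Inf)
      return(ent[m] - t_light_on)
    }
  }
  Inf
}

# construct a burst table directly (bypassing detection) for rule tests
make_table <- function(df, cycle_starts = NULL, frame_interval = 0.5) {
  df <- tibble::as_tibble(df)
  if (!"bursting" %in% names(df)) df$bursting <- !is.na(df$first_focus)
  if (!"duration" %in% names(df)) {
    df$duration <- ifelse(is.na(df$first_focus), 0,
                          pmax(df$last_focus - df$first_focus, frame_interval))
  }
  if (!"x" %in% names(df)) df$x <- 0
  if (!"y" %in% names(df)) df$y <- 0
  if (is.null(cycle_starts)) {
    sch <- nc_schedule()
    cycles <- sort(unique(df$cycle))
    cycle_starts <- stats::setNames(
      vapply(cycles, function(cc) interphase_bounds(sch, cc)[1], numeric(1)),
      cycles)
  }
  attr(df, "cycle_starts") <- cycle_starts
  attr(df, "frame_interval") <- frame_interval
  class(df) <- c("burst_table", class(df))
  df
}

random_burst_table <- function(seed) {
  withr::with_seed(seed, {
    rows <- list()
    id <- 0
    for (cc in 11:14) {
      n <- sample(3:8, 1)
      start <- (cc - 11) * 12
      for (i in seq_len(n)) {
        id <- id + 1
        if (stats::runif(1) < 0.6) {
          f <- start + stats::runif(1, 0, 8)
          l <- f + stats::runif(1, 0, 3)
        } else {
          f <- NA_real_; l <- NA_real_
        }
        rows[[id]] <- data.frame(nucleus_id = id, cycle = cc,
                                 first_focus = f, last_focus = l)
      }
    }
    make_table(do.call(rbind, rows))
  })
}

# small fast movie for pipeline tests
small_movie <- function(scenario = "low_continuous", gene = "byn", seed = 1,
                        imaging = imaging_params(), window = 48) {
  sch <- nc_schedule()
  tr <- simulate_embryo(build_scenario(scenario, sch), params = circuit_params())
  render_movie(tr, gene = gene, schedule = sch, imaging = imaging,
               window_x = c(-window / 2, window / 2),
               window_y = c(-window / 2, window / 2), seed = seed)
}
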