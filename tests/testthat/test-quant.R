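test_that("background subtraction removes flat fields and keeps spots", {
  flat <- matrix(0.3, 64, 64)
  expect_true(all(abs(preprocess(flat, radius = 10)) < 1e-9))

  img <- matrix(0.1, 64, 64)
  img <- stripedyn:::add_spot(img, 32, 32, amp = 0.6, sigma_px = 1.2)
  out <- preprocess(img, radius = 10)
  expect_lt(abs(max(out) - 0.6) / 0.6, 0.05)     # spot preserved
  expect_lt(stats::median(abs(out)), 1e-6)       # background removed

  # projection stage: single plane is the identity, planes are max-combined
  expect_identical(preprocess(list(img), radius = 10),
                   preprocess(img, radius = 10))
  two <- preprocess(list(img, 0.5 * img), radius = 10)
  expect_equal(two, preprocess(img, radius = 10))

  expect_error(preprocess(img, radius = 0), "radius")
})

test_that("a noiseless focus yields exactly one call in the right nucleus", {
  pos <- tibble::tibble(x = c(-8, 8), y = c(0, 0), r = 4,
                        nucleus_id = c(101, 102))
  xpix <- seq(-15.75, 15.75, 0.5)
  lab <- stripedyn:::nucleus_mask(pos, xpix, xpix)
  img <- matrix(0, 64, 64) + 0.12 * (lab > 0)
  img <- stripedyn:::add_spot(img, (8 + 16) / 0.5 + 0.3, 32.6, 0.5, 1.2)
  frames <- array(img, dim = c(64, 64, 1))
  calls <- detect_foci(frames, list(lab), k = 5,
                       frame_times = 0, pixel_size = 0.5,
                       window_x = c(-16, 16), window_y = c(-16, 16))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$nucleus_id, 102)
  expect_lt(abs(calls$x - 8), 1)

  expect_error(detect_foci(frames, list(), k = 5), "masks")
})

test_that("mitosis frames produce no focus calls", {
  mv <- small_movie(seed = 21)
  q <- quantify_movie(mv)
  mitosis <- which(!in_interphase(mv$frame_times, mv$metadata$schedule))
  expect_false(any(q$foci$frame %in% mitosis))
})

test_that("bursting state bridges dropout between first and last focus", {
  foci <- tibble::tibble(frame = c(7, 20), t = c(3.0, 9.5),
                         nucleus_id = 1, x = 0, y = 0, intensity = 1)
  nuclei <- tibble::tibble(nucleus_id = 1, cycle = 11, x = 0, y = 0)
  tab <- annotate_bursting(foci, nuclei, frame_times = seq(0, 15, 0.5),
                           schedule = nc_schedule())
  expect_equal(tab$duration, 6.5)
  expect_true(in_bursting_state(tab, 6.0))       # despite the dropout
  expect_false(in_bursting_state(tab, 9.6))
  # a nucleus without foci has zero duration and is never bursting
  nuclei2 <- dplyr::bind_rows(nuclei,
                              tibble::tibble(nucleus_id = 2, cycle = 11,
                                             x = 5, y = 5))
  tab2 <- annotate_bursting(foci, nuclei2, frame_times = seq(0, 15, 0.5),
                            schedule = nc_schedule())
  expect_equal(tab2$duration[tab2$nucleus_id == 2], 0)
  expect_false(in_bursting_state(tab2, 6.0)[2])
  # a single-frame focus counts one frame interval
  tab3 <- annotate_bursting(foci[1, ], nuclei, seq(0, 15, 0.5),
                            schedule = nc_schedule())
  expect_equal(tab3$duration, 0.5)
})

test_that("proportions count all nuclei in the region", {
  tab <- make_table(data.frame(
    nucleus_id = 1:4, cycle = 12,
    first_focus = c(19, 20, NA, NA), last_focus = c(25, 24, NA, NA)))
  pr <- proportion_bursting(tab)
  expect_equal(pr$proportion, 0.5)               # 2 of 4
  expect_equal(pr$n, 4)
  tab_all <- make_table(data.frame(
    nucleus_id = 1:3, cycle = 12, first_focus = c(19, 19, 20),
    last_focus = c(28, 27, 26)))
  expect_equal(proportion_bursting(tab_all)$proportion, 1)
  expect_error(proportion_bursting(tab[0, ]), "empty")

  # timepoint mode uses the per-cycle denominator
  pt <- proportion_bursting(tab, by = "timepoint", times = c(21, 26))
  expect_equal(pt$proportion, c(0.5, 0))
})

test_that("time_to_half follows the two-step rule on constructed tables", {
  # four nuclei entering at 2, 4, 6, 8 in NC11; later cycles all bursting
  entries <- data.frame(
    nucleus_id = 1:12,
    cycle = rep(c(11, 12, 13), each = 4),
    first_focus = c(2, 4, 6, 8, 19, 19, 20, 21, 33, 33, 34, 35))
  entries$last_focus <- entries$first_focus + 2
  tab <- make_table(entries)
  expect_equal(time_to_half(tab), 4)             # second of four

  # simultaneous entry at the NC11 start, illumination at 0
  sim <- make_table(data.frame(nucleus_id = 1:4, cycle = 11,
                               first_focus = 7, last_focus = 12))
  expect_equal(time_to_half(sim), 7)

  # a 60% cycle followed by a 40% cycle does not qualify; search continues
  mixed <- make_table(data.frame(
    nucleus_id = 1:15,
    cycle = rep(c(11, 12, 13), each = 5),
    first_focus = c(8, 9, 10, NA, NA,      # 60%
                    20, 21, NA, NA, NA,    # 40%
                    33, 34, 35, NA, NA),   # 60%, qualifies
    last_focus = c(12, 12, 12, NA, NA, 24, 24, NA, NA, NA, 40, 40, 40, NA, NA)))
  expect_equal(time_to_half(mixed), 35)          # ceiling(5/2) = 3rd entrant

  # no qualifying cycle
  none <- make_table(data.frame(nucleus_id = 1:4, cycle = 11,
                                first_focus = c(8, NA, NA, NA),
                                last_focus = c(10, NA, NA, NA)))
  expect_identical(time_to_half(none), Inf)
})

test_that("time_to_half agrees with the brute-force oracle on random tables", {
  for (seed in 1:100) {
    tab <- random_burst_table(seed)
    expect_identical(time_to_half(tab), tth_oracle(tab))
  }
})

test_that("time_to_half shifts exactly with a uniform entry-time shift", {
  for (seed in c(3, 14, 59)) {
    tab <- random_burst_table(seed)
    base <- time_to_half(tab)
    if (!is.finite(base)) next
    delta <- 2.5
    shifted <- tab
    shifted$first_focus <- shifted$first_focus + delta
    shifted$last_focus <- shifted$last_focus + delta
    expect_equal(time_to_half(shifted), base + delta)
  }
})

test_that("statistics are invariant to relabeling and interior focus calls", {
  tab <- random_burst_table(8)
  perm <- make_table(tab[sample.int(nrow(tab)), ])
  expect_identical(time_to_half(perm), time_to_half(tab))
  pr1 <- proportion_bursting(tab)
  pr2 <- proportion_bursting(perm)
  expect_equal(pr1, pr2[order(pr2$cycle), ])

  # inserting a focus strictly inside an interval changes nothing downstream
  foci <- tibble::tibble(frame = c(1, 10), t = c(3, 8),
                         nucleus_id = 5, x = 0, y = 0, intensity = 1)
  nuc <- tibble::tibble(nucleus_id = 5, cycle = 11, x = 0, y = 0)
  t_grid <- seq(0, 15, 0.5)
  a <- annotate_bursting(foci, nuc, t_grid, nc_schedule())
  foci2 <- dplyr::bind_rows(foci, tibble::tibble(frame = 5, t = 5.5,
                                                 nucleus_id = 5, x = 0, y = 0,
                                                 intensity = 2))
  b <- annotate_bursting(foci2, nuc, t_grid, nc_schedule())
  expect_equal(a$duration, b$duration)
  expect_identical(time_to_half(a), time_to_half(b))
})

test_that("region cycle starts can follow a delayed mitotic wave", {
  foci <- tibble::tibble(frame = 1, t = 9, nucleus_id = 1, x = 0, y = 0,
                         intensity = 1)
  nuc <- tibble::tibble(nucleus_id = 1, cycle = 11, x = 0, y = 0)
  tab <- annotate_bursting(foci, nuc, seq(0, 15, 0.5), nc_schedule(),
                           appearance = c(`11` = 8.5))
  expect_equal(attr(tab, "cycle_starts")[["11"]], 8.5)
  # proportions at a timepoint before the wave arrives are empty
  expect_equal(nrow(proportion_bursting(tab, "timepoint", times = 8)), 0)
  expect_equal(proportion_bursting(tab, "timepoint", times = 9)$proportion, 1)
})

test_that("quantification boxes have exact sizes and follow the extent rules", {
  foci <- tibble::tibble(frame = 1, t = c(50, 52, 55),
                         nucleus_id = 1:3, x = c(-20, 5, 41), y = c(0, 3, -2),
                         intensity = 1)
  ant <- place_box(foci, "anterior_extent_50x45")
  expect_equal(diff(ant$xlim), 50)
  expect_equal(diff(ant$ylim), 45)
  expect_equal(ant$xlim[1], -20)                 # leading edge at the extent

  bnd <- place_box(foci, "boundary_shift_30x75", boundary = 0)
  expect_equal(diff(bnd$xlim), 30)
  expect_equal(diff(bnd$ylim), 75)
  expect_equal(bnd$xlim[2], 41)                  # far edge at the extent

  # extent at (or within 30 um of) the boundary: the box abuts the boundary
  near <- foci
  near$x <- c(-20, -5, 0.5)
  bx <- place_box(near, "boundary_shift_30x75", boundary = 0)
  expect_equal(bx$xlim, c(0, 30))

  # no NC14 transcription anywhere: explicit error suggesting the fallback
  expect_error(place_box(foci[foci$t > 60, ], "anterior_extent_50x45"),
               "fall back")

  # box membership is half-open on the trailing edges
  expect_true(stripedyn:::in_box(41 - 30, 0, bnd))
  expect_false(stripedyn:::in_box(41, 0, bnd))
})

test_that("membrane enrichment recovers the rendered recruitment amplitude", {
  st <- simulate_stripe(build_scenario("boundary_high"))
  protocol <- build_scenario("boundary_high")$protocol
  im <- imaging_params()
  mv <- render_boundary_movie(st, gene = "byn", protocol = protocol,
                              imaging = im, window_x = c(-40, 40),
                              window_y = c(-25, 25), seed = 2)
  enr <- membrane_enrichment(mv)
  expect_lt(abs(enr - im$membrane_amplitude) / im$membrane_amplitude, 0.1)

  # identical intensities on both sides: enrichment is zero
  uni <- mv
  for (fi in seq_along(uni$frame_times)) uni$frames[, , 2, fi] <- 0.2
  expect_equal(membrane_enrichment(uni), 0)

  # profile is max-normalised and monotone beyond the edge blur
  prof <- boundary_profile(mv)
  expect_equal(max(prof$intensity), 1)
  beyond <- prof[prof$distance > 3 * im$membrane_sigma + 2, ]
  expect_lt(max(beyond$intensity) - min(beyond$intensity), 0.15)
})

test_that("the pipeline recovers burst durations from a noisy movie", {
  mv <- small_movie("low_continuous", seed = 31)
  q <- quantify_movie(mv)
  ft <- mv$frame_times
  tr <- mv$truth_bursts
  tr$f_first <- vapply(tr$t_on, function(a) min(ft[ft >= a - 1e-9]), 1)
  tr$f_last <- vapply(tr$t_off, function(b) max(ft[ft <= b + 1e-9]), 1)
  m <- merge(as.data.frame(q$table), tr[, c("nucleus_id", "cycle",
                                            "f_first", "f_last")],
             by = c("nucleus_id", "cycle"), all.x = TRUE)
  truth_dur <- ifelse(is.na(m$f_first), 0, m$f_last - m$f_first)
  err <- abs(m$duration - truth_dur)
  # dropout (0.15/frame) trims interval ends with geometric tails; the
  # expected fraction of (nucleus, cycle) records recovered to within one
  # frame interval is 1 - 2 p^2 (1-p) - ... ~ 0.94; endpoints are each
  # within one frame for ~0.978^2 ~ 0.96 of records
  expect_gt(mean(err <= 0.5 + 1e-9), 0.85)
  expect_lt(mean(err), 0.5)
  ends_ok <- (is.na(m$f_first) & m$duration == 0) |
    (!is.na(m$f_first) & abs(m$first_focus - m$f_first) <= 0.5 + 1e-9 &
       abs(m$last_focus - m$f_last) <= 0.5 + 1e-9)
  expect_gt(mean(ends_ok), 0.9)
})
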