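test_that("phase durations follow the frame arithmetic and censoring rules", {
  ev <- mitosis_events("c1", condensation_frame = 0, metaphase_frame = 4,
                       anaphase_frame = 7, condensation_censored = FALSE,
                       last_frame = 12)
  d <- phase_durations(ev)
  expect_equal(d$prometaphase_min, 16)
  expect_equal(d$metaphase_min, 12)
  expect_false(d$prometaphase_lower_bound)
  expect_false(d$metaphase_lower_bound)

  # condensation predates the recording: prometaphase is a lower bound
  cen <- mitosis_events("c2", 0, 3, 5, condensation_censored = TRUE,
                        last_frame = 12)
  dc <- phase_durations(cen)
  expect_equal(dc$prometaphase_min, 12)
  expect_true(dc$prometaphase_lower_bound)

  # plate never observed: bound runs to the last recorded frame
  nom <- mitosis_events("c3", 1, NA, NA, FALSE, last_frame = 12)
  dn <- phase_durations(nom)
  expect_equal(dn$prometaphase_min, 44)
  expect_true(dn$prometaphase_lower_bound)
  expect_true(is.na(dn$metaphase_min))

  # anaphase never observed: metaphase duration is a lower bound
  noa <- mitosis_events("c4", 1, 4, NA, FALSE, last_frame = 12)
  da <- phase_durations(noa)
  expect_true(da$metaphase_lower_bound)
  expect_equal(da$metaphase_min, 32)

  expect_error(mitosis_events("bad", 5, 3, 7, FALSE, 12), "ordering")
  expect_error(phase_durations(ev, frame_interval_min = 0), "positive")
})

test_that("durations are non-negative multiples of the frame interval", {
  ev <- generate_mitosis_events(200, seed = 51)
  d <- phase_durations(ev)
  expect_true(all(d$prometaphase_min >= 0))
  expect_true(all(d$prometaphase_min %% 4 == 0))
  met <- d$metaphase_min[!is.na(d$metaphase_min)]
  expect_true(all(met %% 4 == 0))
})

test_that("the long-prometaphase fraction handles lower bounds correctly", {
  mk <- function(pro, lb) data.frame(cell_id = seq_along(pro),
                                     prometaphase_min = pro,
                                     prometaphase_lower_bound = lb,
                                     metaphase_min = rep(NA_real_, length(pro)),
                                     metaphase_lower_bound = rep(FALSE, length(pro)))
  expect_equal(long_prometaphase_fraction(mk(c(10, 50), c(FALSE, FALSE)))$fraction, 0.5)
  expect_equal(long_prometaphase_fraction(mk(c(10, 20, 40), rep(FALSE, 3)))$fraction, 0)

  # a lower bound already beyond the cutoff is determinate "long"
  r <- long_prometaphase_fraction(mk(c(44, 10), c(TRUE, FALSE)))
  expect_equal(r$fraction, 0.5)
  expect_equal(r$n_indeterminate, 0L)

  # a lower bound below the cutoff is indeterminate and leaves the denominator
  r2 <- long_prometaphase_fraction(mk(c(20, 50), c(TRUE, FALSE)))
  expect_equal(r2$fraction, 1)
  expect_equal(r2$n_determinate, 1L)
  expect_equal(r2$n_indeterminate, 1L)

  expect_error(long_prometaphase_fraction(mk(numeric(0), logical(0))), "no events")
})

test_that("cohort summaries use sample SD and exclude censored cells", {
  d <- data.frame(cell_id = 1:3, prometaphase_min = c(12, 16, 20),
                  prometaphase_lower_bound = FALSE,
                  metaphase_min = c(8, NA, NA), metaphase_lower_bound = FALSE)
  s <- cohort_summary(d)
  expect_equal(s$prometaphase$mean, 16)
  expect_equal(s$prometaphase$sd, 4)
  expect_equal(s$metaphase$n, 1L)
  expect_true(is.na(s$metaphase$sd))  # single value: SD undefined

  # censoring monotonicity: flagging one cell only removes that cell
  d2 <- d; d2$prometaphase_lower_bound[2L] <- TRUE
  s2 <- cohort_summary(d2)
  expect_equal(s2$prometaphase$mean, mean(c(12, 20)))
  expect_equal(s2$prometaphase$n, 2L)
})

test_that("simulated cohorts recover the truncated-normal mean", {
  for (par in list(c(14.4, 7.6), c(23.1, 14.1))) {
    ev <- generate_mitosis_events(500, prometaphase_mean = par[1L],
                                  prometaphase_sd = par[2L], seed = 52)
    s <- cohort_summary(phase_durations(ev))
    oracle <- truncnorm_mean_quadrature(par[1L], par[2L], 4)
    expect_lt(abs(s$prometaphase$mean - oracle), 1.5)
  }
})

test_that("degenerate and fully censored simulations behave as constructed", {
  ev0 <- generate_mitosis_events(50, prometaphase_mean = 16, prometaphase_sd = 0,
                                 metaphase_mean = 12, metaphase_sd = 0, seed = 53)
  d0 <- phase_durations(ev0)
  det <- !d0$prometaphase_lower_bound
  expect_true(any(det))
  expect_true(all(d0$prometaphase_min[det] == 16))
  expect_true(all(d0$metaphase_min[!is.na(d0$metaphase_min) &
                                     !d0$metaphase_lower_bound] == 12))

  # recording far shorter than the durations: every cell is censored somehow
  short <- generate_mitosis_events(80, prometaphase_mean = 40,
                                   prometaphase_sd = 5,
                                   recording_length_frames = 3L, seed = 54)
  ds <- phase_durations(short)
  expect_true(all(ds$prometaphase_lower_bound))
})

test_that("event CSV and timing writers round-trip", {
  ev <- generate_mitosis_events(30, seed = 55)
  path <- tempfile(fileext = ".csv")
  utils::write.csv(ev[, c("cell_id", "condensation_frame", "metaphase_frame",
                          "anaphase_frame", "condensation_censored",
                          "last_frame")], path, row.names = FALSE)
  back <- read_mitosis_events(path)
  expect_equal(back$condensation_frame, ev$condensation_frame)
  expect_equal(back$metaphase_frame, ev$metaphase_frame)

  d <- phase_durations(back)
  csvp <- tempfile(fileext = ".csv"); jsonp <- tempfile(fileext = ".json")
  s <- write_timing_results(d, csvp, jsonp)
  j <- jsonlite::read_json(jsonp)
  expect_equal(j$prometaphase$mean, s$prometaphase$mean, tolerance = 1e-9)
  expect_true(file.exists(csvp))
})
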