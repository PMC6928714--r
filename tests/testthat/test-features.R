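test_that("moving percentile matches hand values and the library oracle", {
  s <- 1:15
  expect_identical(moving_percentile(s, 15, 50)[8], 8)
  expect_true(all(moving_percentile(rep(3.5, 30), 15, 90) == 3.5))
  expect_error(moving_percentile(s, 15, 0), "q must be")
  expect_error(moving_percentile(s, 15, 100), "q must be")
  expect_error(moving_percentile(s, 14, 50), "odd")

  set.seed(11)
  x <- rnorm(400)
  usable <- runif(400) > 0.15
  for (q in c(10, 25, 50, 75, 90)) {
    got <- moving_percentile(x, 15, q, usable = usable)
    for (i in seq_along(x)) {
      j <- max(1, i - 7):min(400, i + 7)
      vals <- x[j][usable[j]]
      want <- if (length(vals)) oracle_percentile(vals, q) else NA_real_
      expect_equal(got[i], want)
    }
  }
})

test_that("weighted moving percentile follows the cumulative-weight rule", {
  # window values 0 and 10 with weights 3 and 1: cumulative weight at 0 is
  # 0.75 >= 0.5, so the weighted median is 0
  expect_identical(wristldct:::weighted_percentile(c(0, 10), c(3, 1), 50), 0)
  # constant series is reproduced for any q
  const <- weighted_moving_percentile(rep(7, 40), 15, 75)
  expect_true(all(const == 7))
  # random series against the scan-based oracle
  set.seed(12)
  x <- sample(0:50, 300, replace = TRUE)  # ties on purpose
  usable <- runif(300) > 0.1
  kern <- wristldct:::triangular_weights(15)
  for (q in c(25, 50, 90)) {
    got <- weighted_moving_percentile(x, 15, q, usable = usable)
    for (i in seq(1, 300, by = 3)) {
      j <- max(1, i - 7):min(300, i + 7)
      keep <- usable[j]
      want <- if (any(keep)) {
        oracle_weighted_percentile(x[j][keep], kern[j - i + 8][keep], q)
      } else NA_real_
      expect_equal(got[i], want)
    }
  }
})

test_that("uniform weights reduce the weighted statistic to the unweighted one", {
  set.seed(13)
  x <- rnorm(250)
  usable <- runif(250) > 0.2
  for (q in c(10, 50, 90)) {
    expect_equal(
      weighted_moving_percentile(x, 15, q, usable = usable,
                                 weights = rep(1, 15)),
      moving_percentile(x, 15, q, usable = usable))
  }
})

test_that("moving percentiles are monotone in q and translation equivariant", {
  set.seed(14)
  x <- rnorm(200, 20, 10)
  qs <- c(10, 25, 50, 75, 90)
  res <- sapply(qs, function(q) moving_percentile(x, 15, q))
  wres <- sapply(qs, function(q) weighted_moving_percentile(x, 15, q))
  expect_true(all(apply(res, 1, diff) >= 0))
  expect_true(all(apply(wres, 1, diff) >= 0))
  shift <- moving_percentile(x + 5, 15, 25)
  expect_equal(shift, moving_percentile(x, 15, 25) + 5)
})

test_that("log tremor transform maps the reference points", {
  expect_identical(log_tremor(0), 0)
  expect_identical(log_tremor(9), 1)
  expect_identical(log_tremor(99), 2)
  expect_error(log_tremor(-1), ">= 0")
})

test_that("weekly series reduces to the aligned day and resists outliers", {
  # single day, no smoothing: the series is that day's aligned BKS
  set.seed(15)
  bks <- runif(720, 5, 35)
  r <- make_flat_recording(bks = bks, n_epochs = 720, ack_min = 421)
  wk <- smoothed_weekly_series(r, offsets = seq(-20, 60, 2),
                               smooth_window = 1)
  anchor <- 420
  expect_equal(wk$value, bks[(anchor + wk$offset_min) / 2 + 1])
  expect_true(all(wk$n_days == 1))

  # six identical days: the series equals one day's profile
  day <- runif(720, 5, 35)
  r6 <- make_flat_recording(bks = rep(day, 6), n_epochs = 6 * 720,
                            ack_min = 421)
  r6$dose_events <- data.frame(reminder_min = (0:5) * 1440 + 419,
                               acknowledgement_min = (0:5) * 1440 + 421,
                               first_of_day = TRUE)
  wk1 <- smoothed_weekly_series(r6, align_times = 421,
                                offsets = seq(-20, 60, 2),
                                smooth_window = 5)
  wk6 <- smoothed_weekly_series(r6, offsets = seq(-20, 60, 2),
                                smooth_window = 5)
  expect_equal(wk6$value, wk1$value)
  expect_true(all(wk6$n_days == 6))

  # one corrupted day cannot move the across-day median
  corrupt <- rep(day, 6)
  corrupt[2881:3600] <- corrupt[2881:3600] + 500
  rc <- r6
  rc$epochs$bks <- corrupt
  wkc <- smoothed_weekly_series(rc, offsets = seq(-20, 60, 2),
                                smooth_window = 5)
  full <- wkc$n_days == 6
  expect_equal(wkc$value[full], wk6$value[full])
})

test_that("weekly series needs an acknowledged first dose", {
  r <- make_flat_recording(bks = 10, n_epochs = 720)
  expect_error(smoothed_weekly_series(r), "no acknowledged")
})

test_that("featurize produces ordered percentiles and the 3 selected features", {
  co <- small_cohort()
  r <- co$recordings[[2]]
  ft <- featurize(r, at = 200:260)
  expect_true(all(diff_ok <- with(ft, BKS_M10P <= BKS_M25P &
                                    BKS_M25P <= BKS_M50P &
                                    BKS_M50P <= BKS_M75P &
                                    BKS_M75P <= BKS_M90P), na.rm = TRUE))
  expect_true(all(with(ft, BKS_WM10P <= BKS_WM50P & BKS_WM50P <= BKS_WM90P),
                  na.rm = TRUE))
  expect_identical(attr(ft, "selected"), selected_features())
  expect_length(selected_features(), 3)
  expect_true(all(selected_features() %in% names(ft)))
  expect_true(all(selected_features() %in% candidate_features()))

  # an all-zero tremor window gives a zero log-tremor feature
  rz <- make_flat_recording(bks = 10, n_epochs = 50, tremor = 0)
  fz <- featurize(rz, at = 25)
  expect_identical(fz$TA_WM50P_Log, 0)
})
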