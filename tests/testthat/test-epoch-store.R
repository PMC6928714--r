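test_that("write then read round-trips a small cohort", {
  cfg <- simulation_config(n_pwp = 1, n_controls = 1, n_days = 2, seed = 2)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_epochs(co$recordings, file.path(dir, "e.csv"),
               file.path(dir, "d.json"), file.path(dir, "c.csv"))
  back <- read_epochs(file.path(dir, "e.csv"), file.path(dir, "d.json"),
                      file.path(dir, "c.csv"))
  expect_length(back, 2)
  for (i in 1:2) {
    orig <- co$recordings[[i]]
    got <- back[[i]]
    expect_identical(got$subject_id, orig$subject_id)
    expect_identical(got$group, orig$group)
    expect_equal(got$epochs$timestamp_min, orig$epochs$timestamp_min)
    expect_equal(got$epochs$bks, orig$epochs$bks)
    expect_equal(got$epochs$off_wrist, orig$epochs$off_wrist)
    if (!is.null(orig$dose_events)) {
      expect_equal(got$dose_events$acknowledgement_min,
                   orig$dose_events$acknowledgement_min)
    }
    if (!is.null(orig$clinical)) {
      expect_equal(got$clinical$updrs_off_raw, orig$clinical$updrs_off_raw)
      expect_identical(got$clinical$scale_version,
                       orig$clinical$scale_version)
    }
  }
})

test_that("schema violations are rejected with informative errors", {
  dir <- withr::local_tempdir()
  tab <- data.frame(subject_id = "s1", group = "PwP", timestamp_min = 0,
                    tremor_amplitude = 0, off_wrist = 0)
  write.csv(tab, file.path(dir, "nobks.csv"), row.names = FALSE)
  expect_error(read_epochs(file.path(dir, "nobks.csv")), "bks")

  tab2 <- data.frame(subject_id = "s1", group = "PwP",
                     timestamp_min = c(0, 2), bks = c(1, 2),
                     tremor_amplitude = c(0, -1), off_wrist = c(0, 0))
  write.csv(tab2, file.path(dir, "negta.csv"), row.names = FALSE)
  expect_error(read_epochs(file.path(dir, "negta.csv")),
               "tremor_amplitude.*row 2")

  epochs <- data.frame(timestamp_min = c(0, 2), bks = c(1, 2),
                       tremor_amplitude = c(0, 0),
                       off_wrist = c(FALSE, FALSE))
  expect_error(new_recording("s1", "patient", epochs), "unknown group")
  expect_error(new_recording("s1", "PwP", epochs[c(2, 1), ]),
               "strictly increasing")
})

test_that("constant high BKS is inactive, constant low BKS active", {
  high <- make_flat_recording(bks = 50, n_epochs = 100)
  expect_true(all(label_activity(high) == "inactive"))
  low <- make_flat_recording(bks = 10, n_epochs = 100)
  expect_true(all(label_activity(low) == "active"))
  # threshold is strict: exactly 40 stays active
  at40 <- make_flat_recording(bks = 40, n_epochs = 100)
  expect_true(all(label_activity(at40) == "active"))
})

test_that("activity labels match a brute-force weighted-median recomputation", {
  set.seed(31)
  n <- 300
  bks <- runif(n, 0, 80)
  off <- runif(n) < 0.1
  rec <- make_flat_recording(bks = bks, n_epochs = n, off_wrist = off)
  labels <- label_activity(rec, window_epochs = 15, inactive_threshold = 40)
  kern <- wristldct:::triangular_weights(15)
  for (i in seq_len(n)) {
    if (off[i]) {
      expect_identical(labels[i], "off_wrist")
      next
    }
    j <- max(1, i - 7):min(n, i + 7)
    keep <- !off[j]
    wm <- oracle_weighted_percentile(bks[j][keep],
                                     kern[j - i + 8][keep], 50)
    expect_identical(labels[i], if (wm > 40) "inactive" else "active")
  }
})

test_that("every epoch receives exactly one label and labeling is idempotent", {
  co <- small_cohort()
  r <- co$recordings[[3]]
  l1 <- label_activity(r)
  expect_true(all(l1 %in% c("active", "inactive", "off_wrist")))
  expect_identical(l1, label_activity(r))
  expect_identical(sum(r$epochs$off_wrist), sum(l1 == "off_wrist"))
})

test_that("off-wrist epochs never influence their neighbours' labels", {
  set.seed(41)
  n <- 200
  bks <- runif(n, 0, 35)
  off <- rep(FALSE, n)
  off[sample(n, 20)] <- TRUE
  base <- make_flat_recording(bks = bks, n_epochs = n, off_wrist = off)
  spiked_bks <- bks
  spiked_bks[off] <- 1e6
  spiked <- make_flat_recording(bks = spiked_bks, n_epochs = n,
                                off_wrist = off)
  expect_identical(label_activity(base), label_activity(spiked))
})

test_that("an even activity window is a parameter error", {
  r <- make_flat_recording(bks = 10, n_epochs = 20)
  expect_error(label_activity(r, window_epochs = 14), "odd")
})
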