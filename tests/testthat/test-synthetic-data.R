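test_that("configuration validation rejects impossible settings", {
  expect_error(simulation_config(n_pwp = 0, n_controls = 0),
               "non-negative counts")
  expect_error(simulation_config(n_pwp = 5, n_controls = 5,
                                 inactivity_rate = 1.2), "inactivity_rate")
  expect_error(simulation_config(n_pwp = 5, n_controls = 5, n_days = 0),
               "n_days")
  expect_error(simulation_config(n_pwp = 5, n_controls = 5,
                                 epoch_minutes = 0), "epoch_minutes")
})

test_that("identical configuration and seed give bit-identical cohorts", {
  cfg <- simulation_config(n_pwp = 3, n_controls = 2, n_days = 2, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  for (i in seq_along(a$recordings)) {
    expect_identical(a$recordings[[i]]$epochs, b$recordings[[i]]$epochs)
    expect_identical(a$recordings[[i]]$dose_events,
                     b$recordings[[i]]$dose_events)
  }
})

test_that("a controls-only cohort has zero severity and no dose events", {
  cfg <- simulation_config(n_pwp = 0, n_controls = 10, n_days = 2, seed = 5)
  co <- simulate_cohort(cfg)
  expect_length(co$recordings, 10)
  expect_true(all(co$truth$updrs_off == 0))
  expect_true(all(co$truth$updrs_on == 0))
  expect_true(all(vapply(co$recordings,
                         function(r) is.null(r$dose_events), TRUE)))
})

test_that("dose-time BKS increases with OFF-state severity (link monotone)", {
  co <- small_cohort()
  tr <- co$truth[co$truth$group == "PwP", ]
  dt_bks <- vapply(co$recordings[seq_len(nrow(tr))], function(r) {
    labels <- label_activity(r)
    idx <- unlist(lapply(r$dose_events$acknowledgement_min, function(a) {
      extract_dt(r, a, labels)
    }))
    if (!length(idx)) return(NA_real_)
    mean(r$epochs$bks[idx])
  }, numeric(1))
  severe <- tr$updrs_off >= 48 & !tr$already_on
  mild <- tr$updrs_off < 25 & !tr$already_on
  expect_gt(mean(dt_bks[severe], na.rm = TRUE),
            mean(dt_bks[mild], na.rm = TRUE))
  # strata means of DT-window BKS are non-decreasing in true severity level
  lev <- updrs_to_mfsl(tr$updrs_off)
  m <- tapply(dt_bks[!tr$already_on], lev[!tr$already_on], mean,
              na.rm = TRUE)
  expect_true(all(diff(m) > -1))
})

test_that("simulated trough latencies recover the implied truncated moments", {
  cfg <- simulation_config(n_pwp = 60, n_controls = 0, n_days = 6, seed = 99)
  co <- simulate_cohort(cfg)
  per_subj <- lapply(co$recordings, function(r) r$truth$doses$latency_min)
  lats <- unlist(per_subj)
  expect_gte(length(lats), 100)
  expect_true(all(lats >= cfg$latency_support[1] &
                    lats <= cfg$latency_support[2]))

  # closed-form truncated-normal moments, mixed over the subject-level
  # spread multiplier (uniform on [0.4, 1.5])
  trunc_moments <- function(mu, sd, lo, hi) {
    a <- (lo - mu) / sd
    b <- (hi - mu) / sd
    z <- pnorm(b) - pnorm(a)
    m <- mu + sd * (dnorm(a) - dnorm(b)) / z
    v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z -
                   ((dnorm(a) - dnorm(b)) / z)^2)
    c(mean = m, var = v)
  }
  mg <- seq(0.4, 1.5, length.out = 2001)
  mom <- sapply(mg, function(m) {
    trunc_moments(cfg$latency_mean, cfg$latency_sd * m,
                  cfg$latency_support[1], cfg$latency_support[2])
  })
  mean_theory <- mean(mom["mean", ])
  var_theory <- mean(mom["var", ])   # mean within-subject variance

  # cluster-aware comparison over per-subject summaries
  subj_means <- vapply(per_subj, mean, numeric(1))
  se_mean <- sd(subj_means) / sqrt(length(subj_means))
  expect_lt(abs(mean(subj_means) - mean_theory), 3 * se_mean)
  subj_vars <- vapply(per_subj, var, numeric(1))
  se_var <- sd(subj_vars) / sqrt(length(subj_vars))
  expect_lt(abs(mean(subj_vars) - var_theory), 3 * se_var)
})

test_that("daytime inactivity bout occupancy matches the configured rate", {
  cfg <- simulation_config(n_pwp = 0, n_controls = 40, n_days = 6,
                           seed = 13, inactivity_rate = 0.10)
  co <- simulate_cohort(cfg)
  fracs <- vapply(co$recordings, function(r) {
    awake <- !r$truth$asleep
    mean(r$truth$inactive_bout[awake])
  }, numeric(1))
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - 0.10), 2 * se)
})

test_that("inactivity bout interiors are detected by the moving-median rule", {
  co <- small_cohort()
  r <- co$recordings[[1]]
  labels <- label_activity(r)
  bout <- r$truth$inactive_bout | r$truth$asleep
  # interior = epochs at least 7 epochs from any bout edge
  run <- rle(bout)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1
  interior <- unlist(mapply(function(s, e, v) {
    if (v && e - s >= 14) (s + 7):(e - 7) else integer(0)
  }, starts, ends, run$values, SIMPLIFY = FALSE))
  interior <- interior[!r$epochs$off_wrist[interior]]
  expect_gt(mean(labels[interior] == "inactive"), 0.99)
})

test_that("control recordings expose the nominal dose-time epoch", {
  cfg <- simulation_config(n_pwp = 0, n_controls = 1, n_days = 3, seed = 3)
  r <- simulate_controls_day(cfg)
  expect_identical(r$group, "control")
  expect_null(r$dose_events)
  # 10:00 on each day lies on a valid epoch of the grid
  for (d in 0:2) {
    expect_true((d * 1440 + 600) %in% r$epochs$timestamp_min)
  }
})

test_that("controls show no dose-locked trough after the nominal dose time", {
  cfg <- simulation_config(n_pwp = 0, n_controls = 30, n_days = 6, seed = 17)
  co <- simulate_cohort(cfg)
  diffs <- vapply(co$recordings, function(r) {
    tod <- r$epochs$timestamp_min %% 1440
    awake <- !r$truth$asleep & !r$truth$inactive_bout
    at_dt <- awake & tod >= 600 & tod < 610
    post <- awake & tod >= 646 & tod <= 690
    mean(r$epochs$bks[post]) - mean(r$epochs$bks[at_dt])
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 2 * se + 0.2)
})

test_that("zero inactivity and off-wrist rates leave all daytime epochs usable", {
  cfg <- simulation_config(n_pwp = 0, n_controls = 1, n_days = 2, seed = 8,
                           inactivity_rate = 0, offwrist_rate = 0)
  r <- simulate_controls_day(cfg)
  labels <- label_activity(r)
  tod <- r$epochs$timestamp_min %% 1440
  daytime <- tod >= 420 & tod < 1350   # clear of sleep and its window edge
  expect_true(all(labels[daytime] == "active"))
})

test_that("already-ON subjects look treated in the morning but worse later", {
  cfg <- simulation_config(n_pwp = 30, n_controls = 0, n_days = 6,
                           seed = 21, frac_already_on = 0.3)
  co <- simulate_cohort(cfg)
  tr <- co$truth
  expect_gt(sum(tr$already_on), 0)
  for (i in which(tr$already_on)) {
    r <- co$recordings[[i]]
    tod <- r$epochs$timestamp_min %% 1440
    ok <- !r$truth$asleep & !r$truth$inactive_bout
    morning <- ok & tod >= 400 & tod < 600
    late <- ok & tod >= 900 & tod < 1100
    expect_gt(mean(r$epochs$bks[late]), mean(r$epochs$bks[morning]))
    # morning severity sits at the treated (ON) level
    expect_lt(mean(r$truth$severity[morning]), tr$updrs_on[i] + 1)
  }
})
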