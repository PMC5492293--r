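make_rec <- function(t, v, site = "LB") {
  raw_recording(site, t, cbind(v, 0 * v, 0 * v))
}

test_that("resampling is the identity on a uniform 50 Hz grid", {
  t <- seq(0, 2, by = 0.02)
  r <- make_rec(t, sin(2 * pi * t))
  out <- resample_50hz(r)
  expect_equal(out$time_s, t)
  expect_equal(out$accel[, "V"], r$accel[, "V"])
})

test_that("resampling a constant 49.5 Hz signal gives the constant", {
  t <- seq(0, 3, by = 1 / 49.5)
  out <- resample_50hz(make_rec(t, rep(1, length(t))))
  expect_true(all(abs(out$accel[, "V"] - 1) < 1e-12))
  expect_equal(diff(out$time_s), rep(0.02, length(out$time_s) - 1))
})

test_that("a 5 Hz sinusoid sampled at 51 Hz resamples onto its closed form", {
  t <- seq(0, 4, by = 1 / 51)
  out <- resample_50hz(make_rec(t, sin(2 * pi * 5 * t)))
  # linear interpolation error bound for sin: (2*pi*f)^2 * h^2 / 8 ~ 0.047
  expect_lt(max(abs(out$accel[, "V"] - sin(2 * pi * 5 * out$time_s))), 0.05)
})

test_that("resampling is idempotent", {
  t <- sort(runif(200, 0, 4))
  withr::local_seed(1)
  r <- make_rec(seq(0, 4, length.out = 210), rnorm(210))
  once <- resample_50hz(r)
  twice <- resample_50hz(once)
  expect_equal(once, twice)
})

test_that("non-monotone time is rejected", {
  expect_error(raw_recording("LB", c(0, 0.02, 0.02), matrix(0, 3, 3)),
               "strictly increasing")
})

test_that("synchronization realigns shifted copies of one signal", {
  t <- seq(0, 20, by = 0.02)
  base <- function(t) 2 * exp(-((t - 1) / 0.05)^2) +
    0.5 * sin(2 * pi * 1.9 * t) * (t > 2)
  recs <- list(raw_recording("LB", t, cbind(base(t), 0, 0)),
               raw_recording("LS", t, cbind(base(t - 0.1), 0, 0)),
               raw_recording("RS", t, cbind(base(t + 0.2), 0, 0)))
  sess <- synchronize(recs)
  expect_s3_class(sess, "session")
  n <- length(sess$time_s)
  for (site in c("LS", "RS"))
    expect_lt(max(abs(sess$signals[[site]][, "V"] -
                        sess$signals$LB[, "V"])), 1e-9)
})

test_that("already aligned signals get zero shift and full overlap", {
  t <- seq(0, 10, by = 0.02)
  v <- 2 * exp(-((t - 1) / 0.05)^2) + 0.1 * sin(t)
  recs <- lapply(c("LB", "LS", "RS"), function(s)
    raw_recording(s, t, cbind(v, 0, 0)))
  sess <- synchronize(recs)
  expect_equal(length(sess$time_s), length(t))
  expect_equal(min(abs(sess$time_s)), 0)
})

test_that("a sensor without a qualifying peak is reported by name", {
  t <- seq(0, 10, by = 0.02)
  v <- 2 * exp(-((t - 1) / 0.05)^2)
  recs <- list(raw_recording("LB", t, cbind(v, 0, 0)),
               raw_recording("LS", t, cbind(v, 0, 0)),
               raw_recording("RS", t, cbind(0 * t, 0, 0)))
  expect_error(synchronize(recs), "RS")
})

test_that("the planted sync spike aligns sites to within one sample", {
  s <- clean_session()
  pp <- clean_pp()
  sess <- pp$session
  # each site's max (the spike) must sit at the common origin
  for (site in c("LB", "LS", "RS")) {
    i <- which.max(sess$signals[[site]][, "V"])
    expect_lte(abs(sess$time_s[i]), 0.02)
  }
})

test_that("step detection ignores constant signals and merges close peaks", {
  t <- seq(0, 12, by = 0.02)
  flat <- lapply(c("LB", "LS", "RS"), function(s)
    raw_recording(s, t, cbind(c(rep(0, 40), 2, rep(0, length(t) - 41)), 0, 0)))
  sess <- synchronize(flat)
  expect_length(detect_steps(sess, "LB")$step_indices, 0)

  v <- numeric(length(t))
  v[c(41, 300, 305, 500)] <- c(2, 1, 0.9, 1)   # 2 peaks 0.1 s apart
  recs <- lapply(c("LB", "LS", "RS"), function(s)
    raw_recording(s, t, cbind(v, 0, 0)))
  sess <- synchronize(recs)
  st <- detect_steps(sess, "LB")$step_indices
  expect_length(st, 2)  # merged pair counts once, plus the peak at 500
})

test_that("detected steps recover the planted impulse train", {
  s <- ideal_session()
  pp <- ideal_pp()
  sess <- pp$session
  st_t <- sess$time_s[pp$steps$LB$step_indices]
  planted <- s$truth$step_times - s$truth$sync_time
  expect_equal(length(st_t), length(planted))
  expect_lt(max(abs(st_t - planted)), 0.021)
  # shank sensors see only their own foot
  expect_equal(length(pp$steps$LS$step_indices),
               length(s$truth$steps_left))
  expect_equal(length(pp$steps$RS$step_indices),
               length(s$truth$steps_right))
})

test_that("turn segments are standardized to five steps with 0.2 s buffers", {
  pp <- clean_pp()
  expect_gt(length(pp$turns), 0)
  for (seg in pp$turns) {
    expect_identical(length(seg$steps), 5L)
    lead_in <- (seg$steps[1] - seg$start_idx) * 0.02
    lead_out <- (seg$end_idx - 1L - seg$steps[5]) * 0.02
    expect_lt(abs(lead_in - 0.2), 0.021)
    expect_lt(abs(lead_out - 0.2), 0.021)
  }
})

test_that("segmentation recovers the planted turns of a clean session", {
  s <- clean_session()
  pp <- clean_pp()
  truth <- s$truth$turn_intervals - s$truth$sync_time
  det <- vapply(pp$turns, function(sg)
    c(pp$session$time_s[sg$start_idx], pp$session$time_s[sg$end_idx - 1L]),
    numeric(2))
  expect_identical(ncol(det), nrow(truth))
  for (j in seq_len(nrow(truth))) {
    ovl <- max(0, min(det[2, j], truth[j, 2]) - max(det[1, j], truth[j, 1]))
    expect_gte(ovl, 0.5 * (truth[j, 2] - truth[j, 1]))
  }
})

test_that("a session without a vertical-magnitude drop yields no turns", {
  prof <- gait_profile(turn_attenuation = 0.999, hf_noise_power = 0,
                       section_variability = 0)
  s <- simulate_session(prof, duration = 80, label = "NF", seed = 4)
  pp <- preprocess_session(s$recordings)
  expect_length(pp$turns, 0)
  expect_true(pp$flagged)
})

test_that("straight segments avoid planted turns and the partition holds", {
  s <- clean_session()
  pp <- clean_pp()
  truth <- s$truth$turn_intervals - s$truth$sync_time
  for (sg in pp$straights) {
    lo <- pp$session$time_s[sg$start_idx]
    hi <- pp$session$time_s[sg$end_idx - 1L]
    for (j in seq_len(nrow(truth)))
      expect_lte(max(0, min(hi, truth[j, 2]) - max(lo, truth[j, 1])), 0)
  }
  # turn + straight segments are pairwise disjoint
  all_seg <- c(pp$turns, pp$straights)
  iv <- t(vapply(all_seg, function(s) c(s$start_idx, s$end_idx), numeric(2)))
  iv <- iv[order(iv[, 1]), ]
  expect_true(all(iv[-1, 1] >= iv[-nrow(iv), 2]))
})

test_that("the straight complement yields n+1 candidates around n turns", {
  t <- seq(0, 60, by = 0.02)
  v <- numeric(length(t))
  step_t <- seq(1, 59, by = 0.5)
  v[round(step_t / 0.02) + 1] <- 1.5
  v[2] <- 5   # sync spike
  recs <- lapply(c("LB", "LS", "RS"), function(s)
    raw_recording(s, t, cbind(v, 0, 0)))
  sess <- synchronize(recs)
  st <- detect_steps(sess, "LB")
  ref <- detect_steps(sess, "LS")
  mk_turn <- function(lo_s, hi_s) {
    idx <- st$step_indices
    mid <- which.min(abs(sess$time_s[idx] - (lo_s + hi_s) / 2))
    structure(list(kind = "turn", start_idx = idx[mid - 2] - 10L,
                   end_idx = idx[mid + 2] + 11L,
                   steps = idx[(mid - 2):(mid + 2)]),
              class = "walk_segment")
  }
  turns <- list(mk_turn(19, 22), mk_turn(39, 42))
  straights <- segment_straight(sess, turns, st, ref, min_strides = 0,
                                exclude = NULL)
  expect_length(straights, length(turns) + 1)
})
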