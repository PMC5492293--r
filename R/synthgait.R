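#' Gait profile for the synthetic six-minute-walk generator
#'
#' A `gait_profile` collects the generative parameters of one participant's
#' walking pattern: cadence, the vertical impulse shape, the knobs that control
#' gait asymmetry, high-frequency content and section-to-section variability,
#' and the geometry of the walkway schedule (straight passes alternating with
#' five-step turns around the cones).
#'
#' @param step_frequency Nominal steps per second (Hz). Stride frequency is
#'   half of this. Default 1.9 Hz (~114 steps/min, typical for older adults).
#' @param cadence_sd Between-session SD (Hz) of the realized step frequency;
#'   each simulated session draws its own cadence so no two participants walk
#'   on an identical clock.
#' @param amp_jitter Coefficient of variation of per-step amplitude noise
#'   (step-to-step variability within a pass).
#' @param step_amplitude Peak vertical acceleration of a foot-strike impulse,
#'   in g.
#' @param harmonic_weights Relative amplitudes of a continuous harmonic series
#'   at multiples of the step frequency added under the impulse train.
#' @param asymmetry Fractional left/right amplitude difference in `[0, 1)`.
#'   Alternate steps are scaled by `1 + asymmetry` and `1 - asymmetry`, which
#'   injects odd stride-frequency harmonics and therefore lowers REOH.
#' @param hf_noise_power Band-limited noise power (g^2) above 12.5 Hz; raising
#'   it lowers FQFFT.
#' @param section_variability Coefficient of variation of the per-section
#'   amplitude scale; raising it inflates the SD-of-feature aggregates.
#' @param turn_attenuation Multiplier in `(0, 1)` applied to the vertical
#'   walking component during each planted turn, reproducing the drop in
#'   vertical acceleration magnitude that marks a turn.
#' @param walkway_time_s Seconds of straight walking per pass between turns.
#' @param sample_rate_jitter Fractional per-sensor deviation from the nominal
#'   50 Hz sampling rate.
#' @param turn_stress Multiplier (>= 1) applied to `asymmetry` and
#'   `hf_noise_power` inside turn windows: turning challenges stability, so
#'   gait deficits express more strongly there. The effective in-turn
#'   asymmetry is capped at 0.85.
#' @param turn_only_effects If `TRUE`, `asymmetry` and `hf_noise_power` act
#'   only inside turn windows (and are zero elsewhere), planting a
#'   condition-specific class difference; pair such a profile with a baseline
#'   whose asymmetry and noise are 0 so straight sections are identically
#'   distributed across classes.
#'
#' @return An object of class `gait_profile`.
#' @export
gait_profile <- function(step_frequency = 1.9,
                         cadence_sd = 0.05,
                         amp_jitter = 0.05,
                         step_amplitude = 1.2,
                         harmonic_weights = c(0.25, 0.12, 0.05),
                         asymmetry = 0.05,
                         hf_noise_power = 0.002,
                         section_variability = 0.08,
                         turn_attenuation = 0.55,
                         walkway_time_s = 26,
                         sample_rate_jitter = 0.01,
                         turn_stress = 1.5,
                         turn_only_effects = FALSE) {
  p <- list(step_frequency = step_frequency,
            cadence_sd = cadence_sd,
            amp_jitter = amp_jitter,
            step_amplitude = step_amplitude,
            harmonic_weights = harmonic_weights,
            asymmetry = asymmetry,
            hf_noise_power = hf_noise_power,
            section_variability = section_variability,
            turn_attenuation = turn_attenuation,
            walkway_time_s = walkway_time_s,
            sample_rate_jitter = sample_rate_jitter,
            turn_stress = turn_stress,
            turn_only_effects = isTRUE(turn_only_effects))
  class(p) <- "gait_profile"
  validate_gait_profile(p)
  p
}

validate_gait_profile <- function(p) {
  stopifnot(inherits(p, "gait_profile"))
  if (!is.numeric(p$step_frequency) || p$step_frequency <= 0)
    stop("invalid gait profile: step_frequency must be > 0", call. = FALSE)
  if (p$asymmetry < 0 || p$asymmetry >= 1)
    stop("invalid gait profile: asymmetry must lie in [0, 1)", call. = FALSE)
  if (p$turn_attenuation <= 0 || p$turn_attenuation >= 1)
    stop("invalid gait profile: turn_attenuation must lie in (0, 1)",
         call. = FALSE)
  if (p$hf_noise_power < 0)
    stop("invalid gait profile: hf_noise_power must be >= 0", call. = FALSE)
  if (p$walkway_time_s <= 0)
    stop("invalid gait profile: walkway_time_s must be > 0", call. = FALSE)
  if (p$sample_rate_jitter < 0 || p$sample_rate_jitter >= 0.2)
    stop("invalid gait profile: sample_rate_jitter must lie in [0, 0.2)",
         call. = FALSE)
  if (p$section_variability < 0)
    stop("invalid gait profile: section_variability must be >= 0",
         call. = FALSE)
  if (p$cadence_sd < 0)
    stop("invalid gait profile: cadence_sd must be >= 0", call. = FALSE)
  if (p$amp_jitter < 0)
    stop("invalid gait profile: amp_jitter must be >= 0", call. = FALSE)
  if (p$turn_stress < 1)
    stop("invalid gait profile: turn_stress must be >= 1", call. = FALSE)
  invisible(p)
}

#' Default non-faller and prospective-faller profiles
#'
#' The non-faller profile is the package default; the prospective-faller
#' profile elevates asymmetry, high-frequency noise power, and
#' section-to-section variability — the three signal properties the feature
#' bank is designed to pick up (lower REOH, lower FQFFT, larger SD
#' aggregates) — and expresses its deficits twice as strongly under turn
#' stress (`turn_stress` 3 vs 1.5), so turn sections carry the larger share
#' of the class signal. The effect sizes are simulation choices, not
#' measured values.
#'
#' @param ... Overrides forwarded to [gait_profile()].
#' @return A `gait_profile`.
#' @export
nf_profile <- function(...) gait_profile(...)

#' @rdname nf_profile
#' @export
pf_profile <- function(...) {
  defaults <- list(asymmetry = 0.12, hf_noise_power = 0.003,
                   section_variability = 0.14, turn_stress = 3)
  args <- utils::modifyList(defaults, list(...))
  do.call(gait_profile, args)
}

# Raised-cosine impulse centred at 0 with support [-width/2, width/2].
raised_cosine <- function(t, width) {
  ifelse(abs(t) < width / 2, 0.5 * (1 + cos(2 * pi * t / width)), 0)
}

# Band-limited noise as a deterministic random harmonic sum, evaluable at
# arbitrary times so all three sensors observe the same continuous process.
make_bl_noise <- function(power, f_lo = 13, f_hi = 24.5, n_comp = 40) {
  if (power <= 0) return(function(t) numeric(length(t)))
  freqs <- stats::runif(n_comp, f_lo, f_hi)
  phases <- stats::runif(n_comp, 0, 2 * pi)
  # sum of sinusoids a*cos(): total power = n * a^2 / 2
  a <- sqrt(2 * power / n_comp)
  function(t) {
    out <- numeric(length(t))
    for (i in seq_len(n_comp)) out <- out + a * cos(2 * pi * freqs[i] * t + phases[i])
    out
  }
}

# Step schedule: steps at the step period from t0. One cone-to-cone cycle
# lasts walkway_time_s and ends with a five-step turn, so the straight
# portion of a pass is walkway_time_s minus the turn duration.
plan_steps <- function(profile, duration, t0 = 2) {
  period <- 1 / profile$step_frequency
  times <- seq(t0, duration - 0.5, by = period)
  n <- length(times)
  is_turn <- logical(n)
  section <- integer(n)      # straight-pass / turn index, increments on change
  sec <- 1L
  straight_time <- max(period, profile$walkway_time_s - 5 * period)
  straight_elapsed <- 0
  i <- 1L
  while (i <= n) {
    if (straight_elapsed >= straight_time && i + 4L <= n) {
      sec <- sec + 1L
      is_turn[i:(i + 4L)] <- TRUE
      section[i:(i + 4L)] <- sec
      sec <- sec + 1L
      straight_elapsed <- 0
      i <- i + 5L
    } else {
      section[i] <- sec
      straight_elapsed <- straight_elapsed + period
      i <- i + 1L
    }
  }
  # foot alternation: odd steps left, even steps right
  foot <- ifelse(seq_len(n) %% 2L == 1L, "L", "R")
  list(times = times, is_turn = is_turn, section = section, foot = foot,
       period = period)
}

turn_intervals_from_plan <- function(plan) {
  idx <- which(plan$is_turn)
  if (length(idx) == 0) return(matrix(numeric(0), ncol = 2))
  starts <- idx[c(TRUE, diff(idx) > 1)]
  ends <- idx[c(diff(idx) > 1, TRUE)]
  cbind(start = plan$times[starts] - plan$period / 2,
        end = plan$times[ends] + plan$period / 2)
}

in_intervals <- function(t, intervals) {
  out <- logical(length(t))
  if (nrow(intervals) == 0) return(out)
  for (i in seq_len(nrow(intervals)))
    out <- out | (t >= intervals[i, 1] & t < intervals[i, 2])
  out
}

#' Simulate one synthetic six-minute-walk accelerometer session
#'
#' Generates tri-axial recordings for the lower back (LB), left shank (LS),
#' and right shank (RS) sensors. The vertical channel is a train of
#' raised-cosine foot-strike impulses at the step frequency plus a small
#' harmonic series; alternate-step amplitude scaling by `1 +/- asymmetry`
#' plants odd stride-frequency harmonics; the walking component is multiplied
#' by `turn_attenuation` across each planted five-step turn window; ML and AP
#' channels are phase-shifted mixtures with a low-frequency ML sway added
#' during turns. Each sensor samples at its own rate (50 Hz +/- jitter) and
#' carries a sharp synchronization spike (3x step amplitude) near t = 0.
#'
#' @param profile A [gait_profile()].
#' @param duration Session length in seconds (>= 30).
#' @param label Class label, `"PF"` or `"NF"`.
#' @param seed Integer seed; identical arguments reproduce identical output.
#' @return A `synthetic_session`: list with `recordings` (one `raw_recording`
#'   per site), `label`, and `truth` (planted turn intervals in seconds,
#'   planted step times per foot, sync spike time).
#' @export
simulate_session <- function(profile, duration = 360, label = c("NF", "PF"),
                             seed = 1) {
  label <- match.arg(label)
  validate_gait_profile(profile)
  if (!is.numeric(duration) || duration < 30)
    stop("duration must be at least 30 s", call. = FALSE)
  set.seed(as.integer(seed))

  # realized cadence for this session
  profile$step_frequency <- max(0.5, stats::rnorm(1, profile$step_frequency,
                                                  profile$cadence_sd))
  plan <- plan_steps(profile, duration)
  turns <- turn_intervals_from_plan(plan)
  n_steps <- length(plan$times)

  # per-section amplitude scale (gait variability across passes)
  n_sec <- max(plan$section)
  sec_scale <- pmax(0.2, stats::rnorm(n_sec, 1, profile$section_variability))

  # per-section variability modulates straight passes; turn amplitude is
  # governed by turn_attenuation alone so the RMS drop stays detectable.
  # Asymmetry expresses at turn_stress strength inside turns and at baseline
  # strength (or zero under turn_only_effects) elsewhere.
  base_gate <- if (profile$turn_only_effects) 0 else 1
  asym_step <- pmin(0.85, profile$asymmetry *
                      ifelse(plan$is_turn, profile$turn_stress, base_gate))
  side_sign <- ifelse(plan$foot == "L", 1, -1)
  step_amp <- profile$step_amplitude *
    (1 + side_sign * asym_step) *
    ifelse(plan$is_turn, profile$turn_attenuation, sec_scale[plan$section]) *
    pmax(0.3, stats::rnorm(n_steps, 1, profile$amp_jitter))

  # per-sensor, per-axis band-limited noise processes (drawn in fixed order)
  sites <- c("LB", "LS", "RS")
  noise <- lapply(sites, function(s)
    lapply(1:3, function(a) make_bl_noise(profile$hf_noise_power)))
  names(noise) <- sites
  rates <- 50 * (1 + stats::runif(3, -profile$sample_rate_jitter,
                                  profile$sample_rate_jitter))
  names(rates) <- sites

  pulse_w <- 0.18
  sync_t <- 0.2
  f_step <- profile$step_frequency
  f_stride <- f_step / 2
  hw <- profile$harmonic_weights

  impulse_train <- function(t, step_sel, amp_scale = 1) {
    out <- numeric(length(t))
    for (k in which(step_sel)) {
      tk <- plan$times[k]
      lo <- tk - pulse_w / 2
      hi <- tk + pulse_w / 2
      j <- which(t >= lo & t <= hi)
      if (length(j))
        out[j] <- out[j] + amp_scale * step_amp[k] *
          raised_cosine(t[j] - tk, pulse_w)
    }
    out
  }

  # phase-locked to the first step so harmonic maxima coincide with foot
  # strikes instead of planting spurious inter-step peaks
  t_first <- plan$times[1]
  harmonic_series <- function(t, phase = 0) {
    out <- numeric(length(t))
    for (h in seq_along(hw))
      out <- out + hw[h] * profile$step_amplitude *
        cos(2 * pi * h * f_step * (t - t_first) + phase)
    out
  }

  walking_mask <- function(t) {
    # raised-cosine ramps avoid onset transients that look like steps
    ramp <- 0.5
    lo <- t_first - 0.1
    hi <- plan$times[n_steps] + 0.1
    m <- rep(1, length(t))
    m[t < lo - ramp | t > hi + ramp] <- 0
    j <- t >= lo - ramp & t < lo
    m[j] <- 0.5 * (1 - cos(pi * (t[j] - (lo - ramp)) / ramp))
    j <- t > hi & t <= hi + ramp
    m[j] <- 0.5 * (1 + cos(pi * (t[j] - hi) / ramp))
    m
  }

  turn_env <- function(t) {
    e <- rep(1, length(t))
    e[in_intervals(t, turns)] <- profile$turn_attenuation
    e
  }

  noise_gate <- function(t) {
    base <- if (profile$turn_only_effects) 0 else 1
    ifelse(in_intervals(t, turns), sqrt(profile$turn_stress), base)
  }

  make_rec <- function(site) {
    rate <- rates[[site]]
    t <- seq(0, duration, by = 1 / rate)
    wm <- walking_mask(t)
    env <- turn_env(t)
    ng <- noise_gate(t)
    sel <- switch(site,
                  LB = rep(TRUE, n_steps),
                  LS = plan$foot == "L",
                  RS = plan$foot == "R")
    cross <- switch(site,
                    LB = rep(FALSE, n_steps),
                    LS = plan$foot == "R",
                    RS = plan$foot == "L")
    # shank vertical is strike-dominated: own-foot impulses plus a small
    # contralateral transient; the continuous harmonic series rides on the
    # pelvis signal only (keeps shank stride detection unambiguous)
    amp_main <- if (site == "LB") 1 else 1.3
    harm_scale <- if (site == "LB") 1 else 0
    vert <- impulse_train(t, sel, amp_main) +
      impulse_train(t, cross, 0.05) +
      harm_scale * env * wm * harmonic_series(t) +
      ng * noise[[site]][[1]](t) +
      3 * profile$step_amplitude * raised_cosine(t - sync_t, 0.08)
    ml <- 0.15 * profile$step_amplitude * wm * sin(2 * pi * f_stride * t) +
      0.4 * profile$step_amplitude * (1 - env) / (1 - profile$turn_attenuation) *
        sin(2 * pi * 0.5 * t) +
      ng * noise[[site]][[2]](t)
    ap <- 0.5 * impulse_train(t - 0.06, sel, amp_main) +
      0.3 * profile$step_amplitude * env * wm *
        cos(2 * pi * f_step * t + 0.8) +
      ng * noise[[site]][[3]](t)
    raw_recording(site = site, time_s = t,
                  accel = cbind(V = vert, ML = ml, AP = ap),
                  nominal_rate = 50)
  }

  recordings <- lapply(sites, make_rec)
  names(recordings) <- sites

  structure(list(
    recordings = recordings,
    label = label,
    truth = list(turn_intervals = turns,
                 step_times = plan$times,
                 steps_left = plan$times[plan$foot == "L"],
                 steps_right = plan$times[plan$foot == "R"],
                 step_is_turn = plan$is_turn,
                 sync_time = sync_t)
  ), class = "synthetic_session")
}

#' Simulate a labeled cohort of synthetic sessions
#'
#' Each participant gets a deterministic seed `seed + index`, so a cohort can
#' be partially regenerated reproducibly. Non-fallers are drawn around
#' `nf_profile`, prospective fallers around `pf_profile` (by default with
#' elevated asymmetry, high-frequency noise, and section variability).
#' Individual participants draw their own asymmetry, noise power, and
#' section variability around the class profile (`param_spread`), so the two
#' class populations overlap the way real cohorts do; set
#' `param_spread = NULL` for exact per-class profiles (useful for controlled
#' experiments).
#'
#' @param n_nf,n_pf Number of non-faller and prospective-faller participants.
#' @param nf_profile,pf_profile Class-mean [gait_profile()]s.
#' @param duration Session length in seconds.
#' @param seed Base integer seed.
#' @param param_spread Named list with `asymmetry` (normal SD),
#'   `hf_log` (log-normal SD of the noise-power multiplier), and
#'   `section_variability` (normal SD) of the per-participant draws, or
#'   `NULL` to disable.
#' @return A list of `synthetic_session`, NF participants first; names are
#'   participant ids `P001`, `P002`, ...
#' @export
simulate_cohort <- function(n_nf, n_pf,
                            nf_profile = turngait::nf_profile(),
                            pf_profile = turngait::pf_profile(),
                            duration = 360, seed = 1,
                            param_spread = list(asymmetry = 0.08,
                                                hf_log = 0.5,
                                                section_variability = 0.05)) {
  if (n_nf < 0 || n_pf < 0) stop("cohort counts must be non-negative",
                                 call. = FALSE)
  if (n_nf + n_pf < 4) stop("cohort must have at least 4 participants",
                            call. = FALSE)
  labels <- c(rep("NF", n_nf), rep("PF", n_pf))
  sessions <- lapply(seq_along(labels), function(i) {
    prof <- if (labels[i] == "NF") nf_profile else pf_profile
    if (!is.null(param_spread)) {
      set.seed((as.integer(seed) + 104729L * i) %% 2147483587L)
      prof$asymmetry <- min(0.85, max(0, stats::rnorm(
        1, prof$asymmetry, param_spread$asymmetry)))
      prof$hf_noise_power <- prof$hf_noise_power *
        stats::rlnorm(1, 0, param_spread$hf_log)
      prof$section_variability <- min(0.6, max(0.01, stats::rnorm(
        1, prof$section_variability, param_spread$section_variability)))
    }
    simulate_session(prof, duration = duration, label = labels[i],
                     seed = as.integer(seed) + i)
  })
  names(sessions) <- sprintf("P%03d", seq_along(labels))
  sessions
}
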