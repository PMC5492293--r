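#' Raw tri-axial accelerometer recording
#'
#' @param site Sensor site, one of `"LB"` (lower back / pelvis), `"LS"` (left
#'   shank), `"RS"` (right shank).
#' @param time_s Strictly increasing sample times in seconds.
#' @param accel Numeric matrix with one row per sample and columns
#'   `V` (vertical, up positive), `ML` (medial-lateral, right positive),
#'   `AP` (anterior-posterior, anterior positive), in g.
#' @param nominal_rate Nominal sampling rate in Hz (50 for the study sensors).
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(site, time_s, accel, nominal_rate = 50) {
  site <- match.arg(site, c("LB", "LS", "RS"))
  accel <- as.matrix(accel)
  if (length(time_s) < 2)
    stop("recording must have at least 2 samples", call. = FALSE)
  if (any(diff(time_s) <= 0))
    stop("recording time must be strictly increasing", call. = FALSE)
  if (nrow(accel) != length(time_s) || ncol(accel) != 3)
    stop("accel must be a length(time_s) x 3 matrix", call. = FALSE)
  if (!all(is.finite(accel)))
    stop("accel values must be finite", call. = FALSE)
  colnames(accel) <- c("V", "ML", "AP")
  structure(list(site = site, time_s = as.numeric(time_s), accel = accel,
                 nominal_rate = nominal_rate),
            class = "raw_recording")
}

#' Resample a recording onto the uniform 50 Hz grid
#'
#' Linear interpolation onto the 0.02 s grid spanning the input time range.
#' Grid points are multiples of 0.02 s, so independently resampled sensors
#' land on a shared phase and can later be aligned by integer sample shifts.
#'
#' @param rec A [raw_recording()].
#' @param rate Target rate in Hz, default 50.
#' @return A `raw_recording` on the uniform grid.
#' @export
resample_50hz <- function(rec, rate = 50) {
  stopifnot(inherits(rec, "raw_recording"))
  dt <- 1 / rate
  t0 <- ceiling(rec$time_s[1] / dt) * dt
  t1 <- floor(rec$time_s[length(rec$time_s)] / dt) * dt
  grid <- seq(t0, t1, by = dt)
  accel <- vapply(1:3, function(j)
    stats::approx(rec$time_s, rec$accel[, j], xout = grid)$y,
    numeric(length(grid)))
  raw_recording(rec$site, grid, accel, nominal_rate = rate)
}

# Local maxima of x with topographic prominence >= `prominence`, at least
# `min_sep` samples apart (greedy, higher peaks win). Returns sorted indices.
# Prominence uses the peak/valley formulation: walk outward over peaks until
# a higher one, tracking the lowest intervening valley; the base is the
# higher of the two valley minima.
find_peaks <- function(x, prominence = 0, min_sep = 1L) {
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  if (length(cand) == 0) return(integer(0))
  k <- length(cand)
  # valley minima between consecutive candidate peaks (and to the ends)
  bounds <- c(1L, cand, n)
  valley <- vapply(seq_len(k + 1L), function(j)
    min(x[bounds[j]:bounds[j + 1L]]), numeric(1))
  h <- x[cand]
  prom <- numeric(k)
  for (i in seq_len(k)) {
    base_l <- valley[i]
    j <- i - 1L
    while (j >= 1L && h[j] <= h[i]) {
      base_l <- min(base_l, valley[j])
      j <- j - 1L
    }
    if (j < 1L) base_l <- min(base_l, valley[1])
    base_r <- valley[i + 1L]
    j <- i + 1L
    while (j <= k && h[j] <= h[i]) {
      base_r <- min(base_r, valley[j + 1L])
      j <- j + 1L
    }
    if (j > k) base_r <- min(base_r, valley[k + 1L])
    prom[i] <- h[i] - max(base_l, base_r)
  }
  keep <- cand[prom >= prominence]
  if (length(keep) <= 1 || min_sep <= 1) return(sort(keep))
  ord <- keep[order(x[keep], decreasing = TRUE)]
  chosen <- integer(0)
  for (i in ord)
    if (!length(chosen) || all(abs(chosen - i) >= min_sep))
      chosen <- c(chosen, i)
  sort(chosen)
}

#' Synchronize the three sensor recordings on their first vertical peak
#'
#' Each recording is time-shifted so that its first qualifying vertical peak
#' (first local maximum with prominence at least `prominence`) lands at a
#' common origin, then all three are truncated to their common overlap. The
#' synthetic generator plants a dedicated 3x-amplitude spike near t = 0 for
#' this purpose.
#'
#' @param recs List of three [raw_recording()]s (sites LB, LS, RS), already
#'   resampled to 50 Hz.
#' @param prominence Minimum prominence (g) for the sync peak, default 1.0.
#' @return A `session`: list with `time_s` (shared time base, 0 at the sync
#'   peak), `signals` (named list of n x 3 matrices per site), `sample_rate`.
#' @export
synchronize <- function(recs, prominence = 1.0) {
  stopifnot(length(recs) == 3)
  sites <- vapply(recs, function(r) r$site, character(1))
  names(recs) <- sites
  if (!setequal(sites, c("LB", "LS", "RS")))
    stop("recordings must cover sites LB, LS, RS", call. = FALSE)
  peak_idx <- lapply(recs, function(r) {
    p <- find_peaks(r$accel[, "V"], prominence = prominence)
    if (!length(p))
      stop(sprintf("no qualifying synchronization peak in site %s", r$site),
           call. = FALSE)
    p[1]
  })
  n <- vapply(recs, function(r) length(r$time_s), integer(1))
  p <- unlist(peak_idx)
  before <- min(p - 1L)
  after <- min(n - p)
  signals <- lapply(sites, function(s) {
    i <- p[[s]]
    recs[[s]]$accel[(i - before):(i + after), , drop = FALSE]
  })
  names(signals) <- sites
  structure(list(time_s = seq(-before, after) * 0.02,
                 signals = signals[c("LB", "LS", "RS")],
                 sample_rate = 50),
            class = "session")
}

#' Detect foot-strike steps in a session's vertical channel
#'
#' Steps are local maxima of the site's vertical acceleration with a minimum
#' separation (default 0.3 s, i.e. a 200 steps/min cadence ceiling) and
#' minimum prominence (default 0.3 g). Peaks before `min_time_s` are ignored
#' so the synchronization transient is not counted as a foot strike.
#'
#' @param session A `session` from [synchronize()].
#' @param site Sensor site.
#' @param min_separation Minimum peak separation in seconds.
#' @param prominence Minimum peak prominence in g.
#' @param min_time_s Earliest admissible step time (s) on the session clock.
#' @return A `step_series`: list with `site` and sorted `step_indices`
#'   (1-based sample indices into the session).
#' @export
detect_steps <- function(session, site, min_separation = 0.3,
                         prominence = 0.3, min_time_s = 0.5) {
  stopifnot(inherits(session, "session"))
  x <- session$signals[[site]][, "V"]
  sep <- max(1L, round(min_separation * session$sample_rate))
  idx <- find_peaks(x, prominence = prominence, min_sep = sep)
  idx <- idx[session$time_s[idx] >= min_time_s]
  structure(list(site = site, step_indices = idx), class = "step_series")
}

new_segment <- function(kind, start_idx, end_idx, steps, depth = NA_real_) {
  structure(list(kind = kind, start_idx = start_idx, end_idx = end_idx,
                 steps = steps, depth = depth), class = "walk_segment")
}

#' Segment walking turns from the drop in vertical acceleration magnitude
#'
#' A sliding-window RMS (default 1.0 s) of the lower-back vertical channel is
#' compared against its session median; maximal runs where the RMS falls below
#' `theta` times the median (run length at least `min_run_s`) are turn
#' candidates. Each candidate's centre step is the detected step nearest the
#' RMS minimum; the turn is standardized to five steps (centre step plus two
#' on each side) with a 0.2 s buffer before the first and after the last
#' step. Candidates with fewer than five available steps are dropped;
#' overlapping segments are resolved by keeping the deeper RMS minimum.
#'
#' @param session A `session`.
#' @param steps A `step_series` for the driving site (normally LB).
#' @param site Site whose vertical channel drives detection, default `"LB"`.
#' @param window_s RMS window length in seconds.
#' @param theta Fraction of the median RMS below which a run is a candidate.
#' @param min_run_s Minimum below-threshold run length in seconds.
#' @param buffer_s Buffer added before the first and after the last turn step.
#' @return List of `walk_segment` of kind `"turn"`, each with exactly 5 steps,
#'   disjoint and ordered. May be empty.
#' @export
segment_turns <- function(session, steps, site = "LB", window_s = 1.0,
                          theta = 0.7, min_run_s = 0.5, buffer_s = 0.2) {
  stopifnot(inherits(session, "session"), inherits(steps, "step_series"))
  rate <- session$sample_rate
  x <- session$signals[[site]][, "V"]
  w <- max(3L, round(window_s * rate))
  if (w %% 2 == 0) w <- w + 1L
  rms <- sqrt(stats::filter(x^2, rep(1 / w, w), sides = 2))
  rms <- as.numeric(rms)
  # pad filter edges with the nearest interior value
  half <- (w - 1L) %/% 2L
  rms[seq_len(half)] <- rms[half + 1L]
  rms[(length(rms) - half + 1L):length(rms)] <- rms[length(rms) - half]
  med <- stats::median(rms)
  below <- rms < theta * med
  if (!any(below)) return(list())
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= round(min_run_s * rate))
  st <- steps$step_indices
  buf <- round(buffer_s * rate)
  cands <- list()
  run_spans <- matrix(integer(0), ncol = 2)
  for (k in runs) {
    seg <- starts[k]:ends[k]
    run_spans <- rbind(run_spans, c(starts[k], ends[k]))
    # centre step: the step nearest the run's midpoint (the RMS minimum
    # itself jitters between step impulses within the attenuated plateau)
    mid_i <- (starts[k] + ends[k]) / 2
    depth <- min(rms[seg])
    if (length(st) < 5) next
    c_pos <- which.min(abs(st - mid_i))
    if (c_pos < 3 || c_pos > length(st) - 2) next
    five <- st[(c_pos - 2):(c_pos + 2)]
    s_idx <- max(1L, five[1] - buf)
    e_idx <- min(length(x) + 1L, five[5] + buf + 1L)  # closed-open
    cands[[length(cands) + 1L]] <-
      new_segment("turn", s_idx, e_idx, five, depth = depth)
  }
  if (!length(cands))
    return(structure(list(), candidate_runs = run_spans))
  # keep deeper minima first, drop overlaps
  ord <- order(vapply(cands, function(s) s$depth, numeric(1)))
  kept <- list()
  for (s in cands[ord]) {
    overlaps <- any(vapply(kept, function(k)
      s$start_idx < k$end_idx && k$start_idx < s$end_idx, logical(1)))
    if (!overlaps) kept[[length(kept) + 1L]] <- s
  }
  out <- kept[order(vapply(kept, function(s) s$start_idx, numeric(1)))]
  # every below-threshold run (even those not yielding a standardized turn)
  # is recorded so straight extraction can stay clear of turning behaviour
  structure(out, candidate_runs = run_spans)
}

#' Extract straight-walking segments as the complement of the turns
#'
#' The walking portion (first to last detected lower-back step) minus the turn
#' segments, trimmed by `buffer_s` at each junction. Segments with fewer than
#' `min_strides` strides of the reference foot (left shank) are discarded.
#'
#' @param session A `session`.
#' @param turns List of turn `walk_segment`s from [segment_turns()].
#' @param steps Lower-back `step_series` (defines the walking portion and the
#'   steps attached to each straight segment).
#' @param ref_steps Reference-foot (LS) `step_series` for the stride filter.
#' @param buffer_s Trim at each junction, seconds.
#' @param min_strides Minimum reference-foot strides per straight segment.
#' @param exclude Optional two-column matrix of extra sample-index intervals
#'   to keep out of straight segments (by default the below-threshold RMS
#'   runs recorded by [segment_turns()], so turning behaviour that did not
#'   yield a standardized five-step turn still never contaminates straight
#'   sections).
#' @return List of `walk_segment` of kind `"straight"`, disjoint from the
#'   turns and from each other, ordered.
#' @export
segment_straight <- function(session, turns, steps, ref_steps,
                             buffer_s = 0.2, min_strides = 3,
                             exclude = attr(turns, "candidate_runs")) {
  stopifnot(inherits(session, "session"))
  st <- steps$step_indices
  if (length(st) < 2) return(list())
  rate <- session$sample_rate
  buf <- round(buffer_s * rate)
  n <- length(session$time_s)
  walk_lo <- max(1L, st[1] - buf)
  walk_hi <- min(n + 1L, st[length(st)] + buf + 1L)
  blocked <- rep(FALSE, n)
  block <- function(lo, hi) {      # closed-open, expanded by the buffer
    lo <- max(1L, as.integer(lo) - buf)
    hi <- min(n, as.integer(hi) + buf - 1L)
    if (lo <= hi) blocked[lo:hi] <<- TRUE
  }
  for (s in turns) block(s$start_idx, s$end_idx)
  if (!is.null(exclude) && nrow(exclude))
    for (i in seq_len(nrow(exclude))) block(exclude[i, 1], exclude[i, 2])
  free <- !blocked & seq_len(n) >= walk_lo & seq_len(n) < walk_hi
  r <- rle(free)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (k in which(r$values)) {
    lo <- starts[k]
    hi <- ends[k] + 1L
    if (hi - lo < rate) next
    ref <- ref_steps$step_indices
    if (sum(ref >= lo & ref < hi) - 1 < min_strides) next
    out[[length(out) + 1L]] <-
      new_segment("straight", lo, hi, st[st >= lo & st < hi])
  }
  out
}

#' Run the full preprocessing chain on one session's raw recordings
#'
#' Resamples each recording to 50 Hz, synchronizes on the first vertical peak,
#' detects steps at all three sites, and segments turns and straight passes.
#' Sessions yielding fewer than two turns are flagged (`flagged = TRUE`),
#' mirroring the exclusion of participants with poor turn segmentation.
#'
#' @param recordings Named list of three [raw_recording()]s.
#' @param sync_prominence Prominence threshold (g) for the sync peak.
#' @param ... Passed to [segment_turns()].
#' @return List with `session`, `steps` (per site), `turns`, `straights`,
#'   `flagged`.
#' @export
preprocess_session <- function(recordings, sync_prominence = 1.0, ...) {
  recs <- lapply(recordings, resample_50hz)
  session <- synchronize(recs, prominence = sync_prominence)
  steps <- lapply(c(LB = "LB", LS = "LS", RS = "RS"),
                  function(s) detect_steps(session, s))
  turns <- segment_turns(session, steps$LB, ...)
  straights <- segment_straight(session, turns, steps$LB, steps$LS)
  list(session = session, steps = steps, turns = turns,
       straights = straights, flagged = length(turns) < 2)
}
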