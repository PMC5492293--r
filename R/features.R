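#' Directional descriptive statistics of one stride's acceleration
#'
#' For a single axis over one stride, statistics are computed separately for
#' the positive direction (samples > 0) and the negative direction (absolute
#' values of samples < 0): maximum, mean, and sample standard deviation
#' (denominator n - 1; 0 when fewer than two samples fall in a direction; all
#' three statistics are 0 when a direction has no samples).
#'
#' @param x Numeric vector, one axis over one stride (>= 2 samples).
#' @return Named numeric vector `max_pos, mean_pos, sd_pos, max_neg,
#'   mean_neg, sd_neg`.
#' @export
directional_stats <- function(x) {
  if (length(x) < 2) stop("stride must have at least 2 samples", call. = FALSE)
  pos <- x[x > 0]
  neg <- abs(x[x < 0])
  one_side <- function(v) {
    if (!length(v)) return(c(0, 0, 0))
    c(max(v), mean(v), if (length(v) >= 2) stats::sd(v) else 0)
  }
  out <- c(one_side(pos), one_side(neg))
  names(out) <- c("max_pos", "mean_pos", "sd_pos",
                  "max_neg", "mean_neg", "sd_neg")
  out
}

#' First-quartile fraction of the FFT magnitude spectrum (FQFFT)
#'
#' Fraction of (mean-detrended) spectral amplitude lying strictly below
#' 12.5 Hz, out of the total up to the 25 Hz Nyquist frequency — the "first
#' quartile" of the 0-50 Hz FFT frequency plot. Values near 1 indicate steady
#' low-frequency movement; high-frequency content pushes the value down.
#'
#' @param x Numeric signal, at least 1 s long.
#' @param rate Sampling rate in Hz (50).
#' @param cutoff Band edge in Hz, default 12.5.
#' @return A value in `[0, 1]`. An all-zero (constant) signal returns 1.
#' @export
fqfft <- function(x, rate = 50, cutoff = 12.5) {
  n <- length(x)
  if (n < rate) stop("need at least 1 s of signal", call. = FALSE)
  x <- x - mean(x)
  amp <- Mod(stats::fft(x))
  freqs <- (seq_len(n) - 1) * rate / n
  half <- freqs > 0 & freqs <= rate / 2
  lo <- sum(amp[half & freqs < cutoff])
  tot <- sum(amp[half])
  if (tot == 0) return(1)
  lo / tot
}

#' Ratio of even to odd harmonics of the stride frequency (REOH)
#'
#' The magnitude spectrum is sampled at the bins nearest the first
#' `n_harmonics` multiples of the stride frequency (the inverse of mean
#' stride time). Even harmonics carry the in-phase, step-periodic component
#' of gait; odd harmonics appear when left and right steps differ. The
#' bounded form even / (even + odd) is returned, so a perfectly symmetric
#' gait approaches 1 and values fall with step-to-step asymmetry.
#'
#' @param x Numeric signal (one axis over one section).
#' @param stride_frequency Stride frequency in Hz (> 0).
#' @param rate Sampling rate in Hz.
#' @param n_harmonics Number of stride-frequency harmonics, default 20.
#' @param normalized If `TRUE` (default) return even/(even+odd); otherwise
#'   the raw even/odd quotient.
#' @return A value in `[0, 1]` (normalized form).
#' @export
reoh <- function(x, stride_frequency, rate = 50, n_harmonics = 20,
                 normalized = TRUE) {
  if (stride_frequency <= 0) stop("stride_frequency must be > 0",
                                  call. = FALSE)
  n <- length(x)
  x <- x - mean(x)
  amp <- Mod(stats::fft(x))
  df <- rate / n
  ks <- seq_len(n_harmonics)
  bins <- pmin(round(ks * stride_frequency / df) + 1L, floor(n / 2) + 1L)
  a <- amp[bins]
  even <- sum(a[ks %% 2 == 0])
  odd <- sum(a[ks %% 2 == 1])
  if (even + odd == 0) return(0)
  if (normalized) even / (even + odd) else even / odd
}

#' Cadence and stride time of a walking section
#'
#' Cadence is computed from the lower-back step train (`60 * (n - 1)` over the
#' first-to-last step interval); stride time is the mean interval between
#' consecutive same-foot (left-shank) strikes.
#'
#' @param lb_step_times Lower-back step times (s) inside the section (>= 2).
#' @param ls_step_times Left-shank strike times (s) inside the section (>= 2).
#' @return Named vector `cadence` (steps/min) and `stride_time` (s).
#' @export
temporal_features <- function(lb_step_times, ls_step_times) {
  if (length(lb_step_times) < 2 || length(ls_step_times) < 2)
    stop("need at least 2 LB steps and 2 reference-foot strikes",
         call. = FALSE)
  span <- lb_step_times[length(lb_step_times)] - lb_step_times[1]
  c(cadence = 60 * (length(lb_step_times) - 1) / span,
    stride_time = mean(diff(ls_step_times)))
}

axes <- c("V", "ML", "AP")

# canonical per-section feature names: 24 per shank, 26 for the lower back
base_feature_names <- function() {
  per_site <- function(site) {
    stats6 <- c("max_pos", "mean_pos", "sd_pos", "max_neg", "mean_neg",
                "sd_neg")
    c(as.vector(outer(stats6, axes,
                      function(s, a) paste(site, s, a, sep = "|"))),
      paste(site, "FQFFT", axes, sep = "|"),
      paste(site, "REOH", axes, sep = "|"))
  }
  c(per_site("LS"), per_site("RS"), per_site("LB"),
    "LB|cadence", "LB|stride_time")
}

# strides of a site inside [lo, hi): list of closed-open index ranges.
# Shank strides are consecutive same-site strike pairs; the lower back is
# anchored to the left-shank strike times.
site_strides <- function(site, lo, hi, steps_by_site) {
  anchor <- if (site == "LB") steps_by_site$LS else steps_by_site[[site]]
  s <- anchor$step_indices
  s <- s[s >= lo & s < hi]
  if (length(s) < 2) return(list())
  lapply(seq_len(length(s) - 1), function(i) c(s[i], s[i + 1]))
}

#' Compute the 74 named features of one walking section
#'
#' Directional statistics are computed per stride and averaged across the
#' section's strides; FQFFT and REOH are computed once on the whole section
#' signal; cadence and stride time come from the lower-back and left-shank
#' step trains. Stride frequency for REOH is the inverse of the section's
#' mean stride time. Features whose inputs are insufficient (e.g. fewer than
#' two reference strikes) are `NA` and are skipped during participant
#' aggregation.
#'
#' @param session A `session`.
#' @param segment A `walk_segment`.
#' @param steps_by_site Named list of `step_series` (LB, LS, RS).
#' @return A `section_features` object: list with `values` (named numeric of
#'   length 74) and `kind`.
#' @export
section_features <- function(session, segment, steps_by_site) {
  lo <- segment$start_idx
  hi <- segment$end_idx
  rate <- session$sample_rate
  nm <- base_feature_names()
  values <- stats::setNames(rep(NA_real_, length(nm)), nm)

  ls_in <- steps_by_site$LS$step_indices
  ls_in <- ls_in[ls_in >= lo & ls_in < hi]
  stride_freq <- if (length(ls_in) >= 2) 1 / mean(diff(ls_in) / rate) else NA

  for (site in c("LS", "RS", "LB")) {
    sig <- session$signals[[site]][lo:(hi - 1), , drop = FALSE]
    strides <- site_strides(site, lo, hi, steps_by_site)
    if (length(strides)) {
      per_stride <- lapply(strides, function(rg) {
        seg <- session$signals[[site]][rg[1]:(rg[2] - 1), , drop = FALSE]
        unlist(lapply(axes, function(a) directional_stats(seg[, a])))
      })
      avg <- Reduce(`+`, per_stride) / length(per_stride)
      k <- 0
      for (a in axes) for (s in c("max_pos", "mean_pos", "sd_pos", "max_neg",
                                  "mean_neg", "sd_neg")) {
        k <- k + 1
        values[paste(site, s, a, sep = "|")] <- avg[k]
      }
    }
    if (nrow(sig) >= rate)
      for (a in axes)
        values[paste(site, "FQFFT", a, sep = "|")] <- fqfft(sig[, a], rate)
    if (!is.na(stride_freq) && nrow(sig) >= 4)
      for (a in axes)
        values[paste(site, "REOH", a, sep = "|")] <-
          reoh(sig[, a], stride_freq, rate)
  }

  lb_in <- steps_by_site$LB$step_indices
  lb_in <- lb_in[lb_in >= lo & lb_in < hi]
  if (length(lb_in) >= 2 && length(ls_in) >= 2) {
    tf <- temporal_features(session$time_s[lb_in], session$time_s[ls_in])
    values["LB|cadence"] <- tf["cadence"]
    values["LB|stride_time"] <- tf["stride_time"]
  }
  structure(list(values = values, kind = segment$kind),
            class = "section_features")
}

#' Aggregate a participant's section features into the 296-feature vector
#'
#' For each of the 74 base features, the maximum, minimum, mean, and sample
#' standard deviation across the participant's sections of one kind are
#' taken, giving 4 x 74 = 296 named values. Missing per-section values are
#' excluded; a base feature missing in every section stays `NA` (the
#' participant should then be excluded from the cohort matrix). The SD of a
#' single observation is 0.
#'
#' @param sections List of `section_features`, all of `condition`'s kind.
#' @param condition `"turn"` or `"straight"`.
#' @param participant_id Participant identifier.
#' @param label `"PF"` or `"NF"`.
#' @return A `participant_features` object: `values` (named numeric, 296),
#'   `participant_id`, `label`, `condition`.
#' @export
aggregate_participant <- function(sections, condition, participant_id,
                                  label = c("NF", "PF")) {
  label <- match.arg(label)
  sections <- Filter(function(s) s$kind == condition, sections)
  if (!length(sections))
    stop("participant has no sections of the requested kind", call. = FALSE)
  mat <- do.call(rbind, lapply(sections, function(s) s$values))
  nm <- base_feature_names()
  aggs <- c("max", "min", "mean", "sd")
  out <- numeric(0)
  for (agg in aggs) {
    v <- apply(mat, 2, function(col) {
      col <- col[!is.na(col)]
      if (!length(col)) return(NA_real_)
      switch(agg,
             max = max(col), min = min(col), mean = mean(col),
             sd = if (length(col) >= 2) stats::sd(col) else 0)
    })
    names(v) <- paste(agg, nm, sep = "|")
    out <- c(out, v)
  }
  structure(list(values = out, participant_id = participant_id,
                 label = label, condition = condition),
            class = "participant_features")
}

#' Concatenate a participant's straight and turn feature vectors
#'
#' @param straight,turn `participant_features` of the same participant with
#'   conditions `"straight"` and `"turn"`.
#' @return A `participant_features` with condition `"combined"` and 592
#'   values, names prefixed by their condition.
#' @export
combine_conditions <- function(straight, turn) {
  if (straight$participant_id != turn$participant_id)
    stop("mismatched participant ids", call. = FALSE)
  if (straight$condition != "straight" || turn$condition != "turn")
    stop("inputs must be the straight and turn condition vectors",
         call. = FALSE)
  values <- c(stats::setNames(straight$values,
                              paste0("straight|", names(straight$values))),
              stats::setNames(turn$values,
                              paste0("turn|", names(turn$values))))
  structure(list(values = values, participant_id = straight$participant_id,
                 label = straight$label, condition = "combined"),
            class = "participant_features")
}

#' Assemble a cohort feature matrix from participant feature vectors
#'
#' Participants with any fully missing feature are dropped (with a message),
#' mirroring the study's exclusion bookkeeping.
#'
#' @param participants List of `participant_features` (same condition).
#' @return A `feature_matrix`: list with `x` (participants x features numeric
#'   matrix), `labels` (factor NF/PF), `participants` (ids).
#' @export
feature_matrix <- function(participants) {
  keep <- vapply(participants, function(p) all(is.finite(p$values)),
                 logical(1))
  if (any(!keep))
    message(sum(!keep), " participant(s) excluded for missing features")
  participants <- participants[keep]
  if (!length(participants)) stop("no complete participants", call. = FALSE)
  x <- do.call(rbind, lapply(participants, function(p) p$values))
  rownames(x) <- vapply(participants, function(p) p$participant_id,
                        character(1))
  structure(list(x = x,
                 labels = factor(vapply(participants, function(p) p$label,
                                        character(1)),
                                 levels = c("NF", "PF")),
                 participants = rownames(x)),
            class = "feature_matrix")
}

#' Extract straight and turn feature matrices from a synthetic cohort
#'
#' Convenience wrapper running [preprocess_session()], [section_features()],
#' and [aggregate_participant()] over every session, returning one
#' [feature_matrix()] per walking condition (plus the combined 592-feature
#' matrix). Sessions flagged for poor turn segmentation are dropped.
#'
#' @param cohort Named list of `synthetic_session` from [simulate_cohort()].
#' @param verbose Print per-session progress counts.
#' @return List with `straight`, `turn`, `combined` feature matrices and
#'   `n_excluded`.
#' @export
cohort_features <- function(cohort, verbose = FALSE) {
  straight <- list()
  turn <- list()
  combined <- list()
  n_excluded <- 0L
  for (id in names(cohort)) {
    sess <- cohort[[id]]
    pp <- preprocess_session(sess$recordings)
    if (pp$flagged || !length(pp$straights)) {
      n_excluded <- n_excluded + 1L
      next
    }
    secs <- lapply(c(pp$turns, pp$straights), function(seg)
      section_features(pp$session, seg, pp$steps))
    ps <- aggregate_participant(secs, "straight", id, sess$label)
    pt <- aggregate_participant(secs, "turn", id, sess$label)
    straight[[id]] <- ps
    turn[[id]] <- pt
    combined[[id]] <- combine_conditions(ps, pt)
    if (verbose)
      message(sprintf("%s: %d turns, %d straights", id, length(pp$turns),
                      length(pp$straights)))
  }
  list(straight = feature_matrix(straight),
       turn = feature_matrix(turn),
       combined = feature_matrix(combined),
       n_excluded = n_excluded)
}
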