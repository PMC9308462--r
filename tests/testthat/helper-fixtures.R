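# Independent brute-force trapezoid oracle: explicit loop, no vectorised
# shortcuts shared with the implementation.
trapezoid_oracle <- function(times, areas) {
  total <- 0
  for (i in seq_len(length(times) - 1)) {
    total <- total + (areas[i] + areas[i + 1]) / 2 * (times[i + 1] - times[i])
  }
  total
}

# Random frame-area series with irregular (but increasing) timestamps.
random_series <- function(n = 15, id = "rnd", whale = "w1") {
  t <- cumsum(runif(n, 0.01, 0.1))
  a <- runif(n, 0, 500)
  frame_area_series(id, whale, t, a)
}

# A 10-Hz speed/jerk track with k lunge templates at known times: 5-s linear
# ramp to 3.5 m/s, 2-s deceleration to 1 m/s, one-sample 2.5 m/s^2
# acceleration pulse at the peak (jerk 25 m/s^3).
make_lunge_track <- function(k, total_s = 600, spacing_s = 60) {
  tt <- seq(0, total_s, by = 0.1)
  n <- length(tt)
  speed <- rep(1.5, n)
  ax <- numeric(n)
  lunge_times <- if (k > 0) 100 + spacing_s * (seq_len(k) - 1) else numeric(0)
  for (lt in lunge_times) {
    ramp <- which(tt >= lt - 5 & tt < lt)
    speed[ramp] <- 1.5 + 2 * (tt[ramp] - (lt - 5)) / 5
    dec <- which(tt >= lt & tt < lt + 2)
    speed[dec] <- 3.5 - 2.5 * (tt[dec] - lt) / 2
    ax[which.min(abs(tt - lt))] <- 2.5
  }
  jerk <- compute_jerk(cbind(ax, 0, 0), times = tt)
  list(times = tt, speed = speed, jerk = jerk, lunge_times = lunge_times)
}

# Breath/submergence event tables for a hand-built deployment: dives at given
# start times/durations, breaths at given times (1-s inhalations by default).
manual_events <- function(breath_times, dive_starts, dive_durs,
                          whale = "bb_manual", breath_dur = 1,
                          ibi_gaps = NULL) {
  breaths <- tibble::tibble(
    whale_id = whale,
    breath_id = sprintf("%s_b%02d", whale, seq_along(breath_times)),
    time_s = breath_times, duration_s = breath_dur)
  subs <- tibble::tibble(
    whale_id = whale, start_s = dive_starts,
    end_s = dive_starts + dive_durs, duration_s = dive_durs,
    max_depth_m = 50, lunge_count = 0)
  if (!is.null(ibi_gaps)) {
    ibis <- tibble::tibble(
      whale_id = whale, start_s = ibi_gaps$start,
      end_s = ibi_gaps$start + ibi_gaps$dur, duration_s = ibi_gaps$dur,
      max_depth_m = 1, lunge_count = 0)
    subs <- dplyr::bind_rows(subs, ibis)
  }
  list(breaths = breaths, submergences = subs)
}
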