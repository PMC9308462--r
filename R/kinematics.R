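#' Compute jerk from 10-Hz tri-axial acceleration
#'
#' Jerk is the norm of the first difference of the tri-axial acceleration
#' signal per unit time: `||a[t+1] - a[t]|| / dt` (m/s^3). The output has one
#' fewer sample than the input and is aligned to the leading sample of each
#' difference.
#'
#' @param accel Numeric matrix or data frame with 3 columns (x, y, z
#'   acceleration, m/s^2), one row per 10-Hz sample.
#' @param times Optional sample timestamps (s), used to check uniform
#'   sampling; if omitted, uniform sampling at `1/fs` is assumed.
#' @param fs Sampling rate (Hz).
#' @param tol Allowed deviation of inter-sample gaps from `1/fs` (s).
#' @return Numeric vector of jerk magnitudes (m/s^3), length `nrow(accel) - 1`.
#' @export
#' @examples
#' a <- cbind(c(0, 2, 2), 0, 0)
#' compute_jerk(a)  # 20, 0
compute_jerk <- function(accel, times = NULL, fs = 10, tol = 1e-6) {
  accel <- as.matrix(accel)
  if (ncol(accel) != 3) stop("accel must have 3 columns", call. = FALSE)
  if (nrow(accel) < 2) stop("need at least 2 samples", call. = FALSE)
  dt <- 1 / fs
  if (!is.null(times)) {
    if (length(times) != nrow(accel))
      stop("times length must match accel rows", call. = FALSE)
    if (any(abs(diff(times) - dt) > tol))
      stop("non-uniform sampling: gaps deviate from ", dt, " s", call. = FALSE)
  }
  d <- diff(accel)
  sqrt(rowSums(d^2)) / dt
}

#' Detect feeding lunges from speed and jerk
#'
#' A lunge is flagged where speed exceeds the speed threshold, drops by at
#' least `decel_frac` of the local peak within the deceleration window that
#' follows, and a jerk sample at or above the jerk threshold occurs within the
#' same window. Candidate events closer together than the refractory gap are
#' merged, keeping the one with the higher peak speed. Thresholds default to
#' the conservative (low) end of the speed and jerk signatures that mark
#' rorqual lunges: acceleration to 3–4 m/s, rapid deceleration at mouth
#' opening, and a 20–30 m/s^3 jerk transient.
#'
#' @param speed Speed series (m/s).
#' @param jerk Jerk series (m/s^3), aligned to `speed` (its natural length is
#'   `length(speed) - 1`; it is compared on the shared index range).
#' @param times Timestamps (s) aligned to `speed`; defaults to 10-Hz indices.
#' @param speed_threshold Minimum peak speed (m/s).
#' @param jerk_threshold Minimum jerk within the window (m/s^3).
#' @param window_s Deceleration window after the peak (s).
#' @param decel_frac Required fractional speed drop within the window.
#' @param refractory_s Events closer than this are merged (s).
#' @return A tibble with one row per lunge: `time_s`, `peak_speed_ms`,
#'   `peak_jerk_ms3`. Empty input gives an empty tibble.
#' @export
detect_lunges <- function(speed, jerk, times = NULL,
                          speed_threshold = 3.0, jerk_threshold = 20,
                          window_s = 5, decel_frac = 0.5,
                          refractory_s = 10) {
  empty <- tibble::tibble(time_s = numeric(0), peak_speed_ms = numeric(0),
                          peak_jerk_ms3 = numeric(0))
  n <- length(speed)
  if (n == 0) return(empty)
  if (is.null(times)) times <- (seq_len(n) - 1) / 10
  if (length(times) != n)
    stop("times must align with speed", call. = FALSE)
  jerk <- c(jerk, rep(0, max(0, n - length(jerk))))[seq_len(n)]

  # local maxima above the speed threshold
  above <- speed > speed_threshold
  if (!any(above)) return(empty)
  is_peak <- above &
    c(TRUE, diff(speed) >= 0) &
    c(speed[-n] >= speed[-1], TRUE)
  cand <- which(is_peak)

  events <- list()
  for (i in cand) {
    win <- which(times > times[i] & times <= times[i] + window_s)
    if (!length(win)) next
    drop_ok <- min(speed[win]) <= (1 - decel_frac) * speed[i]
    jerk_win <- c(i, win)
    jerk_ok <- max(jerk[jerk_win]) >= jerk_threshold
    if (drop_ok && jerk_ok)
      events[[length(events) + 1]] <- tibble::tibble(
        time_s = times[i], peak_speed_ms = speed[i],
        peak_jerk_ms3 = max(jerk[jerk_win]))
  }
  if (!length(events)) return(empty)
  ev <- dplyr::arrange(dplyr::bind_rows(events), .data$time_s)

  # merge within the refractory gap, keeping the higher peak
  keep <- ev[1, ]
  for (i in seq_len(nrow(ev))[-1]) {
    last <- nrow(keep)
    if (ev$time_s[i] - keep$time_s[last] < refractory_s) {
      if (ev$peak_speed_ms[i] > keep$peak_speed_ms[last]) keep[last, ] <- ev[i, ]
    } else keep <- dplyr::bind_rows(keep, ev[i, ])
  }
  keep
}

#' Detect lunges over a kinematic table and attribute them to submergences
#'
#' Runs [compute_jerk()] and [detect_lunges()] per whale over a 10-Hz
#' kinematic table and counts detected lunges per submergence interval.
#'
#' @param kin Kinematic tibble (`whale_id`, `time_s`, `depth_m`, `speed_ms`,
#'   `ax`, `ay`, `az`).
#' @param submergences Optional submergence tibble (`whale_id`, `start_s`,
#'   `end_s`, ...); when given, a `lunge_count` column is recomputed from the
#'   detections.
#' @param config A [naresflow_config()] supplying detector thresholds.
#' @return A list with `lunges` (tibble of detections with `whale_id`) and,
#'   when submergences were given, `submergences` with detected counts.
#' @export
detect_deployment_lunges <- function(kin, submergences = NULL,
                                     config = naresflow_config()) {
  out <- list()
  for (w in unique(kin$whale_id)) {
    k <- kin[kin$whale_id == w, ]
    jerk <- compute_jerk(as.matrix(k[, c("ax", "ay", "az")]), times = k$time_s)
    ev <- detect_lunges(k$speed_ms, jerk, times = k$time_s,
                        speed_threshold = config$lunge_speed_ms,
                        jerk_threshold = config$lunge_jerk_ms3,
                        window_s = config$lunge_window_s,
                        decel_frac = config$lunge_decel_frac,
                        refractory_s = config$lunge_refractory_s)
    if (nrow(ev)) ev$whale_id <- w
    out[[w]] <- ev
  }
  lunges <- dplyr::bind_rows(out)
  res <- list(lunges = lunges)
  if (!is.null(submergences)) {
    sub <- submergences
    sub$lunge_count <- vapply(seq_len(nrow(sub)), function(i) {
      sum(lunges$whale_id == sub$whale_id[i] &
            lunges$time_s >= sub$start_s[i] &
            lunges$time_s < sub$end_s[i])
    }, numeric(1))
    res$submergences <- sub
  }
  res
}
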