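#' Ground-truth parameters for a synthetic deployment
#'
#' Bundles everything the generator needs and everything a recovery test must
#' know afterwards: the log-scale two-component submergence-duration mixture
#' (an inter-breath-interval mode of tens of seconds and a dive mode of
#' minutes), multiplicative breath-type effects on inhalation duration and
#' nares area, the species-dependent plateau fraction of the expansion curve,
#' and the lunge-injection rate.
#'
#' Defaults emulate the two tagged species: the IBI mode centred near 18 s and
#' the dive mode near 250 s (log-scale SD 0.4 each), a terminal breath twice as
#' long and two-and-a-half times as large as an initial breath, a short minke
#' plateau (0.2 of the inhalation) versus a long humpback plateau (0.6), and
#' base inhalation durations of 0.45 s (minke) and 0.9 s (humpback).
#'
#' @param mu_ibi,sigma_ibi Mean and SD of log submergence duration for the
#'   inter-breath-interval component.
#' @param mu_dive,sigma_dive Same for the dive component.
#' @param weight Mixture weight of the IBI component (0 < weight < 1 when both
#'   components are in play; `weight = 1` degenerates to IBIs only).
#' @param dur_mult,area_mult Named multipliers (initial/middle/terminal) on
#'   inhalation duration and maximum nares area; initial is the reference.
#' @param base_duration_s Named per-species baseline initial-breath duration.
#' @param base_area_px Baseline maximum nares area scale; each whale gets its
#'   own camera-dependent scale around this (areas are relative, not absolute).
#' @param plateau_frac Named per-species plateau fraction of the expansion
#'   curve, in (0, 1).
#' @param breath_cv Log-scale SD of per-breath multiplicative noise.
#' @param whale_sd Log-scale SD of the per-whale random effect on duration.
#' @param mean_breaths Mean breath count per surface sequence (min 2 enforced).
#' @param lunge_rate Mean injected lunges per dive (Poisson).
#' @param area_noise_sd SD of additive frame-area noise (px); 0 = noise-free.
#' @param speed_noise_sd SD of additive speed noise (m/s); 0 = noise-free.
#' @param seed Integer seed; all generator substreams derive from it.
#' @return A list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(mu_ibi = log(18), sigma_ibi = 0.4,
                            mu_dive = log(250), sigma_dive = 0.4,
                            weight = 0.85,
                            dur_mult = c(initial = 1, middle = 1, terminal = 2),
                            area_mult = c(initial = 1, middle = 1, terminal = 2.5),
                            base_duration_s = c(bb = 0.45, mn = 0.9),
                            base_area_px = 1500,
                            plateau_frac = c(bb = 0.2, mn = 0.6),
                            breath_cv = 0.2,
                            whale_sd = 0.15,
                            mean_breaths = 6,
                            lunge_rate = 1.5,
                            area_noise_sd = 0,
                            speed_noise_sd = 0,
                            seed = 1L) {
  stopifnot(sigma_ibi > 0, sigma_dive > 0, weight > 0, weight <= 1,
            all(dur_mult > 0), all(area_mult > 0),
            all(plateau_frac > 0), all(plateau_frac < 1),
            breath_cv >= 0, whale_sd >= 0, mean_breaths >= 2,
            lunge_rate >= 0, area_noise_sd >= 0, speed_noise_sd >= 0)
  structure(as.list(environment()), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth>\n")
  cat("  submergence mixture: IBI lognormal(", format(x$mu_ibi, digits = 3),
      ", ", x$sigma_ibi, "), dive lognormal(", format(x$mu_dive, digits = 3),
      ", ", x$sigma_dive, "), IBI weight ", x$weight, "\n", sep = "")
  cat("  duration multipliers: ", paste(names(x$dur_mult), x$dur_mult,
                                        sep = "=", collapse = ", "), "\n", sep = "")
  cat("  area multipliers: ", paste(names(x$area_mult), x$area_mult,
                                    sep = "=", collapse = ", "), "\n", sep = "")
  cat("  seed: ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Generate one trapezoidal nares-expansion curve
#'
#' The nares area rises linearly from zero, holds a plateau near the maximum
#' for `plateau_frac` of the inhalation, and falls linearly back to zero — the
#' rapid-increase/plateau/rapid-decrease shape seen on tag video, with the
#' plateau fraction separating species (short for minke, long for humpback).
#' Optional iid Gaussian noise is added and clipped at zero.
#'
#' @param duration Inhalation duration (s), at least `3 * dt`.
#' @param max_area Plateau area (px).
#' @param plateau_frac Plateau length as a fraction of `duration`, in (0, 1).
#' @param dt Frame interval (s); 1/30 matches 30-fps tag video.
#' @param noise_sd SD of additive area noise (px).
#' @param seed Optional integer seed for the noise.
#' @param breath_id,whale_id Identifiers for the resulting series.
#' @return A [frame_area_series()].
#' @export
#' @examples
#' s <- generate_expansion_curve(1, 100, 0.5)
#' max(s$areas)
generate_expansion_curve <- function(duration, max_area, plateau_frac,
                                     dt = 1 / 30, noise_sd = 0, seed = NULL,
                                     breath_id = "synthetic",
                                     whale_id = "synthetic") {
  stopifnot(duration >= 3 * dt, plateau_frac > 0, plateau_frac < 1,
            max_area > 0)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, duration, by = dt)
  if (duration - times[length(times)] > dt / 2) times <- c(times, duration)
  ramp <- (1 - plateau_frac) / 2 * duration
  areas <- vapply(times, function(t) {
    if (t < ramp) max_area * t / ramp
    else if (t <= duration - ramp) max_area
    else max_area * (duration - t) / ramp
  }, numeric(1))
  if (noise_sd > 0)
    areas <- pmax(0, areas + stats::rnorm(length(areas), 0, noise_sd))
  frame_area_series(breath_id, whale_id, times, areas)
}

#' Draw submergence durations from a two-component lognormal mixture
#'
#' The bimodal (on the log scale) distribution of submersion durations is the
#' basis for splitting submersions into inter-breath intervals and dives.
#'
#' @param n Number of durations to draw.
#' @param truth A [synthetic_truth()] carrying the mixture parameters.
#' @param seed Optional integer seed.
#' @return Numeric vector of durations (s).
#' @export
generate_submergences <- function(n, truth = synthetic_truth(), seed = NULL) {
  stopifnot(n >= 1)
  if (truth$sigma_ibi <= 0 || truth$sigma_dive <= 0)
    stop("mixture sigmas must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  from_ibi <- stats::runif(n) < truth$weight
  stats::rlnorm(n,
                meanlog = ifelse(from_ibi, truth$mu_ibi, truth$mu_dive),
                sdlog = ifelse(from_ibi, truth$sigma_ibi, truth$sigma_dive))
}

#' Generate a breath table with known breath-type effects
#'
#' A lightweight counterpart to [generate_deployment()] for statistical
#' recovery tests: per-whale breath events with types, durations and
#' per-whale-normalized area metrics drawn under known multiplicative
#' breath-type effects and a lognormal whale-level random effect, without
#' kinematics or frame curves. Breaths are organised into surface sequences of
#' random length (min 2) so type proportions are realistic.
#'
#' @param n_whales Number of whales; species alternate bb/mn.
#' @param breaths_per_whale Breath count per whale.
#' @param truth A [synthetic_truth()]; `dur_mult`, `area_mult`, `breath_cv`,
#'   `whale_sd`, `mean_breaths` and the species baselines are used.
#' @param seed Integer seed.
#' @return A tibble with columns `whale_id`, `species`, `breath_id`,
#'   `sequence_id`, `breath_type`, `duration_s`, `max_area_px`, `ia_px_s`,
#'   `norm_IA`, `norm_max_area`.
#' @export
generate_breath_table <- function(n_whales = 6, breaths_per_whale = 40,
                                  truth = synthetic_truth(), seed = 1L) {
  set.seed(seed)
  rows <- list()
  for (w in seq_len(n_whales)) {
    species <- c("bb", "mn")[(w - 1) %% 2 + 1]
    whale_id <- sprintf("%s_sim%02d", species, w)
    base_dur <- truth$base_duration_s[[species]] *
      stats::rlnorm(1, 0, truth$whale_sd)
    area_scale <- truth$base_area_px * stats::runif(1, 0.5, 2)
    types <- character(0)
    s <- 0L
    seq_id <- integer(0)
    while (length(types) < breaths_per_whale) {
      s <- s + 1L
      k <- max(2L, stats::rpois(1, truth$mean_breaths))
      types <- c(types, c("initial", rep("middle", k - 2L), "terminal"))
      seq_id <- c(seq_id, rep(s, k))
    }
    types <- types[seq_len(breaths_per_whale)]
    seq_id <- seq_id[seq_len(breaths_per_whale)]
    n <- breaths_per_whale
    dur <- base_dur * truth$dur_mult[types] *
      stats::rlnorm(n, 0, truth$breath_cv)
    amax <- area_scale * truth$area_mult[types] *
      stats::rlnorm(n, 0, truth$breath_cv)
    pf <- truth$plateau_frac[[species]]
    rows[[w]] <- tibble::tibble(
      whale_id = whale_id, species = species,
      breath_id = sprintf("%s_b%03d", whale_id, seq_len(n)),
      sequence_id = sprintf("%s_s%03d", whale_id, seq_id),
      breath_type = types, duration_s = dur, max_area_px = amax,
      ia_px_s = amax * dur * (1 + pf) / 2)
  }
  out <- dplyr::bind_rows(rows)
  out$norm_IA <- normalize_per_whale(out$ia_px_s, out$whale_id)
  out$norm_max_area <- normalize_per_whale(out$max_area_px, out$whale_id)
  out
}

# Depth profile of one submergence: linear descent (20% of duration), flat
# bottom, linear ascent (20%). Shallow fixed depth for IBIs.
submergence_depth <- function(t_rel, duration, max_depth) {
  ramp <- 0.2 * duration
  ifelse(t_rel < ramp, max_depth * t_rel / ramp,
         ifelse(t_rel > duration - ramp,
                max_depth * (duration - t_rel) / ramp, max_depth))
}

#' Generate a complete synthetic deployment
#'
#' Builds one whale-deployment record with known ground truth: an alternating
#' schedule of submergences (drawn dive-mode for sequence boundaries, IBI-mode
#' for within-sequence gaps), surface sequences of at least two breaths whose
#' terminal breath duration and area are scaled by the truth multipliers, a
#' trapezoidal frame-area curve per breath, a 10-Hz kinematic series (time,
#' depth, speed, tri-axial acceleration), and feeding lunges injected on dive
#' bottom phases as a 5-s speed ramp to 3.5 m/s followed by a 2-s deceleration
#' with a 25 m/s^3 jerk transient.
#'
#' The schedule starts with a dive at time zero so the first sequence has a
#' preceding dive; sequences inside the 30-min warm-up window arise naturally
#' and are left for the segmentation stage to drop. If a drawn submergence
#' would overrun the requested deployment length the schedule is truncated
#' with a warning.
#'
#' @param truth A [synthetic_truth()].
#' @param hours Deployment length (h).
#' @param whale_id Whale identifier; its prefix before `_` is the species code.
#' @param species Species code used for baselines and plateau fraction.
#' @param seed Integer seed; overrides `truth$seed` when given.
#' @return A list with `kinematics` (tibble), `frames` (list of
#'   [frame_area_series()]), `events` (list of `breaths`/`submergences`
#'   tibbles), and `truth` (the input truth plus realised per-breath types,
#'   true lunge times and true sequence boundaries).
#' @export
generate_deployment <- function(truth = synthetic_truth(), hours = 3,
                                whale_id = "bb_sim01", species = NULL,
                                seed = NULL) {
  stopifnot(hours > 0)
  if (is.null(seed)) seed <- truth$seed
  set.seed(seed)
  if (is.null(species)) species <- sub("_.*$", "", whale_id)
  if (!species %in% names(truth$base_duration_s))
    stop("unknown species code: ", species, call. = FALSE)
  total_s <- hours * 3600
  base_dur <- truth$base_duration_s[[species]]
  area_scale <- truth$base_area_px * stats::runif(1, 0.5, 2)
  pf <- truth$plateau_frac[[species]]

  draw_dur <- function(meanlog, sdlog) stats::rlnorm(1, meanlog, sdlog)

  subs <- list(); breaths <- list(); frames <- list()
  lunge_times <- numeric(0); seq_bounds <- list()
  t <- 0; b <- 0L; s <- 0L; truncated <- FALSE

  repeat {
    # dive delimiting the next surface sequence
    dive_dur <- draw_dur(truth$mu_dive, truth$sigma_dive)
    if (t + dive_dur > total_s) { truncated <- TRUE; break }
    max_depth <- max(5, 0.25 * dive_dur * stats::runif(1, 0.8, 1.2))
    n_lunges <- stats::rpois(1, truth$lunge_rate)
    # bottom phase holds the lunges, spaced beyond the detector refractory
    bottom <- c(t + 0.25 * dive_dur, t + 0.75 * dive_dur)
    max_fit <- max(0, floor((bottom[2] - bottom[1]) / 30))
    n_lunges <- min(n_lunges, max_fit)
    lt <- if (n_lunges > 0) bottom[1] + 30 * (seq_len(n_lunges) - 1) +
      stats::runif(n_lunges, 0, 5) else numeric(0)
    lunge_times <- c(lunge_times, lt)
    subs[[length(subs) + 1]] <- tibble::tibble(
      whale_id = whale_id, start_s = t, end_s = t + dive_dur,
      duration_s = dive_dur, max_depth_m = max_depth,
      lunge_count = n_lunges)
    t <- t + dive_dur

    # surface sequence: >= 2 breaths separated by IBI-mode gaps
    n_breaths <- max(2L, stats::rpois(1, truth$mean_breaths))
    types <- c("initial", rep("middle", n_breaths - 2L), "terminal")
    seq_start <- t
    ok <- TRUE
    for (i in seq_len(n_breaths)) {
      ty <- types[i]
      dur <- base_dur * truth$dur_mult[[ty]] *
        stats::rlnorm(1, 0, truth$breath_cv)
      amax <- area_scale * truth$area_mult[[ty]] *
        stats::rlnorm(1, 0, truth$breath_cv)
      if (t + dur > total_s) { truncated <- TRUE; ok <- FALSE; break }
      b <- b + 1L
      bid <- sprintf("%s_b%04d", whale_id, b)
      fr <- generate_expansion_curve(dur, amax, pf, dt = 1 / 30,
                                     noise_sd = truth$area_noise_sd,
                                     breath_id = bid, whale_id = whale_id)
      fr$times <- fr$times + t
      frames[[bid]] <- fr
      breaths[[length(breaths) + 1]] <- tibble::tibble(
        whale_id = whale_id, breath_id = bid, time_s = t, duration_s = dur,
        true_type = ty)
      t <- t + dur
      if (i < n_breaths) {
        gap <- draw_dur(truth$mu_ibi, truth$sigma_ibi)
        if (t + gap > total_s) { truncated <- TRUE; ok <- FALSE; break }
        subs[[length(subs) + 1]] <- tibble::tibble(
          whale_id = whale_id, start_s = t, end_s = t + gap,
          duration_s = gap, max_depth_m = min(2, 0.1 * gap), lunge_count = 0L)
        t <- t + gap
      }
    }
    if (!ok) break
    s <- s + 1L
    seq_bounds[[s]] <- tibble::tibble(whale_id = whale_id,
                                      start_s = seq_start, end_s = t,
                                      n_breaths = n_breaths)
  }
  # hitting the requested deployment end is the normal stopping rule; only a
  # record too short to hold one dive + sequence merits a warning
  if (length(seq_bounds) == 0)
    warning("deployment too short for a single dive + surface sequence",
            call. = FALSE)

  subs <- dplyr::bind_rows(subs)
  breaths <- dplyr::bind_rows(breaths)
  if (nrow(breaths) == 0)
    breaths <- tibble::tibble(whale_id = character(), breath_id = character(),
                              time_s = numeric(), duration_s = numeric(),
                              true_type = character())

  kin <- deployment_kinematics(whale_id, total_s, subs, lunge_times,
                               truth$speed_noise_sd)

  truth_out <- truth
  truth_out$seed <- as.integer(seed)
  truth_out$whale_id <- whale_id
  truth_out$species <- species
  truth_out$breath_types <- breaths[, c("breath_id", "true_type")]
  truth_out$lunge_times <- lunge_times
  truth_out$sequences <- dplyr::bind_rows(seq_bounds)

  list(kinematics = kin,
       frames = frames,
       events = list(breaths = breaths[, c("whale_id", "breath_id", "time_s",
                                           "duration_s")],
                     submergences = subs),
       truth = truth_out)
}

# 10-Hz time/depth/speed/accel series for one deployment. Surface cruise at
# 1.5 m/s; each lunge is a 5-s linear ramp to 3.5 m/s, 2-s deceleration to
# 1 m/s, with a single-sample 2.5 m/s^2 acceleration pulse at the peak
# (jerk transient 25 m/s^3 at 10 Hz).
deployment_kinematics <- function(whale_id, total_s, subs, lunge_times,
                                  speed_noise_sd = 0) {
  tt <- seq(0, total_s, by = 0.1)
  n <- length(tt)
  depth <- numeric(n)
  for (i in seq_len(nrow(subs))) {
    idx <- which(tt >= subs$start_s[i] & tt < subs$end_s[i])
    depth[idx] <- submergence_depth(tt[idx] - subs$start_s[i],
                                    subs$duration_s[i], subs$max_depth_m[i])
  }
  speed <- rep(1.5, n)
  ax <- numeric(n); ay <- numeric(n); az <- numeric(n)
  for (lt in lunge_times) {
    ramp <- which(tt >= lt - 5 & tt < lt)
    speed[ramp] <- 1.5 + (3.5 - 1.5) * (tt[ramp] - (lt - 5)) / 5
    dec <- which(tt >= lt & tt < lt + 2)
    speed[dec] <- 3.5 - (3.5 - 1.0) * (tt[dec] - lt) / 2
    peak <- which.min(abs(tt - lt))
    ax[peak] <- 2.5  # one-sample pulse -> jerk 25 m/s^3 at both edges
  }
  if (speed_noise_sd > 0)
    speed <- pmax(0, speed + stats::rnorm(n, 0, speed_noise_sd))
  tibble::tibble(whale_id = whale_id, time_s = tt, depth_m = depth,
                 speed_ms = speed, ax = ax, ay = ay, az = az)
}
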