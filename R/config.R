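#' Build a pipeline run configuration
#'
#' Collects every tunable the pipeline uses: the dive/IBI duration threshold,
#' the post-deployment warm-up exclusion, the per-species frame stride for
#' integrated-area calculation, lunge-detection thresholds, the GLMM family
#' assigned to each breath metric, and the Bonferroni family sizes applied to
#' the contrast and dive-effort tests.
#'
#' @param dive_threshold_s Submersions strictly longer than this are dives;
#'   submersions shorter than or equal to it are inter-breath intervals (s).
#' @param warmup_exclusion_s Surface sequences starting earlier than this many
#'   seconds after tag-on are discarded (tag-deployment stress window).
#' @param frame_stride Named integer vector mapping species code to the frame
#'   stride used for integrated area (every frame = 1, every other frame = 2).
#' @param lunge_speed_ms Minimum peak speed for a lunge candidate (m/s).
#' @param lunge_jerk_ms3 Minimum jerk transient within the lunge window (m/s^3).
#' @param lunge_window_s Deceleration window after the speed peak (s).
#' @param lunge_decel_frac Required fractional speed drop within the window.
#' @param lunge_refractory_s Events closer than this are merged (s).
#' @param glmm_family Named character vector mapping breath metric to GLMM
#'   family; areas are proportions of each whale's maximum (beta/logit),
#'   durations are positive and right-skewed (gamma/log).
#' @param bonferroni Named numeric vector of adjusted critical p-values:
#'   `breath_type` for the three pairwise contrasts (0.05/3), `dive_duration`
#'   and `dive_count` for the dive-effort model families.
#' @param column_map Named character vector remapping the reader's canonical
#'   column names to the names found in a particular CSV, e.g.
#'   `c(time_s = "timestamp")`. Supplementary files in the wild do not share a
#'   single header convention, so the schema is remappable.
#' @param seed Integer seed from which all simulation substreams derive.
#'
#' @return A list of class `naresflow_config`.
#' @export
#' @examples
#' cfg <- naresflow_config(seed = 7)
#' cfg$dive_threshold_s
naresflow_config <- function(dive_threshold_s = 90,
                             warmup_exclusion_s = 1800,
                             frame_stride = c(bb = 1L, mn = 2L),
                             lunge_speed_ms = 3.0,
                             lunge_jerk_ms3 = 20,
                             lunge_window_s = 5,
                             lunge_decel_frac = 0.5,
                             lunge_refractory_s = 10,
                             glmm_family = c(duration = "gamma",
                                             norm_IA = "beta",
                                             norm_max_area = "beta"),
                             bonferroni = c(breath_type = 0.05 / 3,
                                            dive_duration = 0.0125,
                                            dive_count = 0.025),
                             column_map = character(),
                             seed = 1L) {
  stopifnot(dive_threshold_s > 0, warmup_exclusion_s >= 0,
            lunge_speed_ms > 0, lunge_jerk_ms3 > 0, lunge_window_s > 0,
            lunge_decel_frac > 0, lunge_decel_frac < 1,
            lunge_refractory_s >= 0)
  frame_stride <- vapply(frame_stride, as.integer, integer(1))
  if (!all(frame_stride %in% 1:3))
    stop("frame_stride values must be 1, 2 or 3", call. = FALSE)
  if (!all(glmm_family %in% c("gamma", "beta", "poisson")))
    stop("glmm_family values must be 'gamma', 'beta' or 'poisson'", call. = FALSE)
  structure(list(
    dive_threshold_s = dive_threshold_s,
    warmup_exclusion_s = warmup_exclusion_s,
    frame_stride = frame_stride,
    lunge_speed_ms = lunge_speed_ms,
    lunge_jerk_ms3 = lunge_jerk_ms3,
    lunge_window_s = lunge_window_s,
    lunge_decel_frac = lunge_decel_frac,
    lunge_refractory_s = lunge_refractory_s,
    glmm_family = glmm_family,
    bonferroni = bonferroni,
    column_map = column_map,
    seed = as.integer(seed)
  ), class = "naresflow_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected so that typos in a config file fail loudly rather
#' than silently falling back to defaults.
#'
#' @param path Path to a YAML file whose keys match [naresflow_config()]
#'   arguments.
#' @return A `naresflow_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(naresflow_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  for (nm in c("frame_stride", "glmm_family", "bonferroni", "column_map"))
    if (!is.null(vals[[nm]])) vals[[nm]] <- unlist(vals[[nm]])
  do.call(naresflow_config, vals)
}

#' Write a run configuration to YAML
#'
#' @param config A `naresflow_config` list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "naresflow_config"))
  yaml::write_yaml(lapply(unclass(config), function(x)
    if (length(names(x))) as.list(x) else x), path)
  invisible(path)
}

#' @export
print.naresflow_config <- function(x, ...) {
  cat("<naresflow_config>\n")
  cat("  dive threshold: ", x$dive_threshold_s, " s (<= threshold is an IBI)\n", sep = "")
  cat("  warm-up exclusion: ", x$warmup_exclusion_s, " s\n", sep = "")
  cat("  frame stride: ", paste(names(x$frame_stride), x$frame_stride,
                                sep = "=", collapse = ", "), "\n", sep = "")
  cat("  lunge: speed > ", x$lunge_speed_ms, " m/s, jerk >= ", x$lunge_jerk_ms3,
      " m/s^3, window ", x$lunge_window_s, " s\n", sep = "")
  cat("  seed: ", x$seed, "\n", sep = "")
  invisible(x)
}
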