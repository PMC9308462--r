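#' Integrated nares area of one inhalation
#'
#' The integrated area (IA) is the trapezoid sum over consecutive retained
#' frames,
#' `IA = sum_i ((A_i + A_{i+1}) / 2) * (t_{i+1} - t_i)` (px.s),
#' using the actual frame timestamps — no uniform frame interval is assumed.
#' With `stride = 2` every other frame is used (starting at the first frame),
#' the convention for long humpback inhalations; minke inhalations use every
#' frame. The last frame is always retained, so the strided sum still accounts
#' for the total duration of the inhalation.
#'
#' @param frames A [frame_area_series()].
#' @param stride Frame stride (1, 2 or 3).
#' @return IA in px.s.
#' @export
#' @examples
#' s <- frame_area_series("b", "w", c(0, 0.5), c(0, 4))
#' integrated_area(s)  # 1.0
integrated_area <- function(frames, stride = 1L) {
  stopifnot(inherits(frames, "frame_area_series"))
  stride <- as.integer(stride)
  if (!stride %in% 1:3) stop("stride must be 1, 2 or 3", call. = FALSE)
  n <- length(frames$times)
  idx <- unique(c(seq(1L, n, by = stride), n))
  if (length(idx) < 2)
    stop("fewer than 2 frames after striding for breath ", frames$breath_id,
         call. = FALSE)
  t <- frames$times[idx]
  a <- frames$areas[idx]
  sum((a[-length(a)] + a[-1]) / 2 * diff(t))
}

#' Maximum nares area of one inhalation
#'
#' The largest single-frame area (px). Always taken over every frame — the
#' peak is a single-frame statistic, so the IA stride does not apply.
#'
#' @param frames A [frame_area_series()].
#' @return Maximum area in px.
#' @export
max_nares_area <- function(frames) {
  stopifnot(inherits(frames, "frame_area_series"))
  if (length(frames$areas) == 0) stop("empty series", call. = FALSE)
  max(frames$areas)
}

#' Inhalation duration from a frame-area series
#'
#' Time between the first and last frames displaying nares expansion (s);
#' unaffected by the IA stride.
#'
#' @param frames A [frame_area_series()].
#' @return Duration in s.
#' @export
inhalation_duration <- function(frames) {
  stopifnot(inherits(frames, "frame_area_series"))
  frames$times[length(frames$times)] - frames$times[1]
}

#' Normalize breath metrics to each whale's maximum
#'
#' Raw IA and maximum-area values depend on camera placement and are not
#' comparable across whales; each value is therefore divided by its whale's
#' maximum over all analysed breaths (all three breath types), so every
#' whale's largest breath maps to exactly 1.
#'
#' @param values Non-negative metric values, at least one positive per whale.
#' @param whale_ids Whale grouping, same length as `values`.
#' @return Fractions in (0, 1], per-whale maximum exactly 1. `NA` values pass
#'   through untouched and are ignored when finding the maximum.
#' @export
#' @examples
#' normalize_per_whale(c(2, 4, 8), rep("w1", 3))
normalize_per_whale <- function(values, whale_ids) {
  stopifnot(length(values) == length(whale_ids))
  if (any(values < 0, na.rm = TRUE))
    stop("metric values must be non-negative", call. = FALSE)
  out <- rep(NA_real_, length(values))
  for (w in unique(whale_ids)) {
    idx <- whale_ids == w
    m <- suppressWarnings(max(values[idx], na.rm = TRUE))
    if (!is.finite(m) || m <= 0)
      stop("whale ", w, " has no positive metric value to normalize by",
           call. = FALSE)
    out[idx] <- values[idx] / m
  }
  out
}

#' Frame-resolution sensitivity of the integrated area
#'
#' Recomputes the IA of each breath at two strides and returns the per-breath
#' percent difference `100 * (IA_a - IA_b) / IA_b`, the paired input for a
#' t-test of the every-frame versus every-other-frame comparison.
#'
#' @param frames_list A list of [frame_area_series()] with at least 4 frames
#'   each.
#' @param stride_a,stride_b The two strides to compare.
#' @return A tibble with `breath_id`, `whale_id`, `ia_a`, `ia_b`,
#'   `pct_diff`.
#' @export
resolution_difference <- function(frames_list, stride_a = 1L, stride_b = 2L) {
  purrr::map_dfr(frames_list, function(s) {
    if (length(s$times) < 4)
      stop("breath ", s$breath_id, " has fewer than 4 frames", call. = FALSE)
    ia_a <- integrated_area(s, stride_a)
    ia_b <- integrated_area(s, stride_b)
    tibble::tibble(breath_id = s$breath_id, whale_id = s$whale_id,
                   ia_a = ia_a, ia_b = ia_b,
                   pct_diff = 100 * (ia_a - ia_b) / ia_b)
  })
}

#' Normalized expansion curves and per-type summary curves
#'
#' Rescales each breath's frame-area curve to the unit square — time to the
#' breath's own span (endpoints at 0 and 1), area to the largest single-frame
#' area in the deployment (so only the deployment's largest breath reaches
#' 1) — and resamples it onto a fixed 101-point grid by linear interpolation.
#' The summary curve for each breath type is the pointwise mean over that
#' type's breaths. The absolute duration is kept per curve so a
#' longest-duration-stretched rendering remains possible.
#'
#' @param frames_list A list of [frame_area_series()].
#' @param breath_types Optional named character vector (breath_id -> type);
#'   when given, per-type summary curves are computed.
#' @param n_grid Number of grid points on the relative time axis.
#' @return A list with `curves` (tibble: `breath_id`, `whale_id`,
#'   `duration_s`, `rel_time`, `rel_area`) and `summary` (tibble:
#'   `breath_type`, `rel_time`, `mean_rel_area`; `NULL` when no types given).
#' @export
normalized_curves <- function(frames_list, breath_types = NULL,
                              n_grid = 101L) {
  stopifnot(length(frames_list) >= 1)
  amax <- max(vapply(frames_list, function(s) max(s$areas), numeric(1)))
  grid <- seq(0, 1, length.out = n_grid)
  curves <- purrr::map_dfr(frames_list, function(s) {
    dur <- inhalation_duration(s)
    rel_t <- (s$times - s$times[1]) / dur
    rel_a <- s$areas / amax
    tibble::tibble(breath_id = s$breath_id, whale_id = s$whale_id,
                   duration_s = dur, rel_time = grid,
                   rel_area = stats::approx(rel_t, rel_a, xout = grid)$y)
  })
  summary <- NULL
  if (!is.null(breath_types)) {
    curves$breath_type <- unname(breath_types[curves$breath_id])
    summary <- curves |>
      dplyr::filter(!is.na(.data$breath_type)) |>
      dplyr::group_by(.data$breath_type, .data$rel_time) |>
      dplyr::summarise(mean_rel_area = mean(.data$rel_area), .groups = "drop")
  }
  list(curves = curves, summary = summary)
}

#' Compute the full per-breath metric table
#'
#' Applies [inhalation_duration()], [integrated_area()] (at the species
#' stride) and [max_nares_area()] (always stride 1) to every frame-area
#' series, then normalizes IA and maximum area per whale.
#'
#' @param frames_list A list of [frame_area_series()].
#' @param species Named character vector (whale_id -> species code) used to
#'   look up the stride; whales not listed use stride 1.
#' @param config A [naresflow_config()] supplying `frame_stride`.
#' @return A tibble with `whale_id`, `breath_id`, `duration_s`, `ia_px_s`,
#'   `max_area_px`, `norm_IA`, `norm_max_area`, `n_frames_used`.
#' @export
breath_metric_table <- function(frames_list, species = NULL,
                                config = naresflow_config()) {
  out <- purrr::map_dfr(frames_list, function(s) {
    sp <- if (!is.null(species)) species[[s$whale_id]] else NULL
    stride <- if (!is.null(sp) && sp %in% names(config$frame_stride))
      config$frame_stride[[sp]] else 1L
    tibble::tibble(
      whale_id = s$whale_id, breath_id = s$breath_id,
      duration_s = inhalation_duration(s),
      ia_px_s = integrated_area(s, stride),
      max_area_px = max_nares_area(s),
      n_frames_used = length(unique(c(seq(1L, length(s$times), by = stride),
                                      length(s$times)))))
  })
  out$norm_IA <- normalize_per_whale(out$ia_px_s, out$whale_id)
  out$norm_max_area <- normalize_per_whale(out$max_area_px, out$whale_id)
  out
}
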