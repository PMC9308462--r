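#' Construct a nares frame-area series for one inhalation
#'
#' Holds the raw material of the integrated-area calculation: the area of the
#' open nares (px) measured on each exported video frame of one inhalation,
#' with the frame timestamps (s from tag-on).
#'
#' @param breath_id Identifier of the inhalation.
#' @param whale_id Identifier of the tagged whale (field ID).
#' @param times Numeric, strictly increasing frame timestamps (s), length >= 2.
#' @param areas Numeric, non-negative nares areas (px), same length as `times`.
#' @return An object of class `frame_area_series`.
#' @export
#' @examples
#' frame_area_series("b1", "w1", times = c(0, 1 / 30), areas = c(0, 4))
frame_area_series <- function(breath_id, whale_id, times, areas) {
  times <- as.numeric(times)
  areas <- as.numeric(areas)
  if (length(times) != length(areas))
    stop("times and areas must have equal length", call. = FALSE)
  if (length(times) < 2)
    stop("a frame-area series needs at least 2 frames", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(areas < 0))
    stop("areas must be non-negative", call. = FALSE)
  structure(list(breath_id = as.character(breath_id),
                 whale_id = as.character(whale_id),
                 times = times, areas = areas),
            class = "frame_area_series")
}

#' @export
print.frame_area_series <- function(x, ...) {
  cat("<frame_area_series> breath ", x$breath_id, " (whale ", x$whale_id, "): ",
      length(x$times), " frames over ",
      format(x$times[length(x$times)] - x$times[1], digits = 3), " s, peak ",
      format(max(x$areas), digits = 4), " px\n", sep = "")
  invisible(x)
}

# Apply a user column remapping, then check required columns are present.
remap_columns <- function(df, required, column_map = character(), what = "table") {
  for (canon in names(column_map)) {
    src <- column_map[[canon]]
    if (src %in% names(df)) names(df)[names(df) == src] <- canon
  }
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

#' Read per-inhalation frame-area series from CSV
#'
#' Expects columns `whale_id`, `breath_id`, `time_s`, `area_px` (remappable via
#' the config's `column_map`). Rows are grouped by breath and sorted by time,
#' so the result is invariant to input row order. A breath whose timestamps are
#' not strictly increasing after sorting (i.e. duplicated frame times) is
#' rejected with a warning naming the breath; negative areas are an error.
#'
#' @param path CSV file path.
#' @param column_map Optional named character vector, see [naresflow_config()].
#' @return A named list of [frame_area_series()] objects, one per breath.
#' @export
read_frame_areas <- function(path, column_map = character()) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  df <- remap_columns(df, c("whale_id", "breath_id", "time_s", "area_px"),
                      column_map, "frame-area table")
  if (nrow(df) == 0) {
    warning("empty frame-area file: ", path, call. = FALSE)
    return(list())
  }
  if (any(df$area_px < 0))
    stop("negative area_px in ", path, call. = FALSE)
  out <- list()
  for (bid in sort(unique(as.character(df$breath_id)))) {
    rows <- df[df$breath_id == bid, ]
    rows <- rows[order(rows$time_s), ]
    if (anyDuplicated(rows$time_s)) {
      warning("breath ", bid, " rejected: duplicated frame timestamps",
              call. = FALSE)
      next
    }
    out[[as.character(bid)]] <- frame_area_series(
      bid, rows$whale_id[1], rows$time_s, rows$area_px)
  }
  out
}

#' Write frame-area series to CSV
#'
#' Inverse of [read_frame_areas()]: round-trips field-for-field.
#'
#' @param series A list of [frame_area_series()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_frame_areas <- function(series, path) {
  df <- purrr::map_dfr(series, function(s)
    tibble::tibble(whale_id = s$whale_id, breath_id = s$breath_id,
                   time_s = s$times, area_px = s$areas))
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Read a breath/submergence event table from CSV
#'
#' One file carries both record kinds, distinguished by an `event` column with
#' values `"breath"` or `"submergence"`. Breaths need `whale_id`, `breath_id`,
#' `time_s` (inhalation start) and `duration_s`; optional `ia_px_s` and
#' `max_area_px` are kept as-is and flagged `has_area = FALSE` when missing,
#' never imputed. Submergences need `whale_id`, `time_s` (start) and
#' `duration_s`; optional `max_depth_m` and `lunge_count`.
#'
#' @param path CSV file path.
#' @param column_map Optional named character vector, see [naresflow_config()].
#' @return A list with tibbles `breaths` and `submergences`.
#' @export
read_event_table <- function(path, column_map = character()) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) {
    warning("empty event table: ", path, call. = FALSE)
    return(list(breaths = tibble::tibble(), submergences = tibble::tibble()))
  }
  df <- remap_columns(df, c("event", "whale_id", "time_s", "duration_s"),
                      column_map, "event table")
  if (any(!df$event %in% c("breath", "submergence")))
    stop("event column must be 'breath' or 'submergence'", call. = FALSE)
  if (any(df$duration_s <= 0))
    stop("non-positive duration_s in ", path, call. = FALSE)

  br <- df[df$event == "breath", ]
  if (nrow(br)) {
    if (!"breath_id" %in% names(br))
      stop("breath rows need a breath_id column", call. = FALSE)
    dup <- br$breath_id[duplicated(br$breath_id)]
    if (length(dup))
      stop("duplicated breath row(s): ", paste(unique(dup), collapse = ", "),
           call. = FALSE)
    for (opt in c("ia_px_s", "max_area_px"))
      if (!opt %in% names(br)) br[[opt]] <- NA_real_
    br <- tibble::tibble(
      whale_id = as.character(br$whale_id),
      breath_id = as.character(br$breath_id),
      time_s = br$time_s, duration_s = br$duration_s,
      ia_px_s = br$ia_px_s, max_area_px = br$max_area_px,
      has_area = !is.na(br$ia_px_s) & !is.na(br$max_area_px))
    br <- dplyr::arrange(br, .data$whale_id, .data$time_s)
  } else br <- tibble::tibble()

  sub <- df[df$event == "submergence", ]
  if (nrow(sub)) {
    for (opt in c("max_depth_m", "lunge_count"))
      if (!opt %in% names(sub)) sub[[opt]] <- NA_real_
    sub <- tibble::tibble(
      whale_id = as.character(sub$whale_id),
      start_s = sub$time_s, end_s = sub$time_s + sub$duration_s,
      duration_s = sub$duration_s,
      max_depth_m = sub$max_depth_m, lunge_count = sub$lunge_count)
    sub <- dplyr::arrange(sub, .data$whale_id, .data$start_s)
  } else sub <- tibble::tibble()

  list(breaths = br, submergences = sub)
}

#' Write a breath/submergence event table to CSV
#'
#' @param events A list with tibbles `breaths` and `submergences`, as returned
#'   by [read_event_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  br <- events$breaths
  sub <- events$submergences
  rows <- list()
  if (!is.null(br) && nrow(br))
    rows$br <- tibble::tibble(
      event = "breath", whale_id = br$whale_id, breath_id = br$breath_id,
      time_s = br$time_s, duration_s = br$duration_s,
      ia_px_s = if ("ia_px_s" %in% names(br)) br$ia_px_s else NA_real_,
      max_area_px = if ("max_area_px" %in% names(br)) br$max_area_px
                    else NA_real_,
      max_depth_m = NA_real_, lunge_count = NA_real_)
  if (!is.null(sub) && nrow(sub))
    rows$sub <- tibble::tibble(
      event = "submergence", whale_id = sub$whale_id, breath_id = NA_character_,
      time_s = sub$start_s, duration_s = sub$duration_s,
      ia_px_s = NA_real_, max_area_px = NA_real_,
      max_depth_m = sub$max_depth_m, lunge_count = sub$lunge_count)
  readr::write_csv(dplyr::bind_rows(rows), path, progress = FALSE)
  invisible(path)
}

#' Read a 10-Hz kinematic series from CSV
#'
#' Expects `whale_id`, `time_s`, `depth_m`, `speed_ms`, `ax`, `ay`, `az`.
#' Sampling must be uniform at 10 Hz within tolerance and depth non-negative.
#'
#' @param path CSV file path.
#' @param column_map Optional named character vector.
#' @return A tibble, one row per 10-Hz sample.
#' @export
read_kinematics <- function(path, column_map = character()) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  df <- remap_columns(df, c("whale_id", "time_s", "depth_m", "speed_ms",
                            "ax", "ay", "az"), column_map, "kinematic table")
  for (w in unique(df$whale_id)) {
    dt <- diff(df$time_s[df$whale_id == w])
    if (any(abs(dt - 0.1) > 1e-6))
      stop("kinematic series for whale ", w, " is not uniform 10 Hz",
           call. = FALSE)
  }
  if (any(df$depth_m < -1e-9))
    stop("negative depth_m in ", path, call. = FALSE)
  tibble::as_tibble(df)
}

#' Write a kinematic series to CSV
#'
#' @param kin Tibble as returned by [read_kinematics()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_kinematics <- function(kin, path) {
  readr::write_csv(kin, path, progress = FALSE)
  invisible(path)
}
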