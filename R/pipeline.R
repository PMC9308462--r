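#' Simulate a multi-whale study
#'
#' Generates one synthetic deployment per whale (species alternating
#' minke/humpback) and pools the kinematics, frame-area series and event
#' tables. Per-whale generator substreams derive deterministically from the
#' single seed.
#'
#' @param n_whales Number of whales.
#' @param hours Deployment length per whale (h).
#' @param truth A [synthetic_truth()] shared by all whales.
#' @param seed Integer seed.
#' @return A list with `kinematics`, `frames`, `events`, and `truths` (one
#'   realised truth per whale).
#' @export
simulate_deployments <- function(n_whales = 6, hours = 3,
                                 truth = synthetic_truth(), seed = 1L) {
  deps <- lapply(seq_len(n_whales), function(w) {
    species <- c("bb", "mn")[(w - 1) %% 2 + 1]
    generate_deployment(truth, hours = hours,
                        whale_id = sprintf("%s_sim%02d", species, w),
                        species = species, seed = seed + 1000L * w)
  })
  list(
    kinematics = dplyr::bind_rows(lapply(deps, `[[`, "kinematics")),
    frames = do.call(c, lapply(deps, `[[`, "frames")),
    events = list(
      breaths = dplyr::bind_rows(lapply(deps, function(d) d$events$breaths)),
      submergences = dplyr::bind_rows(lapply(deps, function(d)
        d$events$submergences))),
    truths = lapply(deps, `[[`, "truth"))
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> lunge detection -> dive/IBI segmentation
#' -> breath metrics -> the GLMM battery, writing each stage's output as tidy
#' CSV plus a JSON run manifest (config snapshot, seed, record counts, file
#' digests, per-stage wall-clock). Stages communicate only via these files, so
#' any stage can be re-run in isolation.
#'
#' @param config A [naresflow_config()].
#' @param out_dir Output directory (created if needed).
#' @param inputs Optional named list of existing input CSV paths (`frames`,
#'   `events`, `kinematics`); when `NULL` a synthetic study is simulated.
#' @param simulate_args List of arguments passed to [simulate_deployments()]
#'   when simulating (`n_whales`, `hours`, `truth`).
#' @return The run manifest, invisibly, with stage outputs attached as
#'   attribute `"results"`.
#' @export
run_pipeline <- function(config = naresflow_config(), out_dir,
                         inputs = NULL,
                         simulate_args = list(n_whales = 6, hours = 3)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  stages <- list()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    stages[[name]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  if (is.null(inputs)) {
    sim <- do.call(simulate_deployments,
                   c(simulate_args, list(seed = config$seed)))
    frames <- sim$frames
    events <- sim$events
    kin <- sim$kinematics
    truth_path <- file.path(out_dir, "truth.json")
    jsonlite::write_json(lapply(sim$truths, function(tr) list(
      whale_id = tr$whale_id, species = tr$species,
      dur_mult = as.list(tr$dur_mult), area_mult = as.list(tr$area_mult),
      n_breaths = nrow(tr$breath_types), n_lunges = length(tr$lunge_times),
      lunge_times = tr$lunge_times)),
      truth_path, auto_unbox = TRUE, digits = NA)
  } else {
    for (nm in c("frames", "events", "kinematics"))
      if (!file.exists(inputs[[nm]] %||% ""))
        stop("missing input file for stage '", nm, "': ",
             inputs[[nm]] %||% "<unset>", call. = FALSE)
    frames <- read_frame_areas(inputs$frames, config$column_map)
    events <- read_event_table(inputs$events, config$column_map)
    kin <- read_kinematics(inputs$kinematics, config$column_map)
    unknown <- setdiff(unique(vapply(frames, `[[`, character(1), "whale_id")),
                       unique(events$breaths$whale_id))
    if (length(unknown))
      stop("frame data references unknown whale_id: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  write_frame_areas(frames, file.path(out_dir, "frames.csv"))
  write_event_table(events, file.path(out_dir, "events.csv"))
  write_kinematics(kin, file.path(out_dir, "kinematics.csv"))
  tick("inputs")

  lunges <- detect_deployment_lunges(kin, events$submergences, config)
  readr::write_csv(lunges$lunges, file.path(out_dir, "lunges.csv"),
                   progress = FALSE)
  tick("lunges")

  seg <- build_surface_sequences(events$breaths, lunges$submergences,
                                 threshold = config$dive_threshold_s,
                                 warmup_exclusion_s = config$warmup_exclusion_s)
  readr::write_csv(seg$sequences, file.path(out_dir, "sequences.csv"),
                   progress = FALSE)
  tick("segment")

  species <- stats::setNames(sub("_.*$", "", unique(seg$breaths$whale_id)),
                             unique(seg$breaths$whale_id))
  metrics <- breath_metric_table(frames, species = species, config = config)
  breaths <- dplyr::inner_join(
    seg$breaths[, c("whale_id", "breath_id", "sequence_id", "breath_type")],
    metrics[, setdiff(names(metrics), "whale_id")], by = "breath_id")
  breaths$species <- species[breaths$whale_id]
  readr::write_csv(breaths, file.path(out_dir, "breaths.csv"),
                   progress = FALSE)
  tick("metrics")

  fits <- list()
  contrasts <- list()
  for (metric in c("duration", "norm_IA", "norm_max_area")) {
    fits[[metric]] <- fit_breath_metric_glmm(breaths, metric, config)
    ct <- pairwise_contrasts(fits[[metric]])
    ct$metric <- metric
    contrasts[[metric]] <- ct
  }
  contrast_tab <- dplyr::bind_rows(contrasts)
  readr::write_csv(contrast_tab, file.path(out_dir, "contrasts.csv"),
                   progress = FALSE)
  coef_tab <- dplyr::bind_rows(lapply(names(fits), function(m) {
    co <- fits[[m]]$coefficients
    co$metric <- m
    co$AIC <- fits[[m]]$AIC
    co
  }))
  readr::write_csv(coef_tab, file.path(out_dir, "model_coefficients.csv"),
                   progress = FALSE)

  effort <- NULL
  n_complete <- sum(seg$sequences$complete)
  if (n_complete >= 10) {
    effort <- list(
      total_inhalation_duration =
        dive_effort_model_comparison(seg$sequences,
                                     "total_inhalation_duration"),
      breath_count = dive_effort_model_comparison(seg$sequences,
                                                  "breath_count"))
    effort_tab <- dplyr::bind_rows(lapply(names(effort), function(r) {
      tb <- effort[[r]]$table
      tb$response <- r
      tb
    }))
    readr::write_csv(effort_tab, file.path(out_dir, "dive_effort_models.csv"),
                     progress = FALSE)
  }
  tick("stats")

  out_files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- list(
    config = unclass(config),
    seed = config$seed,
    simulated = is.null(inputs),
    counts = list(
      breaths = nrow(breaths),
      submergences = nrow(events$submergences),
      sequences = nrow(seg$sequences),
      complete_sequences = n_complete,
      lunges = nrow(lunges$lunges)),
    stage_seconds = stages,
    outputs = stats::setNames(
      as.list(unname(tools::md5sum(out_files))), basename(out_files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res <- list(breaths = breaths, sequences = seg$sequences,
              lunges = lunges$lunges, fits = fits,
              contrasts = contrast_tab, effort = effort)
  invisible(structure(manifest, results = res))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
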