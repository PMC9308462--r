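#' Classify submersions as dives or inter-breath intervals
#'
#' A submersion strictly longer than the threshold is a dive; one shorter than
#' or equal to it is an inter-breath interval (IBI) lying within a surface
#' sequence. The default 90-s threshold is the rule applied to all whales; see
#' [derive_dive_threshold()] for the data-driven calibration that motivates it.
#'
#' @param durations Positive submersion durations (s).
#' @param threshold Dive/IBI boundary (s); exactly equal durations are IBIs.
#' @return Character vector, `"dive"` or `"IBI"`, one per duration.
#' @export
#' @examples
#' classify_submergences(c(84, 90, 92))
classify_submergences <- function(durations, threshold = 90) {
  if (any(durations <= 0))
    stop("submersion durations must be positive", call. = FALSE)
  ifelse(durations > threshold, "dive", "IBI")
}

#' Derive the dive/IBI threshold from the bimodal log-duration distribution
#'
#' Fits a two-component Gaussian mixture to log submersion durations by EM and
#' returns the back-transformed midpoint of the two component means (the
#' geometric mean of the two modes). With an IBI mode near 18 s and a dive
#' mode near 250 s this lands on the order of the 90-s rule.
#'
#' @param durations Positive submersion durations (s), at least 20, spanning
#'   both modes.
#' @param min_separation Minimum distance between component means (log units)
#'   below which the input is declared unimodal.
#' @return The threshold (s).
#' @export
#' @examples
#' d <- c(rlnorm(200, log(18), 0.3), rlnorm(100, log(250), 0.3))
#' derive_dive_threshold(d)
derive_dive_threshold <- function(durations, min_separation = 0.1) {
  if (any(durations <= 0))
    stop("submersion durations must be positive", call. = FALSE)
  if (length(durations) < 20)
    stop("need at least 20 durations to fit the mixture", call. = FALSE)
  logd <- log(durations)
  # two point masses solve the mixture exactly; EM cannot (zero variances)
  if (length(unique(logd)) == 2) {
    mu <- sort(unique(logd))
    if (diff(mu) < min_separation)
      stop("no bimodality detected: component means within ",
           min_separation, " log-units", call. = FALSE)
    return(exp(mean(mu)))
  }
  # Mclust resolves mclustBIC in the caller's environment; bind it locally
  mclustBIC <- mclust::mclustBIC
  fit <- mclust::Mclust(logd, G = 1:2, modelNames = "V", verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed", call. = FALSE)
  if (fit$G < 2)
    stop("no bimodality detected: one component preferred by BIC",
         call. = FALSE)
  mu <- sort(as.numeric(fit$parameters$mean))
  if (diff(mu) < min_separation)
    stop("no bimodality detected: component means within ",
         min_separation, " log-units", call. = FALSE)
  exp(mean(mu))
}

#' Build surface sequences from breath events and submergences
#'
#' A surface sequence is the ordered series of breaths between two dives; IBIs
#' (submersions at or below the dive threshold) do not split a sequence.
#' Sequences starting inside the warm-up exclusion window are dropped, as are
#' single-breath sequences. A sequence at a recording edge — missing its
#' preceding or upcoming dive — is kept (flagged `complete = FALSE`) for
#' breath-type statistics but must be excluded from dive-effort models.
#'
#' @param breaths Tibble of breath events (`whale_id`, `breath_id`, `time_s`,
#'   `duration_s`, optionally more), time-sorted within whale or not — they
#'   are sorted here.
#' @param submergences Tibble with `whale_id`, `start_s`, `end_s`,
#'   `duration_s`, optionally `max_depth_m`, `lunge_count`.
#' @param threshold Dive/IBI boundary (s).
#' @param warmup_exclusion_s Sequences starting before this are dropped (s).
#' @return A list with `sequences` (one row per retained sequence:
#'   `sequence_id`, `whale_id`, `start_s`, `end_s`, `breath_count`,
#'   `total_inhalation_duration_s`, `complete`, previous/upcoming dive
#'   duration, depth and lunge count) and `breaths` (the input breath rows of
#'   retained sequences with `sequence_id` and `breath_type` attached).
#' @export
build_surface_sequences <- function(breaths, submergences, threshold = 90,
                                    warmup_exclusion_s = 1800) {
  seq_rows <- list(); breath_rows <- list()
  for (w in unique(breaths$whale_id)) {
    br <- dplyr::arrange(breaths[breaths$whale_id == w, ], .data$time_s)
    sub <- dplyr::arrange(submergences[submergences$whale_id == w, ],
                          .data$start_s)
    if (nrow(sub) > 1 && any(sub$start_s[-1] < sub$end_s[-nrow(sub)] - 1e-9))
      stop("overlapping submergences for whale ", w, call. = FALSE)
    sub$class <- classify_submergences(sub$duration_s, threshold)
    dives <- sub[sub$class == "dive", ]

    # dive intervals partition the record; breaths fall in the gaps between
    # consecutive dives (or before the first / after the last = edge
    # sequences). Dive edges are shrunk by a microsecond so a breath logged
    # exactly at a dive boundary survives CSV round-trip rounding.
    eps <- 1e-6
    bounds <- c(-Inf,
                as.vector(t(cbind(dives$start_s + eps, dives$end_s - eps))),
                Inf)
    slot <- findInterval(br$time_s, bounds)  # odd slots = between dives
    in_gap <- slot %% 2 == 1
    if (any(!in_gap))
      stop("breath(s) inside a dive interval for whale ", w, ": ",
           paste(br$breath_id[!in_gap], collapse = ", "), call. = FALSE)
    gap_index <- (slot + 1) %/% 2  # 1 = before first dive, nrow(dives)+1 = after last
    for (g in sort(unique(gap_index))) {
      rows <- br[gap_index == g, ]
      if (nrow(rows) < 2) next  # single-breath sequences omitted
      if (rows$time_s[1] < warmup_exclusion_s) next
      prev_dive <- if (g >= 2) dives[g - 1, ] else NULL
      next_dive <- if (g <= nrow(dives)) dives[g, ] else NULL
      sid <- sprintf("%s_seq%03d", w, g)
      rows$sequence_id <- sid
      rows$breath_type <- assign_breath_types(nrow(rows))
      breath_rows[[sid]] <- rows
      seq_rows[[sid]] <- tibble::tibble(
        sequence_id = sid, whale_id = w,
        start_s = rows$time_s[1],
        end_s = rows$time_s[nrow(rows)] + rows$duration_s[nrow(rows)],
        breath_count = nrow(rows),
        total_inhalation_duration_s = sum(rows$duration_s),
        complete = !is.null(prev_dive) && !is.null(next_dive),
        prev_dive_duration_s = if (is.null(prev_dive)) NA_real_ else prev_dive$duration_s,
        prev_dive_max_depth_m = if (is.null(prev_dive)) NA_real_ else prev_dive$max_depth_m,
        prev_dive_lunges = if (is.null(prev_dive)) NA_real_ else prev_dive$lunge_count,
        next_dive_duration_s = if (is.null(next_dive)) NA_real_ else next_dive$duration_s,
        next_dive_max_depth_m = if (is.null(next_dive)) NA_real_ else next_dive$max_depth_m,
        next_dive_lunges = if (is.null(next_dive)) NA_real_ else next_dive$lunge_count)
    }
  }
  list(sequences = dplyr::bind_rows(seq_rows),
       breaths = dplyr::bind_rows(breath_rows))
}

#' Assign breath types within one surface sequence
#'
#' The first breath after a dive is the initial breath, the last before the
#' next dive is the terminal breath, and everything between is a middle
#' breath.
#'
#' @param n Breath count of the sequence (>= 2; single-breath sequences must
#'   already have been dropped).
#' @return Character vector of length `n`:
#'   `c("initial", "middle" * (n - 2), "terminal")`.
#' @export
#' @examples
#' assign_breath_types(5)
assign_breath_types <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 2)
    stop("a surface sequence must have at least 2 breaths", call. = FALSE)
  c("initial", rep("middle", n - 2L), "terminal")
}
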