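# Wald z for 95% intervals; intervals are estimate +/- 1.96 SE on the link
# scale throughout.
WALD_Z <- 1.96

# Fit a glmmTMB model, progressively dropping random-effect terms whose
# variance collapses to zero when the Hessian is not positive definite (a
# singular fit leaves Wald SEs undefined; the simplified model gives the same
# fixed-effect estimates with usable inference).
fit_glmm_robust <- function(fixed, re_terms, data, family) {
  repeat {
    fstr <- paste(c(fixed, re_terms), collapse = " + ")
    caught <- list()
    fit <- withCallingHandlers(
      glmmTMB::glmmTMB(stats::as.formula(fstr), family = family,
                       data = data),
      warning = function(w) {
        caught[[length(caught) + 1]] <<- w
        invokeRestart("muffleWarning")
      })
    co <- summary(fit)$coefficients$cond
    ok <- isTRUE(fit$sdr$pdHess) && !any(is.nan(co[, "Std. Error"]))
    if (ok || !length(re_terms)) {
      # re-signal warnings only when this fit is the one being returned
      if (!ok) for (w in caught) warning(w)
      return(list(fit = fit, re_terms = re_terms))
    }
    vc <- glmmTMB::VarCorr(fit)$cond
    vars <- vapply(vc, function(v) as.numeric(v[1, 1]), numeric(1))
    smallest <- names(vars)[which.min(vars)]
    re_terms <- re_terms[!grepl(smallest, re_terms, fixed = TRUE)]
  }
}

# Tidy a glmmTMB fit into the package's model_fit container.
as_model_fit <- function(fit, family, link, formula_str) {
  co <- summary(fit)$coefficients$cond
  coefs <- tibble::tibble(
    term = rownames(co),
    estimate = co[, "Estimate"],
    se = co[, "Std. Error"],
    ci_lo = co[, "Estimate"] - WALD_Z * co[, "Std. Error"],
    ci_hi = co[, "Estimate"] + WALD_Z * co[, "Std. Error"],
    z = co[, "z value"],
    p = co[, "Pr(>|z|)"])
  vc <- glmmTMB::VarCorr(fit)$cond
  ranef_var <- vapply(vc, function(v) as.numeric(v[1, 1]), numeric(1))
  fl <- fit$modelInfo$reTrms$cond$flist
  ng <- if (length(fl)) vapply(fl, nlevels, integer(1)) else integer(0)
  structure(list(
    fit = fit, family = family, link = link, formula = formula_str,
    coefficients = coefs, ranef_var = ranef_var,
    AIC = stats::AIC(fit), logLik = as.numeric(stats::logLik(fit)),
    n_obs = stats::nobs(fit), n_groups = ng),
    class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat("<model_fit> ", x$formula, "\n", sep = "")
  cat("  family: ", x$family, "(link = ", x$link, "), ML/Laplace\n", sep = "")
  cat("  n = ", x$n_obs, " observations, groups: ",
      paste(names(x$n_groups), x$n_groups, sep = "=", collapse = ", "),
      "\n", sep = "")
  cat("  AIC = ", format(x$AIC, digits = 6), ", logLik = ",
      format(x$logLik, digits = 6), "\n\n", sep = "")
  print(as.data.frame(x$coefficients), digits = 4, row.names = FALSE)
  invisible(x)
}

# Squeeze proportions in (0, 1] onto the open interval required by the beta
# family: y' = (y * (n - 1) + 0.5) / n. Each whale's normalizing breath sits
# exactly at 1, which the beta support excludes.
squeeze_unit <- function(y) {
  n <- length(y)
  (y * (n - 1) + 0.5) / n
}

#' Fit a breath-metric GLMM with breath type as predictor
#'
#' Fits the maximum-likelihood GLMM (Laplace approximation) for one breath
#' metric with breath type as the fixed predictor and whale ID as a random
#' intercept. The family follows the metric: inhalation duration is positive
#' and right-skewed (gamma, log link); normalized IA and normalized maximum
#' area are proportions of each whale's maximum (beta, logit link, after
#' squeezing the unit maxima onto the open interval).
#'
#' @param breaths Tibble with `whale_id`, `breath_id`, `breath_type` and the
#'   metric column (`duration_s`, `norm_IA` or `norm_max_area`).
#' @param metric One of `"duration"`, `"norm_IA"`, `"norm_max_area"`.
#' @param config A [naresflow_config()]; supplies the metric-to-family map.
#' @return A `model_fit` object.
#' @export
fit_breath_metric_glmm <- function(breaths,
                                   metric = c("duration", "norm_IA",
                                              "norm_max_area"),
                                   config = naresflow_config()) {
  metric <- match.arg(metric)
  col <- switch(metric, duration = "duration_s", metric)
  if (!col %in% names(breaths))
    stop("breaths table lacks column ", col, call. = FALSE)
  d <- breaths[!is.na(breaths[[col]]), ]
  if (length(unique(d$whale_id)) < 2)
    stop("need at least 2 whales", call. = FALSE)
  if (length(unique(d$breath_type)) < 2)
    stop("need at least 2 breath types", call. = FALSE)
  y <- d[[col]]
  family <- config$glmm_family[[metric]]
  if (family == "gamma") {
    bad <- which(y <= 0)
    if (length(bad))
      stop("non-positive ", metric, " for record(s): ",
           paste(d$breath_id[bad], collapse = ", "), call. = FALSE)
    fam <- stats::Gamma(link = "log")
    link <- "log"
  } else if (family == "beta") {
    bad <- which(y <= 0 | y > 1)
    if (length(bad))
      stop(metric, " outside (0, 1] for record(s): ",
           paste(d$breath_id[bad], collapse = ", "), call. = FALSE)
    y <- squeeze_unit(y)
    fam <- glmmTMB::beta_family(link = "logit")
    link <- "logit"
  } else stop("unsupported family for ", metric, call. = FALSE)
  d$.y <- y
  d$breath_type <- factor(d$breath_type,
                          levels = c("initial", "middle", "terminal"))
  d$breath_type <- droplevels(d$breath_type)
  rf <- fit_glmm_robust(".y ~ breath_type", "(1 | whale_id)", d, fam)
  as_model_fit(rf$fit, family, link,
               paste(c(paste0(metric, " ~ breath_type"), rf$re_terms),
                     collapse = " + "))
}

#' Pairwise breath-type contrasts with Bonferroni correction
#'
#' Post-hoc contrasts between each pair of breath types, computed on the
#' model's link scale from estimated marginal means. Significance is flagged
#' against the Bonferroni-adjusted critical p-value `alpha / m` with strict
#' inequality.
#'
#' @param model A `model_fit` from [fit_breath_metric_glmm()].
#' @param alpha Familywise significance level.
#' @param m Bonferroni family size (3 pairs of breath types).
#' @return A tibble with `contrast`, `estimate` (link scale), `se`, `z`, `p`,
#'   `alpha_adjusted`, `significant`.
#' @export
pairwise_contrasts <- function(model, alpha = 0.05, m = 3) {
  stopifnot(inherits(model, "model_fit"))
  emm <- emmeans::emmeans(model$fit, ~breath_type)
  if (nrow(summary(emm)) < 2)
    stop("model has fewer than 2 breath-type levels", call. = FALSE)
  pr <- summary(emmeans::contrast(emm, method = "pairwise", adjust = "none"))
  tibble::tibble(
    contrast = as.character(pr$contrast),
    estimate = pr$estimate, se = pr$SE, z = pr$z.ratio, p = pr$p.value,
    alpha_adjusted = alpha / m,
    significant = pr$p.value < alpha / m)
}

#' Fit a maximum-area vs inhalation-duration GLMM
#'
#' The relationship between normalized maximum nares area (beta, logit link)
#' and inhalation duration, with species as a fixed effect and whale ID as a
#' random intercept.
#'
#' @param breaths Tibble with `whale_id`, `species`, `duration_s`,
#'   `norm_max_area`.
#' @return A `model_fit`.
#' @export
fit_area_duration_glmm <- function(breaths) {
  d <- breaths[!is.na(breaths$norm_max_area), ]
  d$.y <- squeeze_unit(d$norm_max_area)
  d$species <- factor(d$species)
  rf <- fit_glmm_robust(".y ~ duration_s + species", "(1 | whale_id)", d,
                        glmmTMB::beta_family(link = "logit"))
  as_model_fit(rf$fit, "beta", "logit",
               paste(c("norm_max_area ~ duration_s + species", rf$re_terms),
                     collapse = " + "))
}

#' Fit a dive-effort GLMM for one surface-sequence response
#'
#' Second-degree polynomial GLMM relating a surface-sequence response to the
#' duration and/or lunge count of the previous or upcoming dive, with whale ID
#' and species as random intercepts. Total inhalation duration uses the gamma
#' family with log link; breath count uses Poisson with log link. Only
#' complete sequences (both flanking dives present) are used.
#'
#' @param sequences Sequence tibble from [build_surface_sequences()], with a
#'   `species` column (added if missing from the `whale_id` prefix before
#'   `"_"`).
#' @param response `"total_inhalation_duration"` or `"breath_count"`.
#' @param which_dive `"next"` (upcoming) or `"prev"` (previous).
#' @param predictors Subset of `c("duration", "lunges")`.
#' @param degree Polynomial degree for the dive-duration term (lunge count
#'   also receives a quadratic term when degree is 2 and it varies enough).
#' @return A `model_fit`.
#' @export
fit_dive_effort_glmm <- function(sequences,
                                 response = c("total_inhalation_duration",
                                              "breath_count"),
                                 which_dive = c("next", "prev"),
                                 predictors = c("duration", "lunges"),
                                 degree = 2) {
  response <- match.arg(response)
  which_dive <- match.arg(which_dive)
  predictors <- match.arg(predictors, several.ok = TRUE)
  d <- sequences[sequences$complete, ]
  if (nrow(d) < 10)
    stop("need at least 10 complete surface sequences, got ", nrow(d),
         call. = FALSE)
  if (!"species" %in% names(d)) d$species <- sub("_.*$", "", d$whale_id)
  # dive duration enters in minutes: keeps the quadratic term well scaled
  d$dd <- d[[paste0(ifelse(which_dive == "next", "next", "prev"),
                    "_dive_duration_s")]] / 60
  d$lc <- d[[paste0(ifelse(which_dive == "next", "next", "prev"),
                    "_dive_lunges")]]
  terms <- character(0)
  if ("duration" %in% predictors)
    terms <- c(terms, if (degree >= 2) "dd + I(dd^2)" else "dd")
  if ("lunges" %in% predictors)
    terms <- c(terms, if (degree >= 2 && length(unique(d$lc)) > 2)
      "lc + I(lc^2)" else "lc")
  re <- if (length(unique(d$species)) > 1)
    c("(1 | whale_id)", "(1 | species)") else "(1 | whale_id)"
  if (response == "total_inhalation_duration") {
    d$.y <- d$total_inhalation_duration_s
    fam <- stats::Gamma(link = "log"); famname <- "gamma"
  } else {
    d$.y <- d$breath_count
    fam <- stats::poisson(link = "log"); famname <- "poisson"
  }
  rf <- fit_glmm_robust(paste(".y ~", paste(terms, collapse = " + ")),
                        re, d, fam)
  as_model_fit(rf$fit, famname, "log",
               paste(c(paste0(response, " [", which_dive, " dive] ~ ",
                              paste(terms, collapse = " + ")), rf$re_terms),
                     collapse = " + "))
}

#' Compare the dive-effort model set by AIC
#'
#' Fits, for one response, the duration-only, lunge-only and combined
#' predictor models against both the previous and the upcoming dive, and
#' ranks them by AIC (lowest is best).
#'
#' @inheritParams fit_dive_effort_glmm
#' @return A list with `models` (named list of `model_fit`) and `table`
#'   (tibble: `model`, `which_dive`, `predictors`, `AIC`, `logLik`, sorted by
#'   AIC).
#' @export
dive_effort_model_comparison <- function(sequences,
                                         response = c("total_inhalation_duration",
                                                      "breath_count")) {
  response <- match.arg(response)
  specs <- list(
    prev_duration = list("prev", "duration"),
    prev_lunges = list("prev", "lunges"),
    prev_both = list("prev", c("duration", "lunges")),
    next_duration = list("next", "duration"),
    next_lunges = list("next", "lunges"),
    next_both = list("next", c("duration", "lunges")))
  models <- lapply(specs, function(sp)
    fit_dive_effort_glmm(sequences, response, sp[[1]], sp[[2]]))
  tab <- tibble::tibble(
    model = names(specs),
    which_dive = vapply(specs, function(sp) sp[[1]], character(1)),
    predictors = vapply(specs, function(sp)
      paste(sp[[2]], collapse = "+"), character(1)),
    AIC = vapply(models, function(m) m$AIC, numeric(1)),
    logLik = vapply(models, function(m) m$logLik, numeric(1)))
  tab <- dplyr::arrange(tab, .data$AIC)
  list(models = models, table = tab)
}

#' Paired two-sample t-test
#'
#' Classical paired t-test on the differences, used for the left-vs-right
#' nares comparison and the every-frame vs every-other-frame IA comparison.
#'
#' @param x,y Paired measurement vectors of equal length (>= 3).
#' @return A list with `t`, `df` (= n - 1), `p`, `mean_diff`.
#' @export
#' @examples
#' paired_t_test(rnorm(30), rnorm(30))$df  # 29
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0)
    stop("degenerate pairing: zero variance of differences", call. = FALSE)
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate))
}
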