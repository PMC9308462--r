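test_that("family mapping follows the metric", {
  tab <- generate_breath_table(n_whales = 4, breaths_per_whale = 30, seed = 111)
  f_dur <- fit_breath_metric_glmm(tab, "duration")
  expect_equal(f_dur$family, "gamma")
  expect_equal(f_dur$link, "log")
  f_ia <- fit_breath_metric_glmm(tab, "norm_IA")
  expect_equal(f_ia$family, "beta")
  expect_equal(f_ia$link, "logit")
  f_max <- fit_breath_metric_glmm(tab, "norm_max_area")
  expect_equal(f_max$family, "beta")
  expect_equal(f_max$n_obs, nrow(tab))
  expect_equal(unname(f_max$n_groups["whale_id"]), 4L)
})

test_that("Wald intervals reconstruct as estimate +/- 1.96 SE", {
  tab <- generate_breath_table(n_whales = 4, breaths_per_whale = 30, seed = 112)
  f <- fit_breath_metric_glmm(tab, "duration")
  co <- f$coefficients
  expect_equal(co$ci_lo, co$estimate - 1.96 * co$se, tolerance = 1e-6)
  expect_equal(co$ci_hi, co$estimate + 1.96 * co$se, tolerance = 1e-6)
  # AIC = 2k - 2 logLik for the fitted parameter count
  k <- attr(stats::logLik(f$fit), "df")
  expect_equal(f$AIC, 2 * k - 2 * f$logLik, tolerance = 1e-9)
})

test_that("input validation names the offending records", {
  tab <- generate_breath_table(n_whales = 3, breaths_per_whale = 20, seed = 113)
  bad <- tab
  bad$duration_s[5] <- -1
  expect_error(fit_breath_metric_glmm(bad, "duration"), bad$breath_id[5])
  bad2 <- tab
  bad2$norm_IA[7] <- 1.5
  expect_error(fit_breath_metric_glmm(bad2, "norm_IA"), bad2$breath_id[7])
  expect_error(fit_breath_metric_glmm(tab[tab$whale_id == tab$whale_id[1], ],
                                      "duration"), "2 whales")
})

test_that("contrasts flag the generator's effect pattern, not the null pair", {
  truth <- synthetic_truth(dur_mult = c(initial = 1, middle = 1, terminal = 2))
  null_flags <- 0
  for (seed in 114:116) {
    tab <- generate_breath_table(n_whales = 6, breaths_per_whale = 40,
                                 truth = truth, seed = seed)
    f <- fit_breath_metric_glmm(tab, "duration")
    ct <- pairwise_contrasts(f)
    expect_equal(nrow(ct), 3)
    expect_equal(unique(ct$alpha_adjusted), 0.05 / 3)
    # the doubled terminal duration must always be detected against both
    # other types
    expect_true(ct$significant[ct$contrast == "initial - terminal"])
    expect_true(ct$significant[ct$contrast == "middle - terminal"])
    # significance uses strict inequality against alpha / m
    expect_equal(ct$significant, ct$p < 0.05 / 3)
    null_flags <- null_flags +
      ct$significant[ct$contrast == "initial - middle"]
  }
  # the initial-middle pair carries no effect; with 6 whales the Wald test is
  # only approximately calibrated, so allow at most one spurious flag
  expect_lte(null_flags, 1)
})

test_that("identical group means flag nothing", {
  set.seed(115)
  tab <- tibble::tibble(
    whale_id = rep(sprintf("w%d", 1:4), each = 30),
    breath_id = sprintf("b%03d", 1:120),
    breath_type = rep(c("initial", "middle", "terminal"), 40),
    duration_s = rep(stats::rlnorm(40, log(0.6), 0.2), each = 3))
  f <- fit_breath_metric_glmm(tab, "duration")
  ct <- pairwise_contrasts(f)
  expect_false(any(ct$significant))
})

test_that("fixed effects agree with a plain GLM when the RE variance is 0", {
  set.seed(116)
  n <- 300
  tab <- tibble::tibble(
    whale_id = rep(sprintf("w%d", 1:5), each = n / 5),
    breath_id = sprintf("b%03d", 1:n),
    breath_type = sample(c("initial", "middle", "terminal"), n, TRUE),
    duration_s = stats::rgamma(n, shape = 20,
                               rate = 20 / 0.7))  # no whale, no type effect
  f <- fit_breath_metric_glmm(tab, "duration")
  g <- stats::glm(duration_s ~ factor(breath_type, levels = c(
    "initial", "middle", "terminal")), family = stats::Gamma("log"),
    data = tab)
  expect_lt(max(abs(f$coefficients$estimate - unname(stats::coef(g)))),
            2 * max(f$coefficients$se))
})

test_that("dive-effort models use the stated families and recover curvature", {
  # total inhalation duration generated as a quadratic (on the log scale) in
  # the upcoming dive duration, peaking at 5 minutes
  set.seed(117)
  n <- 180
  dd <- stats::runif(n, 1, 9)  # minutes
  peak <- 5
  eta <- log(40) + 0.12 * (-(dd - peak)^2)
  seqs <- tibble::tibble(
    sequence_id = sprintf("s%03d", 1:n),
    whale_id = rep(sprintf("%s_w%d", c("bb", "mn"), 1:6)[1:6], length.out = n),
    complete = TRUE,
    total_inhalation_duration_s = stats::rgamma(n, 25, 25 / exp(eta)),
    breath_count = stats::rpois(n, 8),
    next_dive_duration_s = dd * 60,
    next_dive_lunges = stats::rpois(n, 1.5),
    prev_dive_duration_s = stats::runif(n, 60, 540),
    prev_dive_lunges = stats::rpois(n, 1.5))
  f <- fit_dive_effort_glmm(seqs, "total_inhalation_duration", "next",
                            predictors = "duration")
  expect_equal(f$family, "gamma")
  co <- f$coefficients
  b1 <- co$estimate[co$term == "dd"]
  b2 <- co$estimate[co$term == "I(dd^2)"]
  expect_lt(b2, 0)
  expect_lt(abs(-b1 / (2 * b2) - peak) / peak, 0.15)

  fc <- fit_dive_effort_glmm(seqs, "breath_count", "next")
  expect_equal(fc$family, "poisson")

  # response independent of the previous dive -> no significant prev effect
  fp <- fit_dive_effort_glmm(seqs, "total_inhalation_duration", "prev",
                             predictors = "duration")
  expect_gt(min(fp$coefficients$p[fp$coefficients$term != "(Intercept)"]),
            0.01)
  expect_error(fit_dive_effort_glmm(seqs[1:5, ], "breath_count"),
               "at least 10")
})

test_that("AIC ordering is invariant to gamma response rescaling", {
  set.seed(118)
  n <- 120
  seqs <- tibble::tibble(
    sequence_id = sprintf("s%03d", 1:n),
    whale_id = rep(sprintf("bb_w%d", 1:4), length.out = n),
    complete = TRUE,
    total_inhalation_duration_s = stats::rgamma(n, 20, 2),
    breath_count = stats::rpois(n, 8),
    next_dive_duration_s = stats::runif(n, 60, 540),
    next_dive_lunges = stats::rpois(n, 1.5),
    prev_dive_duration_s = stats::runif(n, 60, 540),
    prev_dive_lunges = stats::rpois(n, 1.5))
  fit_pair <- function(d) c(
    fit_dive_effort_glmm(d, "total_inhalation_duration", "next",
                         predictors = "duration")$AIC,
    fit_dive_effort_glmm(d, "total_inhalation_duration", "next",
                         predictors = "lunges")$AIC)
  a <- fit_pair(seqs)
  seqs2 <- seqs
  seqs2$total_inhalation_duration_s <- seqs$total_inhalation_duration_s * 13
  b <- fit_pair(seqs2)
  expect_equal(order(a), order(b))
  expect_equal(diff(a), diff(b), tolerance = 1e-3)
})

test_that("paired t-test matches its classical definition and guards", {
  set.seed(119)
  x <- stats::rnorm(30)
  y <- x + stats::rnorm(30, 0, 0.5)
  r <- paired_t_test(x, y)
  expect_equal(r$df, 29)
  d <- x - y
  expect_equal(r$t, mean(d) / (stats::sd(d) / sqrt(30)), tolerance = 1e-12)

  expect_error(paired_t_test(1:4, 2:5), "degenerate")
  expect_error(paired_t_test(1:2, 1:2), "at least 3")
  expect_error(paired_t_test(1:4, 1:5), "paired")

  # null rejection rate is ~5%
  rej <- 0
  for (i in 1:1000) {
    x <- stats::rnorm(30); y <- x + stats::rnorm(30, 0, 1)
    if (paired_t_test(x, y)$p < 0.05) rej <- rej + 1
  }
  expect_gt(rej / 1000, 0.02)
  expect_lt(rej / 1000, 0.08)
})

test_that("area-duration model finds the positive relationship and species effect", {
  truth <- synthetic_truth()
  tab <- generate_breath_table(n_whales = 6, breaths_per_whale = 40,
                               truth = truth, seed = 120)
  f <- fit_area_duration_glmm(tab)
  co <- f$coefficients
  # longer breaths have larger multipliers for both area and duration, so the
  # slope on duration must be positive
  expect_gt(co$estimate[co$term == "duration_s"], 0)
  expect_lt(co$p[co$term == "duration_s"], 0.05)
  expect_true("speciesmn" %in% co$term)
})
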