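test_that("integrated area matches hand-computable cases", {
  s <- frame_area_series("b", "w", c(0, 0.5), c(0, 4))
  expect_equal(integrated_area(s), 1.0)

  # constant area over [0, 0.5] at 30 Hz is a rectangle at any stride (the
  # last frame is always retained, so the full span is covered)
  t <- (0:15) / 30
  r <- frame_area_series("r", "w", t, rep(10, length(t)))
  expect_equal(integrated_area(r, 1), 5.0)
  expect_equal(integrated_area(r, 2), 5.0)
  expect_equal(integrated_area(r, 3), 5.0)
})

test_that("integrated area equals the brute-force oracle on random series", {
  set.seed(91)
  for (i in 1:50) {
    s <- random_series(15)
    expect_equal(integrated_area(s), trapezoid_oracle(s$times, s$areas),
                 tolerance = 1e-12)
    # strided IA equals the oracle applied to the strided subsequence
    idx <- unique(c(seq(1, 15, by = 2), 15))
    expect_equal(integrated_area(s, 2),
                 trapezoid_oracle(s$times[idx], s$areas[idx]),
                 tolerance = 1e-12)
  }
})

test_that("max area and duration are simple scans over frames", {
  s <- generate_expansion_curve(1, 100, 0.5, noise_sd = 0)
  expect_equal(max_nares_area(s), 100)
  expect_equal(inhalation_duration(s), 1)

  ramp <- frame_area_series("m", "w", seq(0, 0.9, 0.1), seq(0, 90, 10))
  expect_equal(max_nares_area(ramp), 90)
  expect_equal(inhalation_duration(ramp), 0.9)

  set.seed(92)
  s <- random_series(20)
  expect_equal(max_nares_area(s), max(s$areas))
  # duration is unaffected by the IA stride (stride never drops endpoints here)
  expect_equal(inhalation_duration(s), s$times[20] - s$times[1])
})

test_that("IA respects its bounds and scale equivariance", {
  set.seed(93)
  for (i in 1:20) {
    s <- random_series(12)
    ia <- integrated_area(s)
    dur <- inhalation_duration(s)
    expect_gte(ia, min(s$areas) * dur - 1e-12)
    expect_lte(ia, max(s$areas) * dur + 1e-12)

    s2 <- frame_area_series(s$breath_id, s$whale_id, s$times, s$areas * 7)
    expect_equal(integrated_area(s2), 7 * ia, tolerance = 1e-12)
    expect_equal(max_nares_area(s2), 7 * max_nares_area(s))
  }
})

test_that("per-whale normalization maps each whale's maximum to 1", {
  expect_equal(normalize_per_whale(c(2, 4, 8), rep("w", 3)),
               c(0.25, 0.5, 1))
  v <- c(2, 4, 8, 30, 60)
  w <- c("a", "a", "a", "b", "b")
  out <- normalize_per_whale(v, w)
  expect_equal(out, c(0.25, 0.5, 1, 0.5, 1))

  # permutation invariance
  set.seed(94)
  p <- sample(5)
  expect_equal(normalize_per_whale(v[p], w[p]), out[p])

  # scale equivariance of inputs leaves normalized output unchanged
  expect_equal(normalize_per_whale(v * 3, w), out)
  expect_error(normalize_per_whale(c(0, 0), c("a", "a")), "no positive")
  expect_error(normalize_per_whale(c(-1, 2), c("a", "a")), "non-negative")
})

test_that("resolution difference is zero for rectangles, ~5%-scale for ramps", {
  t <- seq(0, 0.5, by = 1 / 30)
  const <- frame_area_series("c", "w", t, rep(10, length(t)))
  rd <- resolution_difference(list(const))
  expect_equal(rd$pct_diff, 0)

  # linear ramp with even sample count: differences equal recomputation
  ramp <- frame_area_series("r", "w", seq(0, 0.46, by = 1 / 30) + 0,
                            seq(10, 150, length.out = 14))
  rd2 <- resolution_difference(list(ramp))
  idx <- unique(c(seq(1, 14, by = 2), 14))
  ia2 <- trapezoid_oracle(ramp$times[idx], ramp$areas[idx])
  expect_equal(rd2$ia_b, ia2, tolerance = 1e-12)
  expect_equal(rd2$pct_diff, 100 * (rd2$ia_a - ia2) / ia2, tolerance = 1e-12)

  expect_error(resolution_difference(list(frame_area_series(
    "s", "w", c(0, 0.1, 0.2), c(1, 2, 1)))), "fewer than 4")
})

test_that("stride sensitivity stays within 10% on trapezoid fixtures", {
  set.seed(95)
  for (i in 1:20) {
    dur <- runif(1, 0.4, 1.5)
    s <- generate_expansion_curve(dur, runif(1, 50, 500), runif(1, 0.2, 0.7),
                                  noise_sd = 0)
    expect_gte(length(s$times), 10)
    ia1 <- integrated_area(s, 1)
    ia2 <- integrated_area(s, 2)
    expect_lte(abs(ia1 - ia2) / ia1, 0.10)
  }
})

test_that("normalized curves land on the unit square with type summaries", {
  s1 <- generate_expansion_curve(1.0, 100, 0.6, noise_sd = 0, breath_id = "a")
  s2 <- generate_expansion_curve(0.5, 60, 0.6, noise_sd = 0, breath_id = "b")
  nc <- normalized_curves(list(a = s1, b = s2),
                          breath_types = c(a = "terminal", b = "initial"))
  expect_equal(range(nc$curves$rel_time), c(0, 1))
  expect_equal(max(nc$curves$rel_area), 1)  # only the largest breath hits 1
  expect_equal(max(nc$curves$rel_area[nc$curves$breath_id == "b"]), 0.6)
  expect_equal(nrow(nc$curves), 2 * 101)

  # a single-breath type summary equals the breath's own resampled curve
  own <- nc$curves[nc$curves$breath_id == "a", ]
  smry <- nc$summary[nc$summary$breath_type == "terminal", ]
  expect_equal(smry$mean_rel_area, own$rel_area)

  # the plateau occupies ~ the plateau fraction of the breath's own span
  plateau_pts <- mean(own$rel_area >= 0.99 * max(own$rel_area))
  expect_equal(plateau_pts, 0.6, tolerance = 0.08)

  # identical breaths give zero pointwise variance
  nc2 <- normalized_curves(list(x = s1, y = s1),
                           breath_types = c(x = "middle", y = "middle"))
  spread <- nc2$curves |>
    dplyr::group_by(rel_time) |>
    dplyr::summarise(v = stats::var(rel_area))
  expect_true(all(spread$v < 1e-20))
})

test_that("metric table applies species strides and frame-count bookkeeping", {
  truth <- synthetic_truth(area_noise_sd = 0)
  dep_bb <- generate_deployment(truth, hours = 1, whale_id = "bb_m", seed = 96)
  dep_mn <- generate_deployment(truth, hours = 1, whale_id = "mn_m", seed = 97)
  frames <- c(dep_bb$frames, dep_mn$frames)
  tab <- breath_metric_table(frames, species = c(bb_m = "bb", mn_m = "mn"))
  expect_equal(nrow(tab), length(frames))
  expect_true(all(tab$duration_s > 0))
  expect_true(all(tab$ia_px_s <= tab$max_area_px * tab$duration_s + 1e-9))
  for (w in c("bb_m", "mn_m"))
    expect_equal(max(tab$norm_IA[tab$whale_id == w]), 1)
  # typical (initial/middle) breaths use 10-20 frames at the species stride
  expect_gte(median(tab$n_frames_used), 10)
  expect_lte(median(tab$n_frames_used), 20)
})
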