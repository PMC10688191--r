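test_that("build_dos normalizes, bins correctly and handles edge values", {
  d <- build_dos(rep(1.0, 50), n_bins = 10)
  expect_equal(sum(d$mass), 1, tolerance = 1e-12)
  expect_identical(sum(d$mass == 1), 1L)  # one bin carries all the mass
  # 50/50 two-delta series -> two bins with mass 0.5 each
  d2 <- build_dos(rep(c(1.6, 2.5), 100), n_bins = 90)
  expect_identical(sort(d2$mass[d2$mass > 0]), c(0.5, 0.5))
  # a value exactly at pi lands in the last bin, not out of range
  d3 <- build_dos(c(0, pi), n_bins = 9)
  expect_equal(d3$mass[c(1, 9)], c(0.5, 0.5))
  expect_error(build_dos(numeric(0)), "empty")
  expect_error(build_dos(1, n_bins = 1), "at least 2")
  # mixture mode masses track generator weights (Monte Carlo)
  set.seed(1)
  vals <- ifelse(stats::runif(10000) < 0.7, stats::rnorm(10000, 1.6, 0.05),
                 stats::rnorm(10000, 2.5, 0.05))
  dm <- build_dos(vals, 90)
  fm <- find_modes(smooth_dos(dm, 5))
  major_share <- fm$modes$mass[1] / sum(fm$modes$mass[1:2])
  expect_equal(major_share, 0.7, tolerance = 0.03)
})

test_that("smoothing preserves total mass and window=1 is the identity", {
  set.seed(2)
  d <- build_dos(stats::runif(500, 0.2, 3.0), 60)
  expect_identical(smooth_dos(d, 1), d)
  for (w in c(3, 5, 9)) {
    sm <- smooth_dos(d, w)
    expect_equal(sum(sm$mass), 1, tolerance = 1e-9)
  }
  # a delta spreads over `window` bins
  delta <- build_dos(rep(1.5, 10), 90)
  sm <- smooth_dos(delta, 5)
  expect_identical(sum(sm$mass > 1e-12), 5L)
  expect_error(smooth_dos(d, 4), "odd")
})

test_that("find_modes counts modes of unimodal/bimodal/trimodal densities", {
  cases <- list(
    list(mode = "unimodal", n = 1L),
    list(mode = "ss", n = 2L),
    list(mode = "us", n = 2L),
    list(mode = "intermediate", n = 3L))
  for (cs in cases) {
    g <- gen_angle_series(cs$mode, 4000, seed = 10)
    fm <- find_modes(smooth_dos(build_dos(g$series), 5))
    expect_identical(nrow(fm$modes), cs$n, info = cs$mode)
  }
  # mode locations sit at the generator means within one bin (pi/90)
  g <- gen_angle_series("us", 5000, centers = c(1.6, 2.5), seed = 4)
  fm <- find_modes(smooth_dos(build_dos(g$series), 5))
  locs <- sort(fm$modes$location[1:2])
  expect_lt(abs(locs[1] - 1.6), pi / 90)
  expect_lt(abs(locs[2] - 2.5), pi / 90)
  # modes sorted by height descending
  expect_true(all(diff(fm$modes$height) <= 0))
})

test_that("the 14-feature vector obeys its invariants and sentinels", {
  g2 <- gen_angle_series("us", 4000, seed = 5)
  f2 <- dos_features(build_dos(g2$series))
  expect_identical(names(f2), dos_feature_names())
  expect_length(f2, 14L)
  expect_true(all(is.finite(f2)))
  expect_identical(unname(f2["n_modes"]), 2)
  expect_true(f2[["height_ratio"]] >= 0 && f2[["height_ratio"]] <= 1)
  expect_true(f2[["valley_ratio"]] >= 0 && f2[["valley_ratio"]] <= 1)
  expect_true(f2[["minor_mass_fraction"]] >= 0 &&
              f2[["minor_mass_fraction"]] <= 0.5)
  expect_equal(f2[["mode_separation"]], 0.9, tolerance = 0.1)
  # unimodal sentinels
  g1 <- gen_angle_series("unimodal", 4000, seed = 6)
  f1 <- dos_features(build_dos(g1$series))
  expect_identical(unname(f1["n_modes"]), 1)
  expect_identical(unname(f1[c("mode_separation", "minor_height",
                               "minor_mass_fraction", "minor_fwhm")]),
                   rep(0, 4))
  # symmetric equal bimodal: height ratio ~1, minor mass ~0.5
  d <- build_dos(rep(c(1.6, 2.5), 2000), 90)
  fs <- dos_features(d)
  expect_equal(fs[["height_ratio"]], 1, tolerance = 1e-9)
  expect_equal(fs[["minor_mass_fraction"]], 0.5, tolerance = 1e-9)
  # variance/skewness track closed-form mixture moments
  w <- 0.5; mu <- c(1.6, 2.5); s <- 0.08
  mix_mean <- sum(mu) / 2
  mix_var <- s^2 + w * (mu[1] - mix_mean)^2 + w * (mu[2] - mix_mean)^2
  g <- gen_angle_series("us", 20000, switch_prob = 0.5, seed = 8)
  fg <- dos_features(build_dos(g$series))
  expect_equal(fg[["sample_variance"]], mix_var, tolerance = 0.05)
  expect_lt(abs(fg[["sample_skewness"]]), 0.1)  # symmetric mixture
})

test_that("features depend on the empirical distribution, not the frame count", {
  g <- gen_angle_series("us", 1500, seed = 12)
  f1 <- dos_features(build_dos(g$series$values))
  f3 <- dos_features(build_dos(rep(g$series$values, 3L)))
  expect_equal(f1, f3, tolerance = 1e-12)
})

test_that("heuristic labels agree with generator truth on clear margins", {
  modes <- c("unimodal", "ss", "us", "intermediate")
  n_ok <- 0L; n_all <- 0L
  for (i in 1:80) {
    m <- modes[(i %% 4L) + 1L]
    sd <- stats::runif(1, 0.05, 0.1)
    g <- gen_angle_series(m, 2500, centers = c(1.5, 1.5 + 6.5 * sd),
                          sds = sd, seed = 300 + i)
    lab <- heuristic_label(build_dos(g$series))
    n_all <- n_all + 1L
    n_ok <- n_ok + as.integer(lab == g$switch_label)
  }
  expect_gte(n_ok / n_all, 0.98)
  expect_identical(attr(heuristic_label(build_dos(rep(1.2, 10))), "source"),
                   "heuristic")
})
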