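const_profile <- function(D = 4, n_frames = 31L, fps = 30, len = 2.1) {
  fr <- seq_len(n_frames) - 1L
  flow_profile(pmin(sqrt(D * fr / fps), len), fps, channel_length_cm = len)
}

test_that("pointwise diffusion is constant on a single-regime profile", {
  ds <- pointwise_diffusion(const_profile(D = 4))
  expect_equal(ds$D_raw, rep(4, length(ds$D_raw)), tolerance = 1e-12)
  expect_equal(ds$D_value, rep(4, length(ds$D_value)), tolerance = 1e-12)
  expect_equal(ds$frame_index[1], 1)  # t = 0 excluded
  # direct substitution: L = 2 cm at t = 1 s (frame 30)
  expect_equal(ds$D_raw[ds$frame_index == 30], 4)
  expect_error(pointwise_diffusion(const_profile(n_frames = 9L), ma_window = 10),
               class = "capflow_window_error")
})

test_that("pointwise diffusion tracks a two-regime profile like brute-force L^2/t", {
  cfg <- synth_config(seed = 1, noise_sd_cm = 0, D_early = 0.12, D_late = 0.03,
                      crossover_frame = 50L, n_frames = 1000L)
  p <- gen_profile(cfg)
  ds <- pointwise_diffusion(p, ma_window = 10)
  brute <- p$distance_cm[-1]^2 / (p$frame_index[-1] / p$frame_rate)
  expect_equal(ds$D_raw, brute, tolerance = 1e-12)
  far <- ds$frame_index < 40 | ds$frame_index > 60
  expect_lt(max(abs(ds$D_value[far] / brute[far] - 1)), 0.10)
  expect_equal(ds$D_value[2], 0.12, tolerance = 1e-9)   # starts at the early level
  expect_lt(ds$D_value[length(ds$D_value)], 0.12 * 0.5) # decays toward the late level
})

test_that("fit_lw recovers D exactly on noiseless data, within 5% under noise", {
  f <- fit_lw(const_profile(D = 4))
  expect_equal(f$D_hat, 4, tolerance = 1e-12)
  expect_lt(f$rss, 1e-20)
  expect_equal(unname(coef(f)["D"]), f$D_hat)
  expect_equal(residuals(f), rep(0, f$n), tolerance = 1e-10)

  cfg <- synth_config(seed = 11, D_early = 0.09, D_late = 0.09,
                      noise_sd_cm = 0.01, n_frames = 300L)
  fn <- fit_lw(gen_profile(cfg), window = c(1, 299))
  expect_lt(abs(fn$D_hat / 0.09 - 1), 0.05)

  # sqrt and linearized objectives agree on noiseless data
  expect_equal(fit_lw(const_profile(), method = "linearized")$D_hat,
               fit_lw(const_profile(), method = "sqrt")$D_hat, tolerance = 1e-9)

  expect_error(fit_lw(const_profile(), window = c(100, 200)),
               class = "capflow_window_error")
  zeros <- flow_profile(rep(0, 50), 30)
  expect_error(fit_lw(zeros), class = "capflow_degenerate_fit")
})

test_that("fit_lw is scale-consistent: scaling L by c scales D_hat by c^2", {
  cfg <- synth_config(seed = 3, D_early = 0.08, D_late = 0.02, n_frames = 200L)
  p <- gen_profile(cfg)
  f1 <- fit_lw(p)
  p2 <- p
  p2$distance_cm <- p$distance_cm / 2   # shrink to stay within channel bounds
  f2 <- fit_lw(p2)
  expect_equal(f2$D_hat, f1$D_hat / 4, tolerance = 1e-10)
})

test_that("early windows of two-regime profiles fit a higher D than all frames", {
  cfg <- synth_config(seed = 2, noise_sd_cm = 0)
  p <- gen_profile(cfg)
  cw <- compare_windows(p, list(c(1, 50), c(1, 1499)))
  expect_gt(cw$ratio[1, 2], 1)
  expect_equal(cw$fits[[1]]$D_hat, cfg$D_early, tolerance = 1e-9)

  # single regime: window choice is immaterial
  pc <- const_profile(D = 0.05, n_frames = 1001L)
  cwc <- compare_windows(pc, list(c(1, 50), c(1, 1000)))
  expect_equal(cwc$ratio[1, 2], 1, tolerance = 1e-9)

  single <- compare_windows(pc, list(c(1, 50)))
  expect_identical(dim(single$ratio), c(1L, 1L))
  expect_equal(single$ratio[1, 1], 1)
})

test_that("halfway detection frame is half the crossover frame", {
  cfg <- synth_config(seed = 1, noise_sd_cm = 0)
  profs <- lapply(c(0.6, 0.8, 1), function(s) gen_profile(cfg, D_early = cfg$D_early * s))
  expect_identical(select_detection_frame(profs, "halfway"), 25L)

  # other crossover frames scale accordingly
  cfg80 <- synth_config(seed = 1, noise_sd_cm = 0, crossover_frame = 80L)
  expect_identical(select_detection_frame(list(gen_profile(cfg80)), "halfway"), 40L)

  # under the default distance noise the answer stays inside the early regime
  cfgn <- synth_config(seed = 8)
  noisy <- lapply(1:8, function(i) gen_profile(cfgn, seed = 800 + i))
  got <- select_detection_frame(noisy, "halfway")
  expect_lte(abs(got - 25L), 2L)
  expect_lt(got, cfgn$crossover_frame)
})

test_that("degenerate flat series fall back to the default frame with a warning", {
  pc <- const_profile(D = 0.05, n_frames = 200L)
  expect_warning(got <- select_detection_frame(list(pc), "halfway", default_frame = 25L),
                 class = "capflow_no_crossover")
  expect_identical(got, 25L)
})

test_that("max_separation picks the frame where groups differ most", {
  base <- sqrt(0.09 * (0:99) / 30)
  bump <- base
  bump[21:31] <- bump[21:31] + 0.05   # frames 20..30 differ between groups
  mk <- function(L, eps) flow_profile(pmin(pmax(L + eps, 0), 2.1), 30)
  ga <- lapply(c(-0.001, 0, 0.001), function(e) mk(base, e))
  gb <- lapply(c(-0.001, 0, 0.001), function(e) mk(bump, e))
  got <- select_detection_frame(list(a = ga, b = gb), "max_separation")
  expect_gte(got, 20L)
  expect_lte(got, 30L)
  expect_error(select_detection_frame(list(a = ga), "max_separation"),
               class = "capflow_domain_error")
})

test_that("diffusion_from_physics implements R*gamma*cos(theta)/(2 mu)", {
  expect_equal(diffusion_from_physics(physical_params(2, 3, 0, 1.5)), 2)
  expect_lt(diffusion_from_physics(physical_params(1, 1, 90, 1)), 1e-15)
  expect_warning(d <- diffusion_from_physics(physical_params(1, 1, 120, 1)),
                 class = "capflow_nonwetting")
  expect_identical(d, 0)
  # linear in gamma, monotone in R, decreasing in mu
  d1 <- diffusion_from_physics(physical_params(1, 2, 30, 1))
  expect_equal(diffusion_from_physics(physical_params(1, 4, 30, 1)), 2 * d1)
  expect_gt(diffusion_from_physics(physical_params(2, 2, 30, 1)), d1)
  expect_lt(diffusion_from_physics(physical_params(1, 2, 30, 2)), d1)
  expect_error(physical_params(-1, 1, 0, 1), class = "capflow_domain_error")
})

test_that("pointwise plateau and fit_lw agree on single-regime data", {
  p <- const_profile(D = 0.06, n_frames = 400L)
  ds <- pointwise_diffusion(p)
  plateau <- median(ds$D_value[ds$frame_index > 100])
  expect_lt(abs(plateau / fit_lw(p)$D_hat - 1), 0.02)
})
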