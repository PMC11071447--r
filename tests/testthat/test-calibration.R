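test_that("welch_t_test matches the textbook Welch-Satterthwaite formulas", {
  a <- c(2.1, 2.3, 1.9, 2.2)
  b <- c(2.8, 3.1, 2.9, 3.3)
  w <- welch_t_test(a, b)
  # independent recomputation from first principles
  se2a <- var(a) / length(a); se2b <- var(b) / length(b)
  t_ref <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
  df_ref <- (se2a + se2b)^2 /
    (se2a^2 / (length(a) - 1) + se2b^2 / (length(b) - 1))
  p_ref <- 2 * pt(-abs(t_ref), df_ref)
  expect_equal(w$statistic, t_ref, tolerance = 1e-10)
  expect_equal(w$df, df_ref, tolerance = 1e-10)
  expect_equal(w$p_value, p_ref, tolerance = 1e-10)
})

test_that("welch_t_test handles identical, shifted and degenerate samples", {
  x <- c(1, 2, 3, 4)
  same <- welch_t_test(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_lt(welch_t_test(x, x + 10)$p_value, 0.001)
  const <- welch_t_test(c(1, 1, 1), c(2, 2, 2))
  expect_true(const$degenerate)
  expect_equal(const$p_value, 0)
  expect_equal(welch_t_test(c(1, 1), c(1, 1))$p_value, 1)
  expect_error(welch_t_test(1, c(1, 2)), class = "capflow_domain_error")
})

test_that("find_lod returns the lowest significantly different concentration", {
  dr <- capflow:::with_seed(21, make_effect_dr(c_star = 10))
  expect_equal(as.numeric(find_lod(dr)), 10)
  # effect only at the top concentration
  dr_top <- capflow:::with_seed(22, make_effect_dr(c_star = 500))
  expect_equal(as.numeric(find_lod(dr_top)), 500)
  # pure null: every level drawn from the control distribution
  dr_null <- capflow:::with_seed(24, make_effect_dr(c_star = Inf))
  expect_true(is.na(find_lod(dr_null)))
  # control is mandatory
  no_ctrl <- dose_response(c(5, 10), list(rnorm(4), rnorm(4)))
  expect_error(find_lod(no_ctrl), class = "capflow_contract_error")
})

test_that("4PL parameters are recovered to numerical precision on noiseless data", {
  true <- list(A = 0.22, B = 0.30, xmid = log10(15), scal = 0.35)
  fit <- fit_sigmoid(make_4pl_dr(A = true$A, B = true$B, xmid = true$xmid,
                                 scal = true$scal))
  expect_equal(fit$model, "4PL sigmoid")
  expect_equal(fit$direction, "increasing")
  ref <- c(lower = true$A, upper = true$B, ec50 = 10^true$xmid,
           slope = 1 / true$scal)
  expect_lt(max(abs(fit$params - ref) / abs(ref)), 1e-6)
  # predict inverts through the calibration span
  expect_equal(capflow:::invert_calibration(fit, predict(fit, 12)), 12,
               tolerance = 1e-6)
})

test_that("fit_sigmoid recovers ec50 within 15% from 2% noise at n = 8", {
  fit <- fit_sigmoid(make_4pl_dr(n = 8, noise_sd = 0.005, seed = 9))
  expect_equal(fit$model, "4PL sigmoid")
  expect_lt(abs(fit$params[["ec50"]] / 15 - 1), 0.15)
})

test_that("flat and decreasing responses take the fallback/direction paths", {
  flat <- dose_response(c(0, 1, 5, 10, 20), lapply(1:5, function(i) rep(0.25, 3)))
  f <- suppressWarnings(fit_sigmoid(flat))
  expect_true(f$fallback)
  expect_equal(f$model, "linear")
  expect_lt(abs(f$params[["slope"]]), 1e-10)

  dec <- fit_sigmoid(make_4pl_dr(decreasing = TRUE))
  expect_equal(dec$direction, "decreasing")
})

test_that("linear_range matches exhaustive enumeration and excludes the hook limb", {
  # independent brute-force oracle over all contiguous windows
  oracle <- function(conc, means, r2_min = 0.75, min_points = 3) {
    best <- NULL
    n <- length(conc)
    for (i in 1:(n - min_points + 1)) for (j in (i + min_points - 1):n) {
      f <- lm(means[i:j] ~ conc[i:j])
      tss <- sum((means[i:j] - mean(means[i:j]))^2)
      r2 <- if (tss > 0) 1 - sum(residuals(f)^2) / tss else 1
      if (r2 < r2_min) next
      w <- j - i + 1
      if (is.null(best) || w > best$w || (w == best$w && r2 > best$r2))
        best <- list(w = w, r2 = r2, range = c(conc[i], conc[j]))
    }
    best
  }

  lin_conc <- c(0, 5, 10, 20, 40)
  lin <- dose_response(lin_conc, lapply(0.2 + 0.002 * lin_conc, function(m) c(m, m)))
  lr <- linear_range(lin)
  expect_equal(lr$range, c(0, 40))
  expect_equal(lr$r2, 1)

  hook_conc <- c(0, 1, 5, 10, 20, 30, 40, 100, 500)
  hook_means <- c(0.22, 0.225, 0.24, 0.255, 0.27, 0.285, 0.30, 0.27, 0.23)
  hook <- dose_response(hook_conc, lapply(hook_means, function(m) c(m - 1e-3, m + 1e-3)))
  lr2 <- linear_range(hook)
  ref <- oracle(hook_conc, hook_means)
  expect_equal(lr2$range, ref$range)
  expect_equal(lr2$r2, ref$r2, tolerance = 1e-12)
  expect_lte(lr2$range[2], 40)   # post-peak limb excluded

  set.seed(5)
  for (rep in 1:5) {
    mc <- sort(sample(0:100, 7))
    my <- cumsum(rnorm(7, 0.01, 0.01))
    drr <- dose_response(mc, lapply(my, function(m) c(m, m)))
    got <- suppressWarnings(linear_range(drr))
    ref <- oracle(mc, my)
    if (is.null(ref)) expect_null(got) else expect_equal(got$range, ref$range)
  }

  expect_error(linear_range(dose_response(c(0, 5), list(c(1, 1), c(2, 2)))),
               class = "capflow_contract_error")
})

test_that("tier classification inverts the calibration with the documented tie rule", {
  fit <- fit_sigmoid(make_4pl_dr())
  cuts <- c(10, 50)
  expect_equal(classify_tier(predict(fit, 5), fit, cuts)$label, "low")
  expect_equal(classify_tier(predict(fit, 20), fit, cuts)$label, "middle")
  expect_equal(classify_tier(predict(fit, 80), fit, cuts)$label, "high")
  # a signal exactly at a cut goes to the higher tier
  expect_equal(classify_tier(predict(fit, 10), fit, cuts)$label, "middle")
  # decreasing calibration: a high signal maps to a low concentration
  dec <- fit_sigmoid(make_4pl_dr(decreasing = TRUE))
  hi_sig <- predict(dec, 1)
  expect_equal(classify_tier(hi_sig, dec, cuts)$label, "low")
  # extrapolation is flagged
  out <- classify_tier(predict(fit, 100) + 0.05, fit, cuts)
  expect_true(out$extrapolated)
})

test_that("dilution arithmetic reproduces the printed diluted/undiluted pairs", {
  to_und <- function(v, f) convert_dilution(v, f, "to_undiluted", unit = "pg/mL")
  p1 <- to_und(50, 0.01);  expect_equal(p1$value, 5);   expect_equal(p1$unit, "ng/mL")
  p2 <- to_und(50, 0.001); expect_equal(p2$value, 50);  expect_equal(p2$unit, "ng/mL")
  p3 <- to_und(20, 0.1);   expect_equal(p3$value, 0.2); expect_equal(p3$unit, "ng/mL")
  p4 <- to_und(1, 0.01);   expect_equal(p4$value, 0.1); expect_equal(p4$unit, "ng/mL")
  p5 <- convert_dilution(2, 1e-4, "to_diluted", unit = "ng/mL")
  expect_equal(p5$value, 0.2); expect_equal(p5$unit, "pg/mL")
})

test_that("dilution conversion is an identity round trip", {
  expect_equal(convert_dilution(7, 1, "to_undiluted"), 7)
  expect_equal(convert_dilution(7, 1, "to_diluted"), 7)
  for (f in c(1, 0.5, 0.1, 0.01, 1e-4)) {
    up <- convert_dilution(13, f, "to_undiluted", unit = "pg/mL")
    back <- convert_dilution(up, f, "to_diluted")
    expect_equal(back$value, 13)
    expect_equal(back$unit, "pg/mL")
  }
  expect_error(convert_dilution(1, 0, "to_diluted"), class = "capflow_domain_error")
  expect_error(convert_dilution(1, 1.5, "to_diluted"), class = "capflow_domain_error")
})

test_that("group comparisons flag exactly the separated pairs", {
  g <- capflow:::with_seed(32, list(low = rnorm(8, 0, 0.01),
                                    mid = rnorm(8, 0, 0.01),
                                    high = rnorm(8, 0.1, 0.01)))
  gc <- group_comparison(g)
  expect_equal(nrow(gc), 3)
  sig <- gc$significant
  names(sig) <- paste(gc$group1, gc$group2, sep = "-")
  expect_false(sig[["low-mid"]])
  expect_true(sig[["low-high"]])
  expect_true(sig[["mid-high"]])

  far <- list(a = rnorm(6, 0, 0.01), b = rnorm(6, 10, 0.01), c = rnorm(6, 20, 0.01))
  expect_true(all(group_comparison(far)$significant))
})

test_that("pairwise Welch comparisons keep their nominal type-I rate", {
  # three null groups, 400 seeded repetitions: each pair should reject at
  # roughly alpha = 0.05
  reps <- 400
  hits <- matrix(0, reps, 3)
  capflow:::with_seed(77, {
    for (r in seq_len(reps)) {
      g <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8))
      hits[r, ] <- group_comparison(g)$significant
    }
  })
  rate <- colMeans(hits)
  expect_true(all(rate > 0.02 & rate < 0.09))
})
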