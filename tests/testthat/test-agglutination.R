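test_that("derivatives implement the printed mass-action equations", {
  k <- paper_k()
  zero <- agg_derivatives(c(abp = 0, ag = 0, abp_ag = 0, abp2_ag = 0, abp_ag2 = 0), k)
  expect_equal(unname(zero), rep(0, 5))

  d <- agg_derivatives(c(abp = 1, ag = 1, abp_ag = 0, abp2_ag = 0, abp_ag2 = 0), k)
  expect_equal(d[["abp_ag"]], 6)
  expect_equal(d[["abp"]], -6)
  expect_equal(d[["ag"]], -6)
  expect_equal(d[["abp2_ag"]], 0)
  expect_equal(d[["abp_ag2"]], 0)

  # with no free antigen and no monovalent complex, only koff2 dissociation acts
  d2 <- agg_derivatives(c(abp = 1, ag = 0, abp_ag = 0, abp2_ag = 2, abp_ag2 = 0), k)
  expect_equal(d2[["abp2_ag"]], -0.05 * 2)
  expect_equal(d2[["abp_ag"]], 0.05 * 2)
  expect_equal(d2[["abp"]], 0.05 * 2)
  expect_equal(d2[["ag"]], 0)

  # generic state: R-side oracle recomputation of all five equations
  s <- c(abp = 0.7, ag = 1.3, abp_ag = 0.4, abp2_ag = 0.2, abp_ag2 = 0.1)
  with(as.list(s), {
    v1 <- 6 * abp * ag; r1 <- 0.1 * abp_ag
    v2 <- 1 * abp * abp_ag; r2 <- 0.05 * abp2_ag
    v3 <- 2 * abp_ag * ag
    expect_equal(unname(agg_derivatives(s, k)),
                 c(-v1 + r1 - v2 + r2, -v1 + r1 - v3,
                   v1 - r1 - v2 + r2 - v3, v2 - r2, v3))
  })
})

test_that("both conservation laws hold along random-parameter trajectories", {
  set.seed(101)
  for (p in sample_kinetic_params(20)) {
    tr <- simulate_kinetics(p, t_end = 5, n_steps = 100)
    expect_lt(max(conservation_drift(tr)), 1e-6)
    expect_true(all(tr$states >= 0))
  }
})

test_that("the reduced bimolecular system reaches its closed-form equilibrium", {
  # kon2 = kon3 = 0 leaves Abp + Ag <-> Abp.Ag; at equilibrium
  # [Abp][Ag]/[Abp.Ag] = koff1/kon1
  p <- kinetic_params(kon1 = 6, koff1 = 0.1, kon2 = 0, koff2 = 0, kon3 = 0,
                      abp0 = 1, ag0 = 2)
  tr <- simulate_kinetics(p, t_end = 50)
  s <- tr$states[nrow(tr$states), ]
  Kd <- s[["abp"]] * s[["ag"]] / s[["abp_ag"]]
  expect_lt(abs(Kd / (0.1 / 6) - 1), 1e-4)
  # and the independent quadratic closed form for the bound fraction
  Keq <- 0.1 / 6
  b <- 1 + 2 + Keq
  c_eq <- (b - sqrt(b^2 - 4 * 1 * 2)) / 2
  expect_equal(s[["abp_ag"]], c_eq, tolerance = 1e-4)
})

test_that("tightening solver tolerances changes the agglutination level negligibly", {
  p <- paper_k()
  a <- simulate_kinetics(p, t_end = 1, rtol = 1e-8, atol = 1e-10)
  b <- simulate_kinetics(p, t_end = 1, rtol = 1e-10, atol = 1e-12)
  na <- nrow(a$states)
  expect_lt(abs(a$states[na, "abp2_ag"] / b$states[na, "abp2_ag"] - 1), 1e-5)
})

test_that("no antigen means no binding", {
  tr <- simulate_kinetics(kinetic_params(ag0 = 0), t_end = 1)
  expect_equal(unname(tr$states[, "abp"]), rep(10, nrow(tr$states)))
  expect_true(all(tr$states[, c("abp_ag", "abp2_ag", "abp_ag2")] == 0))
})

test_that("with the reference constants, agglutination levels off by t = 1", {
  tr <- simulate_kinetics(paper_k(), t_end = 1, n_steps = 400)
  a2 <- tr$states[, "abp2_ag"]
  expect_true(all(diff(a2) > -1e-9))
  rate <- diff(a2) / diff(tr$times)
  expect_lt(rate[length(rate)], 0.05 * max(rate))
})

test_that("the dose curve rises, saturates and hooks in antigen excess", {
  grid <- log_grid()
  dc <- dose_curve(paper_k(), grid)
  pk <- find_hook_peak(dc)
  expect_true(pk$interior)
  expect_lt(dc$norm_agg[length(grid)], pk$peak_value)
  # unimodal: non-decreasing up to the peak, non-increasing after
  i <- pk$index
  expect_true(all(diff(dc$norm_agg[1:i]) >= -1e-12))
  expect_true(all(diff(dc$norm_agg[i:length(grid)]) <= 1e-12))
  # zero antigen gives zero agglutination
  dc0 <- dose_curve(paper_k(), c(0, 1))
  expect_equal(dc0$norm_agg[1], 0)
})

test_that("more particles shift the hook peak to higher antigen", {
  grid <- log_grid(n = 30)
  p5 <- find_hook_peak(dose_curve(paper_k(abp0 = 5), grid))
  p10 <- find_hook_peak(dose_curve(paper_k(abp0 = 10), grid))
  expect_gt(p10$ag_at_peak, p5$ag_at_peak)
})

test_that("find_hook_peak flags monotone curves and locates constructed peaks", {
  inc <- list(ag0 = 1:6, norm_agg = (1:6) / 10)
  expect_warning(pk <- find_hook_peak(inc), class = "capflow_no_interior_peak")
  expect_false(pk$interior)
  uni <- list(ag0 = 1:7, norm_agg = c(0.1, 0.3, 0.45, 0.5, 0.4, 0.2, 0.1))
  expect_equal(find_hook_peak(uni)$index, 4)
  # tie broken toward the lower antigen level
  tie <- list(ag0 = 1:5, norm_agg = c(0.1, 0.5, 0.5, 0.3, 0.1))
  expect_equal(find_hook_peak(tie)$index, 2)
})

test_that("the coarse-grid hook peak agrees with a 10x denser re-simulation", {
  coarse_grid <- log_grid(lo = 0.1, hi = 100, n = 15)
  pk <- find_hook_peak(dose_curve(paper_k(), coarse_grid))
  i <- pk$index
  dense_grid <- 10^seq(log10(coarse_grid[i - 1]), log10(coarse_grid[i + 1]),
                       length.out = 21)
  pk_dense <- find_hook_peak(dose_curve(paper_k(), dense_grid))
  # within one coarse grid step on the log axis
  step <- log10(coarse_grid[2] / coarse_grid[1])
  expect_lt(abs(log10(pk_dense$ag_at_peak / pk$ag_at_peak)), step + 1e-9)
})

test_that("low- and high-particle dose curves cross", {
  grid <- log_grid(n = 30)
  c5 <- dose_curve(paper_k(abp0 = 5), grid)
  c10 <- dose_curve(paper_k(abp0 = 10), grid)
  cr <- find_crossing(c5, c10)
  expect_true(cr$crossing)
  expect_gt(cr$ag_cross, min(grid))
  expect_lt(cr$ag_cross, max(grid))
  # below the crossing the fewer-particle curve is higher, above it lower
  expect_gt(c5$norm_agg[1] - c10$norm_agg[1], 0)
  expect_lt(c5$norm_agg[30] - c10$norm_agg[30], 0)
})

test_that("find_crossing handles degenerate and constructed cases", {
  a <- list(ag0 = 1:6, norm_agg = c(0.1, 0.2, 0.3, 0.35, 0.38, 0.4))
  expect_warning(cr <- find_crossing(a, a), class = "capflow_degenerate_crossing")
  expect_true(cr$degenerate)
  expect_equal(cr$ag_cross, 1)

  b <- a
  b$norm_agg <- a$norm_agg + c(-0.05, -0.03, -0.01, 0.01, 0.03, 0.05)
  cr2 <- find_crossing(a, b)  # sign change between grid indices 3 and 4
  expect_gt(cr2$ag_cross, a$ag0[3])
  expect_lt(cr2$ag_cross, a$ag0[4])
  expect_equal(cr2$ag_cross, 3.5)  # symmetric differences -> midpoint

  up <- list(ag0 = 1:6, norm_agg = a$norm_agg + 0.1)
  expect_warning(cr3 <- find_crossing(a, up), class = "capflow_no_crossing")
  expect_false(cr3$crossing)
})

test_that("invalid kinetic inputs are rejected", {
  expect_error(kinetic_params(kon1 = -1), class = "capflow_domain_error")
  expect_error(kinetic_params(abp0 = 0), class = "capflow_domain_error")
  expect_error(simulate_kinetics(paper_k(), t_end = 0), class = "capflow_domain_error")
  expect_error(dose_curve(paper_k(), c(5, 1)), class = "capflow_domain_error")
})
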