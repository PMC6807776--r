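test_that("resin N standardization blank-corrects and floors at zero", {
  expect_equal(resin_n_per_area(10, 5, 5), 3)
  expect_equal(resin_n_per_area(10, 5, 5, blank_nh4 = 20), 1)
  expect_equal(resin_n_per_area(10, 5, 10), 1.5)
  expect_error(resin_n_per_area(1, 1, 0))
})

test_that("distance to shrubland follows cell-edge geometry", {
  m <- binary_class_map(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2), res = 5)
  # true cell is (row 1, col 1): x in [0,5], y in [5,10]
  inside <- distance_to_shrubland(data.frame(x = 2.5, y = 7.5), m)
  expect_equal(inside$distance_m, 0)
  expect_true(inside$inside)
  # one cell-width east of the edge: 12.5 - 5 = 7.5 m; center-to-edge 2.5 m
  # for the adjacent cell center
  expect_equal(distance_to_shrubland(data.frame(x = 7.5, y = 7.5),
                                     m)$distance_m, 2.5)
  expect_equal(distance_to_shrubland(data.frame(x = 12.5, y = 7.5),
                                     m)$distance_m, 7.5)
  # corner distance is Euclidean
  expect_equal(distance_to_shrubland(data.frame(x = 8, y = 2), m)$distance_m,
               sqrt(3^2 + 3^2))
  empty <- binary_class_map(matrix(FALSE, 2, 2), res = 5)
  expect_error(distance_to_shrubland(data.frame(x = 1, y = 1), empty),
               "no shrubland")
})

test_that("distance is invariant under joint translation of map and points", {
  set.seed(2)
  vals <- matrix(runif(100) < 0.2, 10, 10)
  vals[1, 1] <- TRUE
  m0 <- binary_class_map(vals, res = 5, xll = 0, yll = 0)
  m1 <- binary_class_map(vals, res = 5, xll = 137, yll = -42)
  pts <- data.frame(x = runif(10, -20, 70), y = runif(10, -20, 70))
  shifted <- data.frame(x = pts$x + 137, y = pts$y - 42)
  expect_equal(distance_to_shrubland(pts, m0)$distance_m,
               distance_to_shrubland(shifted, m1)$distance_m)
})

test_that("distance agrees with a segment-geometry oracle on random maps", {
  set.seed(31)
  for (i in 1:15) {
    nr <- sample(3:50, 1); nc <- sample(3:50, 1)
    vals <- matrix(runif(nr * nc) < runif(1, 0.02, 0.3), nr, nc)
    if (!any(vals)) vals[sample(nr, 1), sample(nc, 1)] <- TRUE
    m <- binary_class_map(vals, res = runif(1, 1, 10),
                          xll = runif(1, -50, 50), yll = runif(1, -50, 50))
    pts <- data.frame(
      x = runif(6, m$xll - 20, m$xll + nc * m$res + 20),
      y = runif(6, m$yll - 20, m$yll + nr * m$res + 20))
    got <- distance_to_shrubland(pts, m)$distance_m
    want <- vapply(seq_len(nrow(pts)), function(j)
      oracle_distance_to_map(pts$x[j], pts$y[j], m), numeric(1))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("noiseless seasonal data are recovered exactly by both engines", {
  cfg <- scenario_config(seed = 4)
  tr <- gen_resin_transect(cfg, noise_sd = 0)
  for (eng in c("lm", "profile")) {
    f <- fit_negative_exponential(tr$records, "seasonal_A_shared_b",
                                  engine = eng)
    expect_equal(f$params$A_winter, 33.84, tolerance = 1e-6)
    expect_equal(f$params$A_summer, 1.73, tolerance = 1e-6)
    expect_equal(f$params$b, 0.22, tolerance = 1e-6)
    expect_lt(f$sigma, 1e-6)
  }
})

test_that("flat data give a near-zero extinction coefficient", {
  d <- data.frame(distance_m = rep(seq(0, 50, length.out = 20), 2),
                  season = rep(c("winter", "summer"), each = 20),
                  resin_n = 7)
  f <- fit_negative_exponential(d, "seasonal_A_shared_b")
  expect_equal(f$params$b, 0, tolerance = 1e-6)
  expect_equal(f$params$A_winter, 7, tolerance = 1e-4)
})

test_that("fitted curve is the intercept at d = 0 and decays monotonically", {
  cfg <- scenario_config(seed = 8)
  f <- fit_negative_exponential(gen_resin_transect(cfg)$records)
  d_grid <- seq(0, 100, by = 1)
  curve_w <- f$params$A_winter * exp(-f$params$b * d_grid)
  expect_equal(curve_w[1], f$params$A_winter)
  if (f$params$b > 0) expect_true(all(diff(curve_w) < 0))
  expect_lt(curve_w[length(curve_w)], curve_w[1])
})

test_that("single-season fit equals the shared model on duplicated data", {
  cfg <- scenario_config(seed = 12)
  tr <- gen_resin_transect(cfg)$records
  win <- tr[tr$season == "winter", ]
  dup <- win
  dup$season <- "summer"
  both <- rbind(win, dup)
  f_shared <- fit_negative_exponential(both, "seasonal_A_shared_b")
  f_single <- fit_negative_exponential(win, "shared_A_shared_b")
  expect_equal(f_shared$params$A_winter, f_single$params$A,
               tolerance = 1e-6)
  expect_equal(f_shared$params$A_summer, f_single$params$A,
               tolerance = 1e-6)
  expect_equal(f_shared$params$b, f_single$params$b, tolerance = 1e-6)
})

test_that("model comparison runs LRTs on nested fits and reports AIC", {
  cfg <- scenario_config(seed = 21)
  d <- gen_resin_transect(cfg)$records
  fits <- lapply(c("shared_A_shared_b", "seasonal_A_shared_b",
                   "seasonal_A_seasonal_b"),
                 function(v) fit_negative_exponential(d, v))
  cmp <- compare_models(fits)
  expect_true(cmp$selected %in% cmp$table$variant)
  # maximized likelihood is monotone in nesting
  expect_true(all(diff(cmp$table$logLik) >= -1e-8))
  expect_true(all(cmp$tests$p_value >= 0 & cmp$tests$p_value <= 1))
  # identical data but different objects: fits to different data are rejected
  d2 <- d; d2$resin_n <- d2$resin_n + 1
  f_other <- fit_negative_exponential(d2, "shared_A_shared_b")
  expect_error(compare_models(fits[[2]], f_other), "identical data")
})

test_that("the generating variant is selected in most seasonal-A datasets", {
  cfg <- scenario_config(seed = 2)
  wins <- vapply(1:100, function(s) {
    d <- gen_resin_transect(cfg, seed = 400 + s)$records
    fits <- lapply(c("shared_A_shared_b", "seasonal_A_shared_b",
                     "seasonal_A_seasonal_b"),
                   function(v) fit_negative_exponential(d, v,
                                                        engine = "profile"))
    compare_models(fits)$selected == "seasonal_A_shared_b"
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("bootstrap CIs are reproducible and degenerate without noise", {
  cfg <- scenario_config(seed = 4)
  noiseless <- gen_resin_transect(cfg, noise_sd = 0)$records
  b0 <- bootstrap_ci(noiseless, n_iter = 50, seed = 9)
  expect_lt(b0$ci["upper", "b"] - b0$ci["lower", "b"], 1e-6)
  noisy <- gen_resin_transect(cfg)$records
  b1 <- bootstrap_ci(noisy, n_iter = 100, seed = 7)
  b2 <- bootstrap_ci(noisy, n_iter = 100, seed = 7)
  expect_identical(b1$ci, b2$ci)
  expect_true(b1$ci["lower", "b"] <= b1$point$params$b)
  expect_true(b1$ci["upper", "b"] >= b1$point$params$b)
  # residual scheme also runs and brackets the point estimate
  br <- bootstrap_ci(noisy, n_iter = 100, seed = 7, scheme = "residual")
  expect_true(br$ci["lower", "b"] <= br$point$params$b + 1e-8)
})

test_that("median relative error of b-hat matches its asymptotic prediction", {
  cfg <- scenario_config(seed = 3)
  errs <- vapply(1:100, function(s) {
    sim <- gen_resin_transect(cfg, seed = 700 + s)
    f <- fit_negative_exponential(sim$records, engine = "profile")
    abs(f$params$b - sim$truth$b) / sim$truth$b
  }, numeric(1))
  # asymptotic prediction: with the noise SDs calibrated to the reported CI
  # widths, SE(b) at this design is ~0.074, so the median absolute relative
  # error should sit near 0.674 x SE(b)/b ~ 0.23
  dc <- cfg$decay
  d <- rep(seq(dc$distance_range[1], dc$distance_range[2],
               length.out = dc$n_plots), 2)
  s <- rep(c("winter", "summer"), each = dc$n_plots)
  A <- ifelse(s == "winter", dc$A_winter, dc$A_summer)
  e <- exp(-dc$b * d)
  J <- cbind(ifelse(s == "winter", e, 0), ifelse(s == "summer", e, 0),
             -A * d * e)
  sig <- ifelse(s == "winter", dc$noise_sd_winter, dc$noise_sd_summer)
  JtJi <- solve(crossprod(J))
  V <- JtJi %*% t(J) %*% (J * sig^2) %*% JtJi
  predicted <- 0.674 * sqrt(V[3, 3]) / dc$b
  expect_lt(median(errs), 1.4 * predicted)
  expect_gt(median(errs), 0.5 * predicted)
})
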