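test_that("OLS recovers exact lines and the two-point formula", {
  pts <- tibble::tibble(length = c(100, 200, 300, 400),
                        count = 0.32 * c(100, 200, 300, 400) + 5.8,
                        motif = "bonds", ensemble = "random")
  fit <- motif_trend_fit(pts)
  expect_equal(fit$slope, 0.32, tolerance = 1e-12)
  expect_equal(fit$intercept, 5.8, tolerance = 1e-12)

  two <- tibble::tibble(length = c(100, 200, 100), count = c(37, 69, 37),
                        motif = "bonds", ensemble = "x")
  fit2 <- motif_trend_fit(two)
  expect_equal(fit2$slope, 0.32, tolerance = 1e-12)
  expect_equal(fit2$intercept, 5.0, tolerance = 1e-12)

  degen <- tibble::tibble(length = c(100, 100, 100), count = 1:3,
                          motif = "m", ensemble = "e")
  expect_error(motif_trend_fit(degen), "degenerate")
})

test_that("OLS residuals are orthogonal to the design", {
  set.seed(3)
  pts <- tibble::tibble(length = rep(c(50, 100, 200), each = 20),
                        motif = "bonds", ensemble = "random")
  pts$count <- 0.3 * pts$length + rnorm(nrow(pts), sd = 4)
  fit <- motif_trend_fit(pts)
  resid <- pts$count - fit$slope * pts$length - fit$intercept
  expect_lt(abs(sum(resid)), 1e-8)
  expect_lt(abs(sum(resid * pts$length)), 1e-6)
})

test_that("bootstrap CIs are seeded, cover the estimate, and collapse on noiseless data", {
  set.seed(21)
  pts <- tibble::tibble(length = rep(c(50, 100, 150, 200), each = 25),
                        motif = "bonds", ensemble = "random")
  pts$count <- 0.3 * pts$length + 2 + rnorm(nrow(pts), sd = 3)
  f1 <- motif_trend_fit(pts, B = 400, seed = 10)
  f2 <- motif_trend_fit(pts, B = 400, seed = 10)
  expect_identical(tidy(f1), tidy(f2))
  expect_lte(f1$slope_lo, f1$slope)
  expect_gte(f1$slope_hi, f1$slope)
  expect_lte(f1$intercept_lo, f1$intercept)
  expect_gte(f1$intercept_hi, f1$intercept)

  # bootstrap width within 2x of the analytic OLS band
  se <- summary(lm(count ~ length, pts))$coefficients["length", "Std. Error"]
  width <- f1$slope_hi - f1$slope_lo
  expect_lt(width, 2 * (2 * 1.96 * se))
  expect_gt(width, (2 * 1.96 * se) / 2)

  exact <- tibble::tibble(length = rep(c(50, 100, 150), each = 5),
                          motif = "m", ensemble = "e")
  exact$count <- 0.1 * exact$length + 1
  fe <- motif_trend_fit(exact, B = 200, seed = 1)
  expect_equal(fe$slope_lo, fe$slope_hi, tolerance = 1e-10)
})

test_that("length-grid datasets are well-formed, seeded, and trend upward", {
  eng <- folding_engine("nussinov")
  pts <- build_length_grid_dataset(eng, c(30, 60), n_per_length = 2, seed = 1)
  expect_equal(nrow(pts), 2 * 2 * 5)  # 5 motifs per structure
  expect_setequal(unique(pts$length), c(30, 60))
  expect_setequal(unique(pts$motif),
                  c("bulges", "loops", "junctions", "helices", "bonds"))
  expect_identical(pts, build_length_grid_dataset(eng, c(30, 60), 2, seed = 1))

  grid <- build_length_grid_dataset(eng, c(40, 80, 120, 160), 12, seed = 2)
  fits <- motif_trend_fit(grid)
  bonds <- fits$slope[fits$motif == "bonds"]
  helices <- fits$slope[fits$motif == "helices"]
  loops <- fits$slope[fits$motif == "loops"]
  expect_gt(bonds, helices)
  expect_gt(helices, loops)
  expect_gt(loops, 0)
})

test_that("trend fits expose tidy, glance and autoplot", {
  eng <- folding_engine("nussinov")
  grid <- build_length_grid_dataset(eng, c(40, 80), 5, seed = 4)
  fit <- motif_trend_fit(grid, B = 150, seed = 1)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 5L)
  gl <- glance(fit)
  expect_true(gl$bootstrapped)
  expect_equal(gl$n_points, nrow(grid))
  expect_s3_class(autoplot(fit), "ggplot")
})
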