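test_that("hill_response semantics", {
  expect_equal(hill_response(122, 122, n = 2, A = 1), 0.5)
  expect_equal(hill_response(0, 50), 0)
  expect_equal(hill_response(50, 50, n = 2, A = 4), 2)
  # sigmoid with n = 2: second derivative changes sign exactly once
  L <- seq(0.1, 1000, length.out = 2000)
  d2 <- diff(diff(hill_response(L, 122)))
  expect_equal(sum(diff(sign(d2)) != 0), 1L)
})

test_that("fit_hill recovers parameters", {
  doses <- c(10, 25, 50, 100, 150, 250, 375, 500)
  ds <- gen_dose_response("hill", list(K_half = 122, n = 2, A = 1), doses,
                          reps = 1,
                          config = generator_config(seed = 1, noise_sd = 0))
  f <- fit_hill(ds)
  expect_equal(f$K_half, 122, tolerance = 1e-6)
  expect_equal(f$A, 1, tolerance = 1e-6)
  expect_true(f$converged)

  # doses above max_dose (overoxidation regime) are excluded
  ds2 <- rbind(ds, data.frame(dose = 800, response = 0.1))
  class(ds2) <- class(ds)
  f2 <- fit_hill(ds2, max_dose = 500)
  expect_equal(f2$K_half, f$K_half)

  # dose-axis rescaling rescales K_half accordingly
  ds3 <- ds; ds3$dose <- ds3$dose / 1000
  f3 <- fit_hill(ds3, max_dose = 0.5)
  expect_equal(f3$K_half * 1000, f$K_half, tolerance = 1e-4)
})

test_that("tight_binding_y matches its limits and monotonicity", {
  expect_equal(tight_binding_y(0, 5, 1, 3), 1)
  # saturation: L0 = 1e6 K_D with small dy_max
  expect_lt(abs(tight_binding_y(1e6 * 5, 5, 1, 3) - 3), 1e-3 * 2)
  # monotone increasing in L0, decreasing in K_D, increasing in dy_max
  L <- seq(0, 100, by = 0.5)
  y <- tight_binding_y(L, 10, 0, 5)
  expect_true(all(diff(y) > 0))
  expect_true(all(y >= 0 & y <= 5 + 1e-12))
  Ks <- c(0.1, 1, 10, 100)
  at <- vapply(Ks, function(K) tight_binding_y(20, K, 0, 5), numeric(1))
  expect_true(all(diff(at) < 0))
  dm <- vapply(c(1, 2, 5, 10), function(d) tight_binding_y(20, 10, 0, d),
               numeric(1))
  expect_true(all(diff(dm) > 0))
})

test_that("tight_binding_y equals the bisection equilibrium oracle", {
  for (dmax in c(0.5, 2, 10)) {
    for (K in c(0.1, 1, 10)) {
      for (L0 in c(0, 0.5, 5, 50)) {
        want <- oracle_bound_bisect(L0, K, dmax)
        expect_lt(abs(tight_binding_y(L0, K, 2, 2 + dmax) - (2 + want)),
                  1e-9)
      }
    }
  }
})

test_that("fit_two_state recovers parameters and potency ratios", {
  doses <- c(0, 1, 2, 5, 10, 20, 50, 100)
  ds <- gen_dose_response("twostate", list(K_D = 10, y_min = 1, y_max = 3),
                          doses, reps = 1,
                          config = generator_config(seed = 2, noise_sd = 0))
  f <- fit_two_state(ds)
  expect_equal(f$K_D, 10, tolerance = 1e-6)
  expect_equal(f$y_min, 1, tolerance = 1e-6)
  expect_equal(f$y_max, 3, tolerance = 1e-6)
  expect_equal(f$half_max_L, 10 + 1, tolerance = 1e-6)

  # two proteins with a 10x K_D ratio: half-maximal concentration ratio
  # ~10 in the weak-depletion regime (dy_max << K_D), 5% noise
  mk <- function(K, seed) {
    d <- K * c(0, 0.125, 0.25, 0.5, 1, 2, 4, 8)
    fit_two_state(gen_dose_response(
      "twostate", list(K_D = K, y_min = 0.2, y_max = 0.2 + 0.05 * K), d,
      reps = 3, config = generator_config(seed = seed, noise_sd = 0.05)))
  }
  wt <- mk(10, 11); mut <- mk(100, 12)
  expect_equal(mut$half_max_L / wt$half_max_L, 10, tolerance = 0.1)
})

test_that("linear inhibition fits and truncates correctly", {
  ds <- dose_response(c(0, 1, 2, 3, 4, 6), 10 - 2 * c(0, 1, 2, 3, 4, 6))
  f <- fit_linear_inhibition(ds)
  expect_equal(f$intercept, 10, tolerance = 1e-9)
  expect_equal(f$slope, -2, tolerance = 1e-9)
  expect_equal(f$x_zero, 5, tolerance = 1e-9)

  # slope equals the closed-form normal-equations solution (data kept
  # well above zero so the truncation rule stays inert)
  set.seed(42)
  x <- c(0, 1, 2, 3, 4, 5); y <- 12 - 1.3 * x + rnorm(6, sd = 0.3)
  f2 <- fit_linear_inhibition(dose_response(x, y))
  slope_oracle <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  intercept_oracle <- mean(y) - slope_oracle * mean(x)
  expect_equal(f2$slope, slope_oracle, tolerance = 1e-9)
  expect_equal(f2$intercept, intercept_oracle, tolerance = 1e-9)

  # constant data: zero slope, warning, x_zero undefined
  expect_warning(f3 <- fit_linear_inhibition(
    dose_response(c(0, 1, 2, 3), rep(5, 4))), "x_zero undefined")
  expect_equal(f3$slope, 0)
  expect_true(is.na(f3$x_zero))

  # points past depletion are dropped once and the line refit
  x <- c(0, 1, 2, 3, 4, 5, 6, 7)
  y <- pmax(10 - 2 * x, 0)  # flat tail at zero beyond x = 5
  f4 <- fit_linear_inhibition(dose_response(x, y))
  expect_equal(f4$slope, -2, tolerance = 1e-9)
  expect_equal(f4$x_zero, 5, tolerance = 1e-9)
})

test_that("relative biofilm normalizes per experiment", {
  tab <- data.frame(
    experiment = c(rep("e1", 4), rep("e2", 3)),
    strain = c("WT", "WT", "dgcZ", "dgcZ", "WT", "WT", "dgcZ"),
    treatment = c("untreated", "untreated", "hocl", "hocl",
                  "untreated", "untreated", "hocl"),
    a562 = c(0.9, 1.1, 0.8, 1.2, 0.5, 0.5, 0.8))
  out <- relative_biofilm(tab)
  # untreated WT rows average exactly 1 in each experiment
  for (ex in c("e1", "e2")) {
    ref <- out$experiment == ex & out$strain == "WT" &
      out$treatment == "untreated"
    expect_equal(mean(out$relative_biofilm[ref]), 1.0)
  }
  # sample 0.8 against WT mean 0.5 -> 1.6-fold
  expect_equal(out$relative_biofilm[out$experiment == "e2" &
                                    out$strain == "dgcZ"], 1.6)
  # invariant to per-experiment scaling
  tab2 <- tab
  tab2$a562[tab2$experiment == "e1"] <- tab2$a562[tab2$experiment == "e1"] * 7
  expect_equal(relative_biofilm(tab2)$relative_biofilm,
               out$relative_biofilm)
  # missing reference names the experiment
  expect_error(relative_biofilm(tab[tab$experiment == "e1" &
                                    tab$strain != "WT", ]), "e1")
})

test_that("paired t handles regular and degenerate inputs", {
  # identical vectors: zero differences -> t = 0, p = 1
  r <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0); expect_equal(r$p, 1)
  # constant nonzero differences -> infinite t, p -> 0
  r <- paired_t(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_identical(r$t, Inf); expect_equal(r$p, 0)
  # hand-computed 4-pair example
  treated <- c(5.1, 4.8, 6.0, 5.5); control <- c(4.9, 4.5, 5.2, 5.0)
  d <- treated - control
  t_oracle <- mean(d) / (sd(d) / sqrt(4))
  p_oracle <- 2 * pt(-abs(t_oracle), df = 3)
  r <- paired_t(treated, control)
  expect_equal(r$t, t_oracle, tolerance = 1e-12)
  expect_equal(r$p, p_oracle, tolerance = 1e-12)
  expect_equal(r$df, 3)
})
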