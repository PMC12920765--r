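# Gauss-Newton phase fitting, asymptotic inference, AIC, nested comparison.

test_that("noise-free design data are recovered to machine-level accuracy", {
  sch <- default_schedule()
  obs <- noise_free_data(0.871, 1.119, 4.075, 0.33)

  f1 <- fit_phase(obs, "contamination", sch, "pooled")
  expect_true(f1$converged)
  expect_equal(f1$estimates$kA, 0.871, tolerance = 1e-6)
  expect_equal(f1$estimates$kE, 1.119, tolerance = 1e-6)

  f2 <- fit_phase(obs, "decontamination", sch, "pooled")
  expect_equal(f2$estimates$kA, 4.075, tolerance = 1e-6)
  expect_equal(f2$estimates$kE, 0.33, tolerance = 1e-6)

  # zero-noise fit: CI width collapses
  expect_true(all(f1$ci95[, 2] - f1$ci95[, 1] < 1e-5))
})

test_that("habitat symmetry: identical generating params give equal estimates", {
  sch <- default_schedule()
  cfg <- pooled_truth_config(seed = 71)
  obs <- generate_dataset(cfg)$observations
  fh <- fit_phase(obs, "contamination", sch, "by_habitat")
  # same truth in both habitats: estimates differ only by sampling noise
  expect_equal(fh$estimates$kA_forest, fh$estimates$kA_city,
               tolerance = 0.5)
  expect_equal(fh$estimates$kE_forest, fh$estimates$kE_city,
               tolerance = 0.5)
  expect_equal(fh$n_params, 2L * fit_phase(obs, "contamination", sch,
                                           "pooled")$n_params)
})

test_that("Gauss-Newton matches the brute-force grid oracle on small data", {
  sch <- default_schedule()
  set.seed(21)
  for (i in 1:5) {
    kA <- runif(1, 0.3, 2); kE <- runif(1, 0.4, 2)
    # early days keep kE identifiable on small instances
    t <- rep(c(1, 2, 3, 5, 10, 21), each = 2)
    y <- oracle_curve(t, 2, 100, kA, kE) + rnorm(length(t), 0, 3)
    y <- pmax(y, 0)
    obs <- data.frame(colony_id = as.character(seq_along(t)),
                      habitat = "forest", region = "paris",
                      time_days = t, concentration = y)
    fit <- fit_phase(obs, "contamination", sch, "pooled")
    oracle <- grid_search(y, t, 2, 100,
                          seq(0.01, 10, length.out = 240),
                          seq(0.01, 10, length.out = 240))
    # the optimizer can only improve on the best grid point
    expect_lte(fit$rss, oracle$rss * (1 + 1e-6))
    # and the grid RSS at the Gauss-Newton optimum is within grid error
    cell <- 10 / 239
    near <- grid_search(y, t, 2, 100,
                        fit$estimates$kA + cell * c(-1, 0, 1),
                        fit$estimates$kE + cell * c(-1, 0, 1))
    expect_lte(near$rss, oracle$rss * (1 + 1e-6))
  }
})

test_that("all default starts reach the same optimum on design-truth data", {
  sch <- default_schedule()
  for (seed in c(31, 32, 33)) {
    obs <- generate_dataset(pooled_truth_config(seed = seed))$observations
    for (phase in c("contamination", "decontamination")) {
      fit <- fit_phase(obs, phase, sch, "pooled")
      ms <- fit$multistart
      rss_ok <- ms$rss[ms$converged]
      expect_gt(length(rss_ok), 0)
      spread <- (max(rss_ok) - min(rss_ok)) / min(rss_ok)
      expect_lt(spread, 1e-8)
    }
  }
})

test_that("asymptotic CIs match a linearized-regression computation", {
  # oracle: with kE held near truth the model is linear in kA, so the
  # profile SE of kA from ordinary linear regression should approximate the
  # Jacobian-based SE when kE is nearly noiseless
  sch <- default_schedule()
  obs <- generate_dataset(pooled_truth_config(seed = 41))$observations
  fit <- fit_phase(obs, "contamination", sch, "pooled")
  expect_true(all(fit$ci95[, 1] < fit$ci95[, 2]))
  expect_true(all(unlist(fit$estimates) > fit$ci95[, 1]))
  expect_true(all(unlist(fit$estimates) < fit$ci95[, 2]))
  # z intervals are strictly narrower than t intervals
  fz <- asymptotic_ci(fit, quantile = "z")
  expect_true(all(fz$ci95[, 2] - fz$ci95[, 1] <
                    fit$ci95[, 2] - fit$ci95[, 1]))
  # manual reconstruction from the stored Jacobian
  J <- fit$jacobian
  s2 <- fit$rss / (fit$n_obs - fit$n_params)
  se_manual <- sqrt(diag(s2 * solve(t(J) %*% J)))
  expect_equal(unname(fit$se), unname(se_manual), tolerance = 1e-10)
})

test_that("adjusted R2 follows its definition and edge cases", {
  sch <- default_schedule()
  obs <- noise_free_data(0.871, 1.119, 4.075, 0.33)
  f <- fit_phase(obs, "contamination", sch, "pooled")
  expect_equal(adjusted_r2(f), 1, tolerance = 1e-9)

  obs2 <- generate_dataset(pooled_truth_config(seed = 51))$observations
  f2 <- fit_phase(obs2, "contamination", sch, "pooled")
  n <- f2$n_obs; p <- f2$n_params
  expect_equal(adjusted_r2(f2),
               1 - (f2$rss / (n - p)) / (f2$tss / (n - 1)),
               tolerance = 1e-12)
  expect_equal(adjusted_r2(f2, obs2), adjusted_r2(f2), tolerance = 1e-12)
  # a constant prediction equal to the data mean scores <= 0 after the
  # degrees-of-freedom penalty
  f3 <- f2
  f3$rss <- f3$tss
  expect_lte(adjusted_r2(f3), 0)
})

test_that("AIC implements the Gaussian-likelihood formula", {
  sch <- default_schedule()
  # six-point toy fit, hand computation of the formula
  t <- c(1, 3, 5, 10, 15, 21)
  y <- oracle_curve(t, 2, 100, 0.9, 1.1) + c(2, -3, 1, -1, 2, -1)
  obs <- data.frame(colony_id = as.character(1:6), habitat = "forest",
                    region = "paris", time_days = t, concentration = y)
  f <- fit_phase(obs, "contamination", sch, "pooled")
  n <- 6
  expect_equal(aic(f), n * log(2 * pi * f$rss / n) + n + 2 * (2 + 1),
               tolerance = 1e-9)
  # equal rss and p give equal AIC regardless of estimates
  g <- f; g$estimates <- list(kA = 1, kE = 1)
  expect_equal(aic(g), aic(f))
  # and it matches stats::AIC on an equivalent least-squares fit
  lmfit <- lm(y ~ 1)
  flm <- f; flm$rss <- sum(resid(lmfit)^2); flm$n_params <- 1L
  expect_equal(aic(flm), AIC(lmfit), tolerance = 1e-9)
  f$rss <- 0
  expect_error(aic(f), "degenerate")
})

test_that("nested comparison reproduces the extra-sum-of-squares F", {
  sch <- default_schedule()
  obs <- generate_dataset(simulation_config(seed = 61))$observations
  f0 <- fit_phase(obs, "contamination", sch, "pooled")
  f1 <- fit_phase(obs, "contamination", sch, "by_habitat")
  cmp <- compare_nested(f0, f1)

  # nestedness: the richer model can never fit worse
  expect_lte(f1$rss, f0$rss)
  expect_equal(cmp$df_num, 2)
  expect_equal(cmp$df_den, f1$n_obs - 4)
  F_manual <- ((f0$rss - f1$rss) / 2) / (f1$rss / cmp$df_den)
  expect_equal(cmp$f_stat, F_manual, tolerance = 1e-12)
  expect_equal(cmp$p_value, pf(F_manual, 2, cmp$df_den, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(cmp$preferred,
               if (cmp$aic_alt < cmp$aic_null) "by_habitat" else "pooled")

  # identical fits compare as F = 0, p = 1
  same <- compare_nested(f0, f0)
  expect_equal(same$f_stat, 0)
  expect_equal(same$p_value, 1)

  # mismatched data are rejected
  obs2 <- generate_dataset(simulation_config(seed = 62))$observations
  g1 <- fit_phase(obs2, "contamination", sch, "by_habitat")
  expect_error(compare_nested(f0, g1), "same observations")
})

test_that("decontamination anchoring uses the pooled phase-1 switch value", {
  sch <- default_schedule()
  obs <- generate_dataset(simulation_config(seed = 63))$observations
  p1 <- fit_phase(obs, "contamination", sch, "pooled")
  expected_anchor <- concentration_at_switch(
    kinetic_params(p1$estimates$kA, p1$estimates$kE), sch)
  f2 <- fit_phase(obs, "decontamination", sch, "pooled")
  expect_equal(unname(f2$anchor$values[1]), expected_anchor,
               tolerance = 1e-10)
  expect_equal(f2$anchor$type, "pooled")
  # habitat-specific anchors differ when kinetics differ by habitat
  f2h <- fit_phase(obs, "decontamination", sch, "by_habitat",
                   anchor = "by_habitat")
  expect_equal(f2h$anchor$type, "by_habitat")
  expect_false(isTRUE(all.equal(unname(f2h$anchor$values["forest"]),
                                unname(f2h$anchor$values["city"]))))
  # explicit user anchor wins
  f2u <- fit_phase(obs, "decontamination", sch, "pooled", c_switch = 80)
  expect_equal(unname(f2u$anchor$values[1]), 80)
})

test_that("fit preconditions are enforced", {
  sch <- default_schedule()
  obs <- generate_dataset(simulation_config(seed = 64))$observations
  two_days <- obs[obs$time_days %in% c(1, 3), ]
  expect_error(fit_phase(two_days, "contamination", sch, "pooled"),
               "distinct time points")
  one_hab <- obs[obs$habitat == "forest", ]
  expect_error(fit_phase(one_hab, "contamination", sch, "by_habitat"),
               "both habitat levels")
  tiny <- obs[obs$time_days %in% c(1, 3, 5), ][1:3, ]
  expect_error(fit_phase(tiny[1:2, ], "contamination", sch, "pooled"),
               "distinct time points")
  # fewer observations than parameters
  four <- rbind(obs[obs$time_days == 1, ][1:2, ],
                obs[obs$time_days == 3, ][1, ],
                obs[obs$time_days == 5, ][2, ])
  four$habitat <- c("forest", "city", "forest", "city")
  expect_error(fit_phase(four, "contamination", sch, "by_habitat"),
               "cannot identify")
})
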