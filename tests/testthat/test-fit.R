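test_that("fitting model-exact data from the truth gives objective ~0", {
  tab <- predict_ratios(flux_star())
  fit <- fit_fluxes(tab, starts = matrix(theta_star, nrow = 1,
                                         dimnames = list(NULL, names(theta_star))))
  expect_lt(fit$objective, 1e-12)
  expect_equal(est_vec(fit), theta_star, tolerance = 1e-6)
})

test_that("noiseless data are recovered from the default starts", {
  tab <- predict_ratios(flux_star())
  fit <- fit_fluxes(tab, seed = 1)
  expect_equal(est_vec(fit), theta_star, tolerance = 1e-3)
  # best-of-starts up to the documented tie tolerance
  expect_lte(fit$objective,
             min(fit$starts$objective[fit$starts$converged]) + 1e-10)
})

test_that("identical seeds give bit-identical fits", {
  tab <- generate_dataset(scenario_spec("rep", flux_star(), n_replicates = 1,
                                        noise_sd = 0.01, seed = 3))
  f1 <- fit_fluxes(tab, seed = 9)
  f2 <- fit_fluxes(tab, seed = 9)
  expect_identical(est_vec(f1), est_vec(f2))
  expect_identical(f1$objective, f2$objective)
})

test_that("degenerate and undersized tables are rejected", {
  tab <- predict_ratios(flux_star())
  tab$ratio <- 0
  expect_error(fit_fluxes(tab), class = "tcaflux_validation_error")
  ok <- predict_ratios(flux_star())
  expect_error(fit_fluxes(ok[1:3, ]), class = "tcaflux_validation_error")
})

test_that("sem column switches the objective to 1/sem^2 weighting", {
  tab <- predict_ratios(flux_star())
  tab$sem <- 0.02
  fit <- fit_fluxes(tab, n_restarts = 0)
  expect_equal(unique(fit$obs_weights), 1 / 0.02^2)
  expect_equal(est_vec(fit), theta_star, tolerance = 1e-3)
})

test_that("reduced variants clamp their fixed flux", {
  tab <- predict_ratios(flux_params(0.7, 0.3, 0, 0.1))
  fnc <- fit_fluxes(tab, variant = "NO_CYCLING", seed = 1)
  expect_identical(fnc$estimate$pk, 0)
  fnp <- fit_fluxes(predict_ratios(flux_params(0.7, 0, 0, 0.2)),
                    variant = "NO_PC", seed = 1)
  expect_identical(fnp$estimate$y_pc, 0)
})

test_that("bootstrap intervals are deterministic and collapse on exact data", {
  tab <- predict_ratios(flux_star())
  fit <- fit_fluxes(tab, n_restarts = 0)
  b1 <- bootstrap_ci(tab, fit, n_resamples = 60, seed = 4)
  b2 <- bootstrap_ci(tab, fit, n_resamples = 60, seed = 4)
  expect_identical(b1$ci, b2$ci)
  expect_lt(max(b1$ci[, "upper"] - b1$ci[, "lower"]), 1e-3)
  expect_true(all(b1$ci[, "lower"] <= est_vec(fit) + 1e-12))
  expect_true(all(b1$ci[, "upper"] >= est_vec(fit) - 1e-12))
  expect_error(bootstrap_ci(tab, fit, n_resamples = 10),
               class = "tcaflux_input_error")
})

test_that("a single-variant comparison equals the plain fit", {
  tab <- generate_dataset(scenario_spec("one", flux_star(), n_replicates = 1,
                                        noise_sd = 0.01, seed = 5))
  cmp <- compare_models(tab, "FULL", seed = 2)
  expect_equal(nrow(cmp$ranking), 1)
  fit <- fit_fluxes(tab, variant = "FULL", seed = 2)
  expect_equal(cmp$fits$FULL$objective, fit$objective)
  expect_equal(est_vec(cmp$fits$FULL), est_vec(fit))
})

test_that("failed variants annotate the ranking instead of aborting it", {
  tab <- predict_ratios(flux_star())
  cmp <- compare_models(tab, c("FULL", "NO_CYCLING"), seed = 1,
                        aggregate_replicates = FALSE)
  expect_equal(nrow(cmp$ranking), 2)
  expect_true(all(is.finite(cmp$ranking$aicc)))
  expect_equal(cmp$ranking$variant[1], "FULL")  # data contain cycling signal
})

test_that("Welch comparison matches the closed form and stats::t.test", {
  g <- group_compare(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
  # hand-checkable: diff -0.3, se sqrt(0.02/3), df 4
  expect_equal(g$statistic, -0.3 / sqrt(0.01 / 3 + 0.01 / 3), tolerance = 1e-9)
  expect_equal(g$df, 4, tolerance = 1e-9)
  ref <- stats::t.test(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
  expect_equal(g$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(g$p_value, 0.02131164, tolerance = 1e-6)
  # one-sided
  g1 <- group_compare(c(0.4, 0.5, 0.6), c(0.1, 0.2, 0.3),
                      alternative = "greater")
  expect_equal(g1$p_value, ref$p.value / 2, tolerance = 1e-12)
})

test_that("group comparison edge cases follow the stated conventions", {
  expect_equal(group_compare(c(0.2, 0.2), c(0.2, 0.2))$p_value, 1)
  z <- group_compare(c(0.2, 0.2), c(0.5, 0.5))
  expect_equal(z$p_value, 0)
  expect_error(group_compare(0.1, c(0.2, 0.3)), class = "tcaflux_input_error")
  fits <- list(flux_params(0.7, 0.3, 0.2, 0.1), flux_params(0.6, 0.2, 0.1, 0.1))
  expect_error(group_compare(fits, fits), class = "tcaflux_input_error")
  g <- group_compare(fits, fits, flux_name = "y_pc")
  expect_equal(g$p_value, 1, tolerance = 1e-9)
})

test_that("per-sample fitting summarizes conditions as mean +/- SEM", {
  tab <- generate_dataset(preset_scenario("WT", n_replicates = 3, seed = 8))
  fs <- fit_samples(tab, seed = 1)
  expect_length(fs$fits, 3)
  expect_equal(sort(unique(fs$summary$flux)),
               c("f_pdh", "pk", "y_pc", "y_s"))
  pk_row <- fs$summary[fs$summary$flux == "pk", ]
  pk_est <- vapply(fs$fits, function(f) f$estimate$pk, 0)
  expect_equal(pk_row$mean, mean(pk_est))
  expect_equal(pk_row$sem, sd(pk_est) / sqrt(3))
})
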