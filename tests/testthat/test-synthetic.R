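test_that("zero noise reproduces the model prediction per replicate", {
  sc <- scenario_spec("clean", flux_star(), n_replicates = 3, noise_sd = 0)
  tab <- generate_dataset(sc)
  ref <- predict_ratios(flux_star())
  for (s in unique(tab$sample_id)) {
    sub <- tab[tab$sample_id == s, ]
    expect_equal(sub$ratio, ref$ratio, tolerance = 1e-12)
  }
})

test_that("generated tables have the documented shape and are seeded", {
  sc <- scenario_spec("shape", flux_star(), n_replicates = 4, noise_sd = 0.01,
                      seed = 21)
  tab <- generate_dataset(sc)
  expect_equal(nrow(tab), 4 * (4 + 3 + 4 + 2 + 4))
  expect_identical(tab, generate_dataset(sc))
  expect_false(identical(tab$ratio, generate_dataset(sc, seed = 22)$ratio))
  expect_true(validate_ratio_table(tab))
})

test_that("per-replicate flux variability perturbs fluxes admissibly", {
  sc <- scenario_spec("cv", flux_star(), n_replicates = 6, noise_sd = 0,
                      flux_cv = 0.2, seed = 31)
  tab <- generate_dataset(sc)
  # replicates differ when flux_cv > 0
  r1 <- tab$ratio[tab$sample_id == "cv_r1"]
  r2 <- tab$ratio[tab$sample_id == "cv_r2"]
  expect_gt(max(abs(r1 - r2)), 1e-6)
  expect_true(validate_ratio_table(tab))
})

test_that("empirical noise sd matches noise_sd for small-fraction components", {
  # renormalization shrinks the sd of dominant components, so the additive
  # scale is only visible on components well below ~0.1 (and above the
  # clipping region)
  sc <- scenario_spec("noise", flux_star(), n_replicates = 1000,
                      noise_sd = 0.01, seed = 42)
  tab <- generate_dataset(sc)
  ref <- predict_ratios(flux_star())
  truth <- setNames(ref$ratio, ref$multiplet)
  sds <- tapply(tab$ratio, tab$multiplet, sd)
  sel <- names(truth)[truth >= 3 * 0.01 & truth <= 0.1]
  expect_gt(length(sel), 0)
  for (m in sel) expect_equal(unname(sds[[m]]), 0.01, tolerance = 0.1)
})

test_that("presets satisfy the reported orderings and flux invariants", {
  names <- c("WT", "MUL1KO", "MUL1KO_PERI", "MUL1KO_CTM",
             "AKT2KO", "AKT2KO_DMOG")
  fl <- lapply(names, function(n) preset_scenario(n)$true_fluxes)
  names(fl) <- names
  # all presets valid flux vectors (constructor enforces invariants)
  for (f in fl) expect_s3_class(f, "flux_params")
  # knockout raises cycling and carboxylase anaplerosis
  expect_gt(fl$MUL1KO$pk, fl$WT$pk)
  expect_gt(fl$MUL1KO$y_pc, fl$WT$y_pc)
  # inhibitors pull both back toward/below WT
  expect_lt(fl$MUL1KO_PERI$pk, fl$MUL1KO$pk)
  expect_lt(fl$MUL1KO_CTM$pk, fl$MUL1KO$pk)
  expect_lt(fl$MUL1KO_PERI$pk, fl$WT$pk + 1e-9)
  expect_lt(fl$MUL1KO_CTM$y_pc, fl$MUL1KO$y_pc)
  # Akt2 loss suppresses cycling; HIF-1a activation partially restores it
  expect_lt(fl$AKT2KO$pk, fl$WT$pk)
  expect_gt(fl$AKT2KO_DMOG$pk, fl$AKT2KO$pk)
  expect_lt(fl$AKT2KO_DMOG$pk, fl$WT$pk)
  expect_gt(fl$AKT2KO_DMOG$y_pc, fl$WT$y_pc)
  expect_lt(fl$AKT2KO_DMOG$y_pc, fl$MUL1KO$y_pc)
  expect_gt(fl$AKT2KO_DMOG$y_s, fl$AKT2KO$y_s)
  # succinyl-CoA anaplerosis depressed in both Akt2-knockout presets
  expect_lt(fl$AKT2KO$y_s, min(fl$WT$y_s, fl$MUL1KO$y_s))
  expect_lt(fl$AKT2KO_DMOG$y_s, min(fl$WT$y_s, fl$MUL1KO$y_s))
  expect_error(preset_scenario("HELA"), class = "tcaflux_input_error")
})

test_that("scenario invariants are enforced", {
  expect_error(scenario_spec("x", flux_star(), n_replicates = 0),
               class = "tcaflux_input_error")
  expect_error(scenario_spec("x", flux_star(), noise_sd = -0.1),
               class = "tcaflux_input_error")
})
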