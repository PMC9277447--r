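test_that("network variants are built and unknown variants rejected", {
  net <- build_tca_network("FULL")
  expect_s3_class(net, "tca_network")
  expect_setequal(names(net$pools),
                  c("PYR", "LAC", "ACCOA", "OAA", "AKG_GLU", "SUC", "PEP"))
  expect_equal(unname(net$pools[c("PYR", "ACCOA", "OAA", "AKG_GLU")]),
               c(3L, 2L, 4L, 5L))
  # the seven enzymatic steps plus the two dilution inflows and tracer
  expect_setequal(vapply(net$terms, `[[`, "", "name"),
                  c("glycolysis", "pk", "ldh", "pepck", "pdh",
                    "accoa_dilution", "mdh", "pc", "kgdh", "ys", "cs"))
  expect_error(build_tca_network("BANANAS"), class = "tcaflux_variant_error")
  # NO_CYCLING keeps the PEP -> PYR map but gives it zero weight
  nc <- build_tca_network("NO_CYCLING")
  w <- mixing_weights(nc, flux_params(0.6, 0.2, 0.1, 0.1))
  expect_equal(unname(w[["pk"]]), 0)
  expect_true("pk" %in% vapply(nc$terms, `[[`, "", "name"))
})

test_that("mixing weights sum to 1 per pool for random admissible fluxes", {
  net <- build_tca_network("FULL")
  targets <- vapply(net$terms, `[[`, "", "target")
  set.seed(41)
  for (i in 1:20) {
    w <- mixing_weights(net, random_fluxes())
    sums <- tapply(w, targets, sum)
    expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-12)
  }
})

test_that("flux parameter invariants are enforced", {
  expect_error(flux_params(1.2, 0, 0, 0), class = "tcaflux_flux_error")
  expect_error(flux_params(0.5, -0.1, 0, 0.2), class = "tcaflux_flux_error")
  expect_error(flux_params(0.5, 0.1, 0.5, 0.2), class = "tcaflux_flux_error")
  f <- flux_params(0.5, 0.1, 0.25, 0.2)
  expect_equal(f$pepck, 0.3)
  expect_equal(f$cs, 1)
  expect_error(tracer_spec(enrichment = 1.5), class = "tcaflux_tracer_error")
  expect_error(tracer_spec(g = 0), class = "tcaflux_tracer_error")
})

test_that("fully labeled and unlabeled limits are exact point masses", {
  net <- build_tca_network("FULL")
  ss <- steady_state(net, flux_params(1, 0, 0, 0), tracer_spec(1))
  expect_equal(unname(ss$distributions$AKG_GLU[[pat(1:5)]]), 1,
               tolerance = 1e-8)
  expect_equal(unname(ss$distributions$LAC[[pat(1:3)]]), 1, tolerance = 1e-8)
  ss0 <- steady_state(net, flux_params(0.5, 0.2, 0.1, 0.1), tracer_spec(0))
  for (d in ss0$distributions) expect_equal(unname(d[[1]]), 1,
                                            tolerance = 1e-9)
})

test_that("distributions conserve probability for random fluxes", {
  net <- build_tca_network("FULL")
  set.seed(7)
  for (i in 1:10) {
    ss <- steady_state(net, random_fluxes(), tracer_spec(runif(1)))
    for (d in ss$distributions) {
      expect_true(all(d >= -1e-12))
      expect_equal(sum(d), 1, tolerance = 1e-9)
    }
  }
})

test_that("fumarase scrambling symmetrizes oxaloacetate when y_pc = 0", {
  net <- build_tca_network("FULL")
  ss <- steady_state(net, flux_params(0.7, 0, 0, 0.2), tracer_spec(1))
  m <- marginal_labeling(ss$distributions$OAA)
  expect_equal(m[1], m[4], tolerance = 1e-9)
  expect_equal(m[2], m[3], tolerance = 1e-9)
})

test_that("single-pass evaluation reproduces the first-turn labeling logic", {
  net <- build_tca_network("FULL")
  # PDH-only entry labels glutamate C4-C5 only
  sp <- single_pass(net, flux_params(1, 0, 0, 0), tracer_spec(1))
  m <- marginal_labeling(sp$AKG_GLU)
  expect_equal(m[1:3], rep(0, 3), tolerance = 1e-12)
  expect_true(all(m[4:5] > 0.99))
  # PC-only entry labels glutamate C2-C3 only
  sp2 <- single_pass(net, flux_params(0, 0.3, 0, 0), tracer_spec(1))
  m2 <- marginal_labeling(sp2$AKG_GLU)
  expect_equal(m2[c(1, 4, 5)], rep(0, 3), tolerance = 1e-12)
  expect_true(all(m2[2:3] > 0))
})

test_that("increasing succinyl-CoA anaplerosis never increases labeling", {
  net <- build_tca_network("FULL")
  frac <- sapply(c(0, 0.1, 0.3, 0.6, 1), function(ys) {
    ss <- steady_state(net, flux_params(0.6, 0.2, 0.1, ys), tracer_spec(1))
    marginal_labeling(ss$distributions$AKG_GLU)
  })
  for (pos in 1:5) expect_true(all(diff(frac[pos, ]) <= 1e-10))
})

test_that("non-convergence raises an error carrying the last residual", {
  net <- build_tca_network("FULL")
  err <- tryCatch(
    steady_state(net, flux_params(0.6, 0.2, 0.1, 0.1), tracer_spec(1),
                 max_iterations = 2L),
    tcaflux_convergence_error = function(e) e)
  expect_s3_class(err, "tcaflux_convergence_error")
  expect_true(is.finite(err$residual) && err$residual > 0)
})

test_that("natural-abundance mixing adds background labeling", {
  net <- build_tca_network("FULL")
  ss <- steady_state(net, flux_params(0.5, 0.1, 0, 0.1),
                     tracer_spec(0, natural_abundance = 0.011))
  m <- marginal_labeling(ss$distributions$AKG_GLU)
  expect_equal(unname(m), rep(0.011, 5), tolerance = 1e-9)
})
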