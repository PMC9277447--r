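test_that("lineage sampling is reproducible under a fixed seed", {
  net <- build_tca_network("FULL")
  fl <- flux_params(0.6, 0.2, 0.1, 0.1)
  a <- sample_molecules(net, fl, tracer_spec(), 2000, seed = 5, pools = "LAC")
  b <- sample_molecules(net, fl, tracer_spec(), 2000, seed = 5, pools = "LAC")
  expect_identical(a$distributions, b$distributions)
  expect_equal(sum(a$distributions$LAC), 1, tolerance = 1e-12)
})

test_that("with full enrichment and no dilution every molecule is U-13C", {
  net <- build_tca_network("FULL")
  mc <- sample_molecules(net, flux_params(1, 0, 0, 0), tracer_spec(1),
                         n_molecules = 100, seed = 2, pools = "AKG_GLU")
  expect_equal(unname(mc$distributions$AKG_GLU[[pat(1:5)]]), 1)
})

test_that("lineage oracle matches the fixed-point solver within sampling error", {
  net <- build_tca_network("FULL")
  set.seed(11)
  for (i in 1:3) {
    fl <- random_fluxes()
    ss <- steady_state(net, fl, tracer_spec())
    mc <- sample_molecules(net, fl, tracer_spec(), n_molecules = 5000,
                           seed = 100 + i, pools = "AKG_GLU")
    p <- ss$distributions$AKG_GLU
    q <- mc$distributions$AKG_GLU
    se <- sqrt(pmax(p * (1 - p), 1e-12) / 5000)
    expect_true(all(abs(q - p) <= 3 * se + 1e-6))
  }
})

test_that("sampler rejects invalid inputs", {
  net <- build_tca_network("FULL")
  fl <- flux_params(0.6, 0.2, 0.1, 0.1)
  expect_error(sample_molecules(net, fl, tracer_spec(), 0, seed = 1),
               class = "tcaflux_input_error")
  expect_error(sample_molecules(net, fl, tracer_spec(), 10, seed = 1,
                                pools = "NADH"),
               class = "tcaflux_input_error")
})
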