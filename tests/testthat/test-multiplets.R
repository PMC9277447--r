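glu <- coupling_scheme("glutamate")
lac <- coupling_scheme("lactate")

test_that("point-mass isotopomers give the forced multiplets", {
  # [4,5-13C2]glutamate: C4 couples only to labeled C5
  d <- numeric(32); d[pat(4, 5)] <- 1
  expect_equal(multiplet_pattern(d, 4, glu)$components,
               c(C4S = 0, C4D34 = 0, C4D45 = 1, C4Q = 0))
  # [U-13C]glutamate: all neighbors labeled
  u <- numeric(32); u[pat(1:5)] <- 1
  expect_equal(multiplet_pattern(u, 2, glu)$components[["C2Q"]], 1)
  expect_equal(multiplet_pattern(u, 3, glu)$components[["C3T"]], 1)
  expect_equal(multiplet_pattern(u, 4, glu)$components[["C4Q"]], 1)
  expect_equal(multiplet_pattern(u, 5, glu)$components[["C5D45"]], 1)
  # [1,2-13C2]glutamate: C2 doublet from C1
  d12 <- numeric(32); d12[pat(1, 2)] <- 1
  expect_equal(multiplet_pattern(d12, 2, glu)$components[["C2D12"]], 1)
})

test_that("fractions are conditional probabilities summing to 1", {
  net <- build_tca_network("FULL")
  set.seed(13)
  for (i in 1:5) {
    ss <- steady_state(net, random_fluxes(), tracer_spec())
    for (pos in 2:5) {
      mp <- multiplet_pattern(ss$distributions$AKG_GLU, pos, glu)
      expect_equal(sum(mp$components), 1, tolerance = 1e-9)
      expect_true(all(mp$components >= 0))
    }
  }
})

test_that("zero signal area raises an explicit error, never NaN", {
  d <- numeric(32); d[1] <- 1  # unlabeled only
  expect_error(multiplet_pattern(d, 2, glu), class = "tcaflux_zero_area_error")
})

test_that("one-neighbor positions invert exactly (label <-> neighbor state)", {
  # C5 has only C4 as neighbor: C5S <=> C4 unlabeled, C5D45 <=> C4 labeled
  d <- numeric(32)
  d[pat(5)] <- 0.3        # C5 only
  d[pat(4, 5)] <- 0.7     # C4 and C5
  mp <- multiplet_pattern(d, 5, glu)
  expect_equal(mp$components, c(C5S = 0.3, C5D45 = 0.7))
})

test_that("signal_ratio_table covers glutamate C2-C5 and lactate C2", {
  net <- build_tca_network("FULL")
  ss <- steady_state(net, flux_params(1, 0, 0, 0), tracer_spec(1))
  tab <- signal_ratio_table(ss)
  expect_equal(nrow(tab), 17)
  expect_setequal(unique(tab$pool), c("glutamate", "lactate"))
  hot <- setNames(tab$ratio, tab$multiplet)
  expect_equal(unname(hot[c("C2Q", "C3T", "C4Q", "C5D45", "LC2Q")]),
               rep(1, 5), tolerance = 1e-8)
  # per-position normalization
  sums <- tapply(tab$ratio, paste(tab$pool, tab$position), sum)
  expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-9)
})

test_that("lactate doublets vanish exactly when pyruvate cycling is off", {
  tab <- predict_ratios(flux_params(0.6, 0.2, 0, 0.1), tracer_spec(1))
  lacr <- setNames(tab$ratio[tab$pool == "lactate"],
                   tab$multiplet[tab$pool == "lactate"])
  expect_equal(unname(lacr[c("LC2S", "LC2D12", "LC2D23")]), rep(0, 3))
  expect_equal(unname(lacr[["LC2Q"]]), 1)
})

test_that("fast extraction path agrees with multiplet_pattern", {
  net <- build_tca_network("FULL")
  ex <- tcaflux:::ratio_extractors()
  set.seed(17)
  for (i in 1:5) {
    ss <- steady_state(net, random_fluxes(), tracer_spec())
    fast <- tcaflux:::extract_ratios(ss$distributions, ex)
    tab <- signal_ratio_table(ss)
    slow <- setNames(tab$ratio, tab$multiplet)
    expect_equal(fast[names(slow)], slow, tolerance = 1e-12)
  }
})

test_that("collapse rule merges equal couplings into D and T", {
  labs3 <- vapply(tcaflux:::multiplet_states(glu, 3), `[[`, "", "label")
  expect_setequal(labs3, c("C3S", "C3D", "C3T"))
  labs2 <- vapply(tcaflux:::multiplet_states(lac, 2), `[[`, "", "label")
  expect_setequal(labs2, c("LC2S", "LC2D12", "LC2D23", "LC2Q"))
})
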