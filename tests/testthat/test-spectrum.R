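glu <- coupling_scheme("glutamate")

c2_pattern <- function(fracs) {
  d <- numeric(32)
  d[pat(2)] <- fracs[1]; d[pat(1, 2)] <- fracs[2]
  d[pat(2, 3)] <- fracs[3]; d[pat(1, 2, 3)] <- fracs[4]
  multiplet_pattern(d, 2, glu)
}

test_that("a noise-free singlet integrates to its area", {
  mp <- c2_pattern(c(1, 0, 0, 0))
  mod <- spectrum_model(55.6)
  sp <- render_spectrum(mp, mod, glu, total_area = 2)
  dx <- mod$axis[2] - mod$axis[1]
  expect_equal(sum(sp$intensity) * dx, 2, tolerance = 2e-3)
})

test_that("a triplet renders three lines with 1:2:1 areas", {
  d <- numeric(32); d[pat(2, 3, 4)] <- 1
  mp <- multiplet_pattern(d, 3, glu)
  expect_equal(mp$components[["C3T"]], 1)
  mod <- spectrum_model(27.8)
  sp <- render_spectrum(mp, mod, glu)
  j_ppm <- glu$J[2] / mod$freq_mhz
  at <- function(ppm) sp$intensity[which.min(abs(sp$ppm - ppm))]
  side <- at(27.8 - j_ppm)
  centre <- at(27.8)
  expect_equal(centre / side, 2, tolerance = 0.05)
  expect_equal(at(27.8 + j_ppm) / side, 1, tolerance = 0.05)
})

test_that("noise-free line fitting inverts the forward model exactly", {
  mp <- c2_pattern(c(0.1, 0.4, 0.3, 0.2))
  mod <- spectrum_model(55.6)
  sp <- render_spectrum(mp, mod, glu)
  pf <- fit_areas(sp, mod, glu, 2)
  expect_true(pf$converged)
  expect_equal(unname(pf$areas), unname(mp$components), tolerance = 1e-6)
  rt <- areas_to_ratios(pf)
  expect_equal(rt$components, mp$components, tolerance = 1e-9)
})

test_that("recovered areas scale linearly with the spectrum", {
  mp <- c2_pattern(c(0.25, 0.25, 0.25, 0.25))
  mod <- spectrum_model(55.6)
  sp1 <- render_spectrum(mp, mod, glu, total_area = 1)
  sp5 <- render_spectrum(mp, mod, glu, total_area = 5)
  a1 <- fit_areas(sp1, mod, glu, 2)$areas
  a5 <- fit_areas(sp5, mod, glu, 2)$areas
  expect_equal(a5, 5 * a1, tolerance = 1e-9)
})

test_that("round trip at SNR 50 recovers fractions within 0.01", {
  mp <- c2_pattern(c(0.25, 0.25, 0.25, 0.25))
  clean <- render_spectrum(mp, spectrum_model(55.6), glu)
  for (s in 1:3) {
    mod <- spectrum_model(55.6, noise_sd = max(clean$intensity) / 50,
                          seed = s)
    sp <- render_spectrum(mp, mod, glu)
    rt <- areas_to_ratios(fit_areas(sp, mod, glu, 2))
    expect_lt(max(abs(rt$components - mp$components)), 0.01)
  }
})

test_that("an all-zero spectrum gives zero areas and the zero-area error", {
  mod <- spectrum_model(27.8)
  pf <- fit_areas(rep(0, length(mod$axis)), mod, glu, 3)
  expect_true(pf$converged)
  expect_equal(unname(sum(pf$areas)), 0)
  expect_error(areas_to_ratios(pf), class = "tcaflux_zero_area_error")
})

test_that("fully overlapping component lines are rejected as singular", {
  # J12 = 0 collapses the D12 lines onto the singlet position
  sch0 <- coupling_scheme("lactate", J = c(0, 35))
  d <- numeric(8); d[pat(1, 2)] <- 1
  mp <- multiplet_pattern(d, 2, sch0)
  mod <- spectrum_model(69.3)
  expect_error(fit_areas(render_spectrum(mp, mod, sch0), mod, sch0, 2),
               class = "tcaflux_conditioning_error")
})

test_that("sub-resolution couplings are flagged in the render result", {
  sch <- coupling_scheme("glutamate", J = c(53, 0.001, 0.001, 51))
  d <- numeric(32); d[pat(2, 3, 4)] <- 1
  mp <- multiplet_pattern(d, 3, sch)
  mod <- spectrum_model(27.8, n_points = 1024L)
  sp <- render_spectrum(mp, mod, sch)
  expect_gt(length(sp$warnings), 0)
})

test_that("spectra round-trip through two-column text and JCAMP-DX", {
  mp <- c2_pattern(c(0.5, 0.2, 0.2, 0.1))
  mod <- spectrum_model(55.6, n_points = 2048L)
  sp <- render_spectrum(mp, mod, glu)
  tf <- tempfile(fileext = ".tsv")
  write_spectrum(sp, tf, "tsv")
  r <- read_spectrum(tf)
  expect_equal(r$intensity, sp$intensity, tolerance = 1e-10)
  jf <- tempfile(fileext = ".jdx")
  write_spectrum(sp, jf, "jcamp")
  rj <- read_spectrum(jf)
  expect_equal(length(rj$ppm), length(sp$ppm))
  expect_equal(rj$intensity, sp$intensity, tolerance = 1e-6)
  expect_match(readLines(jf, n = 2)[2], "JCAMP-DX")
})
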