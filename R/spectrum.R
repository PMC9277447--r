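# Lorentzian rendering and linear line-fitting of 13C multiplet regions.
#
# A multiplet component contributes a set of Lorentzian lines: a singlet
# one line; a doublet two lines split by its one-bond coupling; a quartet
# (doublet of doublets) four lines at +/- J1/2 +/- J2/2; a triplet three
# lines at -J, 0, +J with 1:2:1 areas. Areas are the only free parameters
# of the inverse problem, so recovery is (non-negative) linear least
# squares; an optional 1-D refinement adjusts a common linewidth factor.

# Literature-typical chemical-shift centers (ppm); config constants — only
# relative line positions matter for the fit.
DEFAULT_SHIFTS <- list(glutamate = c(`2` = 55.6, `3` = 27.8, `4` = 34.4,
                                     `5` = 182.0),
                       lactate = c(`2` = 69.3))

#' Spectrum model: ppm grid, spectrometer frequency and lineshape
#'
#' @param center_ppm Chemical-shift center of the rendered region.
#' @param freq_mhz Spectrometer 13C frequency in MHz, used to convert Hz
#'   couplings to ppm (default 150.9).
#' @param linewidth_hz Lorentzian full width at half maximum in Hz
#'   (default 1).
#' @param ppm_window Width of the rendered window in ppm (default 12; wide
#'   enough that Lorentzian tails carry well under 0.1\% of the area).
#' @param n_points Grid points (default 16384, ~9 points per linewidth at
#'   the defaults); the grid is strictly increasing.
#' @param noise_sd Gaussian intensity noise sd added on render (default 0).
#' @param seed Seed for the rendering noise.
#' @return An object of class `"spectrum_model"`.
#' @export
spectrum_model <- function(center_ppm, freq_mhz = 150.9, linewidth_hz = 1,
                           ppm_window = 12, n_points = 16384L,
                           noise_sd = 0, seed = 1L) {
  if (linewidth_hz <= 0)
    tca_stop("linewidth_hz must be positive", "tcaflux_input_error")
  if (freq_mhz <= 0 || ppm_window <= 0 || n_points < 16)
    tca_stop("invalid spectrum grid specification", "tcaflux_input_error")
  axis <- seq(center_ppm - ppm_window / 2, center_ppm + ppm_window / 2,
              length.out = n_points)
  structure(list(center_ppm = center_ppm, freq_mhz = freq_mhz,
                 linewidth_hz = linewidth_hz, axis = axis,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "spectrum_model")
}

# Unit-area Lorentzian on the ppm axis.
lorentzian <- function(axis, center, width_ppm) {
  hw <- width_ppm / 2
  (hw / pi) / ((axis - center)^2 + hw^2)
}

# Line offsets (Hz) and area weights of one multiplet component.
component_lines <- function(label, scheme, position) {
  suffix <- sub(sprintf("^%s%d", scheme$prefix, position), "", label)
  nb <- scheme_neighbors(scheme, position)
  if (suffix == "S") return(list(offset = 0, weight = 1))
  if (suffix == "T") {
    j <- mean(c(scheme$J[nb[1]], scheme$J[position]))
    return(list(offset = c(-j, 0, j), weight = c(0.25, 0.5, 0.25)))
  }
  if (suffix == "Q") {
    j1 <- scheme$J[nb[1]]; j2 <- scheme$J[position]
    return(list(offset = c(-j1 - j2, -j1 + j2, j1 - j2, j1 + j2) / 2,
                weight = rep(0.25, 4)))
  }
  if (suffix == "D") {  # merged doublet (equal couplings)
    j <- mean(c(scheme$J[nb[1]], scheme$J[position]))
    return(list(offset = c(-j / 2, j / 2), weight = c(0.5, 0.5)))
  }
  if (grepl("^D[0-9][0-9]$", suffix)) {
    a <- as.integer(substr(suffix, 2, 2)); b <- as.integer(substr(suffix, 3, 3))
    j <- scheme$J[min(a, b)]
    return(list(offset = c(-j / 2, j / 2), weight = c(0.5, 0.5)))
  }
  tca_stop(sprintf("unrecognized multiplet label '%s'", label),
           "tcaflux_input_error")
}

# Design matrix: one unit-area rendered component per column.
multiplet_design <- function(model, scheme, position,
                             linewidth_hz = model$linewidth_hz) {
  labels <- vapply(multiplet_states(scheme, position), `[[`, "", "label")
  width_ppm <- linewidth_hz / model$freq_mhz
  center <- model$center_ppm
  cols <- lapply(labels, function(lb) {
    ln <- component_lines(lb, scheme, position)
    y <- numeric(length(model$axis))
    for (k in seq_along(ln$offset))
      y <- y + ln$weight[k] *
        lorentzian(model$axis, center + ln$offset[k] / model$freq_mhz,
                   width_ppm)
    y
  })
  X <- do.call(cbind, cols)
  colnames(X) <- labels
  X
}

#' Render a multiplet pattern as a Lorentzian line spectrum
#'
#' @param pattern A [multiplet_pattern()] (fractions summing to 1).
#' @param model A [spectrum_model()]; its `center_ppm` defaults are in
#'   `DEFAULT_SHIFTS`.
#' @param scheme The [coupling_scheme()] the pattern came from.
#' @param total_area Total integrated area of the resonance (default 1);
#'   component areas are `total_area * fractions`.
#' @return An object of class `"tca_spectrum"`: `ppm`, `intensity`,
#'   `warnings` (e.g. a coupling splitting below the grid resolution),
#'   plus the model, position and pool. Seeded Gaussian noise is added when
#'   `model$noise_sd > 0`.
#' @examples
#' sch <- coupling_scheme("glutamate")
#' d <- numeric(32); d[32] <- 1  # [U-13C]glutamate
#' sp <- render_spectrum(multiplet_pattern(d, 4, sch),
#'                       spectrum_model(34.4), sch)
#' @export
render_spectrum <- function(pattern, model, scheme, total_area = 1) {
  if (!inherits(pattern, "multiplet_pattern"))
    tca_stop("pattern must be a multiplet_pattern", "tcaflux_input_error")
  if (abs(sum(pattern$components) - 1) > 1e-6)
    tca_stop("pattern fractions must sum to 1", "tcaflux_input_error")
  X <- multiplet_design(model, scheme, pattern$position)
  if (!identical(colnames(X), names(pattern$components)))
    tca_stop("pattern components do not match the coupling scheme",
             "tcaflux_input_error")
  warnings <- character(0)
  dx_hz <- (model$axis[2] - model$axis[1]) * model$freq_mhz
  min_j <- min(scheme$J[unique(c(scheme_neighbors(scheme, pattern$position),
                                 pattern$position))], na.rm = TRUE)
  if (min_j > 0 && min_j < dx_hz)
    warnings <- c(warnings, sprintf(
      "coupling splitting %.2f Hz below grid resolution %.2f Hz",
      min_j, dx_hz))
  y <- as.numeric(X %*% (total_area * pattern$components))
  if (model$noise_sd > 0) {
    if (exists(".Random.seed", globalenv())) {
      old_seed <- get(".Random.seed", globalenv())
      on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    }
    set.seed(model$seed)
    y <- y + rnorm(length(y), sd = model$noise_sd)
  }
  structure(list(ppm = model$axis, intensity = y, warnings = warnings,
                 model = model, position = pattern$position,
                 pool = pattern$pool),
            class = "tca_spectrum")
}

#' Recover multiplet component areas by line fitting
#'
#' Non-negative linear least squares with the line positions and couplings
#' fixed by the template; optionally refines a common linewidth by 1-D
#' search. The design is rejected as singular when component line patterns
#' fully overlap.
#'
#' @param spectrum A `"tca_spectrum"` or a numeric intensity vector on the
#'   template's grid.
#' @param model A [spectrum_model()] template declaring grid, center and
#'   linewidth (areas unknown).
#' @param scheme The [coupling_scheme()] of the resonance.
#' @param position Carbon position of the resonance.
#' @param refine_linewidth Optimize a common linewidth factor in
#'   `[0.25, 4]` (default `FALSE`).
#' @return An object of class `"tca_peakfit"`: non-negative `areas` per
#'   component, `residual_norm`, `converged`, `linewidth_hz`.
#' @export
fit_areas <- function(spectrum, model, scheme, position,
                      refine_linewidth = FALSE) {
  y <- if (inherits(spectrum, "tca_spectrum")) spectrum$intensity
       else as.numeric(spectrum)
  if (length(y) != length(model$axis))
    tca_stop("spectrum length does not match the template grid",
             "tcaflux_input_error")
  solve_lw <- function(lw) {
    X <- multiplet_design(model, scheme, position, linewidth_hz = lw)
    if (qr(X)$rank < ncol(X))
      tca_stop("singular line-fit design: component line patterns fully overlap",
               "tcaflux_conditioning_error")
    ans <- pracma::lsqnonneg(X, y)
    list(areas = stats::setNames(ans$x, colnames(X)),
         resid = sqrt(sum((y - as.numeric(X %*% ans$x))^2)))
  }
  lw <- model$linewidth_hz
  if (refine_linewidth) {
    obj <- function(f) solve_lw(lw * f)$resid
    opt <- stats::optimize(obj, c(0.25, 4))
    lw <- lw * opt$minimum
  }
  sol <- solve_lw(lw)
  structure(list(areas = sol$areas, residual_norm = sol$resid,
                 converged = TRUE, linewidth_hz = lw, position = position,
                 pool = scheme$pool),
            class = "tca_peakfit")
}

#' Convert recovered areas to multiplet area fractions
#'
#' @param peakfit A [fit_areas()] result.
#' @return A `"multiplet_pattern"` with fractions `areas / sum(areas)`;
#'   raises the zero-area error when the total recovered area is zero.
#' @export
areas_to_ratios <- function(peakfit) {
  if (!inherits(peakfit, "tca_peakfit"))
    tca_stop("peakfit must be a tca_peakfit", "tcaflux_input_error")
  total <- sum(peakfit$areas)
  if (total <= 0)
    tca_stop(sprintf(
      "zero signal area at position %d (no molecules labeled there): multiplet ratios undefined",
      peakfit$position), "tcaflux_zero_area_error")
  structure(list(position = peakfit$position, pool = peakfit$pool,
                 components = peakfit$areas / total),
            class = "multiplet_pattern")
}

#' Write a spectrum to two-column text or JCAMP-DX
#'
#' @param spectrum A `"tca_spectrum"` or list/data.frame with `ppm` and
#'   `intensity`.
#' @param path Output path.
#' @param format `"tsv"` (two columns: ppm, intensity) or `"jcamp"`
#'   (minimal JCAMP-DX with an XYPOINTS table).
#' @param title Title written into the JCAMP header.
#' @return Invisibly `path`.
#' @export
write_spectrum <- function(spectrum, path, format = c("tsv", "jcamp"),
                           title = "tcaflux spectrum") {
  format <- match.arg(format)
  ppm <- spectrum$ppm; y <- spectrum$intensity
  if (is.null(ppm) || is.null(y) || length(ppm) != length(y))
    tca_stop("spectrum must carry matching ppm and intensity vectors",
             "tcaflux_input_error")
  if (format == "tsv") {
    utils::write.table(data.frame(ppm = ppm, intensity = y), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("##TITLE=%s", title),
                 "##JCAMP-DX=4.24",
                 "##DATA TYPE=NMR SPECTRUM",
                 "##XUNITS=PPM", "##YUNITS=ARBITRARY UNITS",
                 sprintf("##NPOINTS=%d", length(ppm)),
                 sprintf("##FIRSTX=%.10g", ppm[1]),
                 sprintf("##LASTX=%.10g", ppm[length(ppm)]),
                 "##XYPOINTS=(XY..XY)"), con)
    writeLines(sprintf("%.10g, %.10g", ppm, y), con)
    writeLines("##END=", con)
  }
  invisible(path)
}

#' Read a spectrum written by [write_spectrum()]
#'
#' Autodetects JCAMP-DX (leading `##`) versus two-column delimited text.
#'
#' @param path Input path.
#' @return List with `ppm` and `intensity`.
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path))
    tca_stop(sprintf("file not found: %s", path), "tcaflux_io_error")
  first <- readLines(path, n = 1L, warn = FALSE)
  if (startsWith(first, "##")) {
    lines <- readLines(path, warn = FALSE)
    start <- grep("^##XYPOINTS=", lines)
    if (!length(start))
      tca_stop("JCAMP-DX file lacks an XYPOINTS table", "tcaflux_io_error")
    end <- grep("^##END=", lines)
    end <- end[end > start][1]
    body <- lines[(start + 1):(end - 1)]
    parts <- do.call(rbind, strsplit(body, ","))
    list(ppm = as.numeric(parts[, 1]), intensity = as.numeric(parts[, 2]))
  } else {
    x <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("ppm", "intensity") %in% names(x)))
      tca_stop("two-column spectrum must have ppm and intensity columns",
               "tcaflux_io_error")
    list(ppm = x$ppm, intensity = x$intensity)
  }
}
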