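# Readers, writers and validators for the canonical table and result
# formats. TSV is the canonical ratio-table dialect (comma accepted on
# read); UTF-8; header row mandatory. Fit results serialize to JSON with
# fixed key order and fixed float precision so identical runs produce
# byte-identical artifacts.

RATIO_COLUMNS <- c("sample_id", "condition", "pool", "position",
                   "multiplet", "ratio", "sem")

# Known multiplet labels per (pool, position).
known_labels <- function(pool, position) {
  sch <- coupling_scheme(pool)
  if (!(position %in% quantified_positions(pool))) return(character(0))
  vapply(multiplet_states(sch, position), `[[`, "", "label")
}

#' Validate a multiplet ratio table
#'
#' Checks the canonical layout: required columns; known pool names and
#' multiplet labels; ratios inside `[0, 1]`; non-negative `sem`; and
#' per-resonance sums within 0.02 of 1 (the measurement tolerance).
#' Violations raise a `"tcaflux_validation_error"` naming the offending
#' row numbers.
#'
#' @param x Ratio table `data.frame`.
#' @return Invisibly `TRUE` on success.
#' @export
validate_ratio_table <- function(x) {
  if (!is.data.frame(x))
    tca_stop("ratio table must be a data.frame", "tcaflux_validation_error")
  missing_cols <- setdiff(setdiff(RATIO_COLUMNS, "sem"), names(x))
  if (length(missing_cols))
    tca_stop(paste("ratio table missing column(s):",
                   paste(missing_cols, collapse = ", ")),
             "tcaflux_validation_error")
  if (nrow(x) == 0)
    tca_stop("ratio table has no rows", "tcaflux_validation_error")
  bad_pool <- which(!(x$pool %in% c("glutamate", "lactate")))
  if (length(bad_pool))
    tca_stop(paste("unknown pool in row(s):",
                   paste(head(bad_pool, 10), collapse = ", ")),
             "tcaflux_validation_error")
  ok_label <- mapply(function(p, pos, m) m %in% known_labels(p, pos),
                     x$pool, x$position, x$multiplet)
  if (any(!ok_label))
    tca_stop(paste("unknown multiplet label in row(s):",
                   paste(head(which(!ok_label), 10), collapse = ", ")),
             "tcaflux_validation_error")
  bad_ratio <- which(is.na(x$ratio) | x$ratio < 0 | x$ratio > 1)
  if (length(bad_ratio))
    tca_stop(paste("ratio outside [0, 1] in row(s):",
                   paste(head(bad_ratio, 10), collapse = ", ")),
             "tcaflux_validation_error")
  if ("sem" %in% names(x)) {
    bad_sem <- which(!is.na(x$sem) & x$sem < 0)
    if (length(bad_sem))
      tca_stop(paste("negative sem in row(s):",
                     paste(head(bad_sem, 10), collapse = ", ")),
               "tcaflux_validation_error")
  }
  key <- paste(x$sample_id, x$pool, x$position)
  sums <- tapply(x$ratio, key, sum)
  off <- names(sums)[abs(sums - 1) > 0.02]
  if (length(off)) {
    rows <- which(key %in% off)
    tca_stop(sprintf(
      "resonance fractions do not sum to 1 (+/- 0.02) for %s; row(s): %s",
      paste(head(off, 5), collapse = "; "),
      paste(head(rows, 20), collapse = ", ")),
      "tcaflux_validation_error")
  }
  invisible(TRUE)
}

#' Write a ratio table to delimited text
#'
#' @param x Ratio table `data.frame`.
#' @param path Output path; tab-separated, UTF-8, header row.
#' @return Invisibly `path`.
#' @export
write_ratio_table <- function(x, path) {
  validate_ratio_table(x)
  utils::write.table(x[intersect(RATIO_COLUMNS, names(x))], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a ratio table from delimited text
#'
#' Tab-separated canonical dialect; comma-separated accepted. The table is
#' validated on read.
#'
#' @param path Input path.
#' @return Ratio table `data.frame`.
#' @export
read_ratio_table <- function(path) {
  if (!file.exists(path))
    tca_stop(sprintf("file not found: %s", path), "tcaflux_io_error")
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  x <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (!("sem" %in% names(x))) x$sem <- NA_real_
  validate_ratio_table(x)
  x
}

#' Read a structured run configuration
#'
#' YAML with nested sections `tracer` (`enrichment`, `g`,
#' `natural_abundance`), `network` (`variant`), `solver` (`tolerance`,
#' `max_iterations`), `fit` (`seed`, `n_restarts`, `include_lactate`) and
#' optional `scenario`. Missing keys take package defaults.
#'
#' @param path Path to the YAML config.
#' @return List with class `"tca_config"` containing filled sections and
#'   the config `hash`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    tca_stop(sprintf("config file not found: %s", path), "tcaflux_io_error")
  raw <- yaml::read_yaml(path)
  defaults <- list(
    tracer = list(enrichment = 1, g = 2, natural_abundance = 0),
    network = list(variant = "FULL"),
    solver = list(tolerance = 1e-10, max_iterations = 10000L),
    fit = list(seed = 1L, n_restarts = 9L, include_lactate = TRUE),
    scenario = NULL)
  cfg <- modifyList(defaults, raw[names(raw) %in% names(defaults)])
  bad <- setdiff(names(raw), names(defaults))
  if (length(bad))
    tca_stop(paste("unknown config section(s):", paste(bad, collapse = ", ")),
             "tcaflux_validation_error")
  v <- toupper(cfg$network$variant)
  if (!(v %in% TCA_VARIANTS))
    tca_stop(sprintf("unknown network variant '%s' in config",
                     cfg$network$variant), "tcaflux_variant_error")
  cfg$network$variant <- v
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "tca_config")
}

# Stable content hash of an R object (md5 of its canonical serialization).
config_hash <- function(x) {
  x$hash <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(x), tmp)
  unname(tools::md5sum(tmp))
}

#' Serialize a fit result to JSON
#'
#' Fixed key order and fixed float precision, so identical runs produce
#' byte-identical artifacts. Includes the estimate, per-start trace,
#' optional confidence intervals, AICc and provenance (seed, variant,
#' tracer, config hash when supplied).
#'
#' @param fit A [fit_fluxes()] result.
#' @param path Output path.
#' @param config_hash Optional config hash recorded as provenance.
#' @return Invisibly `path`.
#' @export
write_fit_result <- function(fit, path, config_hash = NULL) {
  if (!inherits(fit, "tca_fit"))
    tca_stop("fit must be a tca_fit", "tcaflux_input_error")
  doc <- list(
    estimate = unclass(fit$estimate),
    objective = fit$objective,
    n_residuals = fit$n_residuals,
    aicc = fit$aicc,
    variant = fit$variant,
    ci = if (!is.null(fit$ci))
      list(level = fit$level,
           lower = as.list(stats::setNames(fit$ci[, "lower"], rownames(fit$ci))),
           upper = as.list(stats::setNames(fit$ci[, "upper"], rownames(fit$ci))))
    else NULL,
    starts = fit$starts,
    provenance = list(seed = fit$seed,
                      tracer = unclass(fit$tracer),
                      include_lactate = fit$include_lactate,
                      config_hash = config_hash))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = 10,
                           null = "null", dataframe = "rows")
  writeLines(json, path)
  invisible(path)
}

#' Read a fit result JSON written by [write_fit_result()]
#'
#' @param path Input path.
#' @return List mirroring the serialized document.
#' @export
read_fit_result <- function(path) {
  if (!file.exists(path))
    tca_stop(sprintf("file not found: %s", path), "tcaflux_io_error")
  jsonlite::fromJSON(readLines(path, warn = FALSE), simplifyVector = TRUE)
}
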