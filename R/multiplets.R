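# 13C-NMR multiplet calculator.
#
# A carbon resonance splits according to which adjacent carbons carry 13C:
# no labeled neighbor -> singlet (S); one labeled neighbor -> doublet (D,
# named by the coupled pair, e.g. D12); both neighbors labeled -> doublet of
# doublets, i.e. quartet (Q), unless the two one-bond couplings are equal
# within the collapse tolerance, in which case the lines merge into a 1:2:1
# triplet (T) and the two doublets merge into a single D. Multiplet area
# fractions are conditional probabilities of neighbor-labeling states among
# molecules labeled at the observed position, so they sum to 1 per
# resonance.

#' One-bond 13C-13C coupling scheme for a reporter metabolite
#'
#' Default couplings are literature-typical one-bond J constants (Hz):
#' glutamate J12 = 53, J23 = 34, J34 = 34, J45 = 51; lactate J12 = 55,
#' J23 = 35. Glutamate C3 sees two equal couplings, so its two-neighbor
#' state collapses to a triplet and its one-neighbor states merge into a
#' single doublet. Long-range (two-bond) couplings are not modeled.
#'
#' @param pool `"glutamate"` or `"lactate"`.
#' @param J Numeric vector of one-bond couplings in Hz, entry `i` coupling
#'   Ci to Ci+1; defaults as above.
#' @param collapse_tol Two couplings within this tolerance (Hz) produce a
#'   triplet rather than a quartet (default 1 Hz).
#' @return An object of class `"coupling_scheme"`.
#' @export
coupling_scheme <- function(pool = c("glutamate", "lactate"), J = NULL,
                            collapse_tol = 1) {
  pool <- match.arg(pool)
  if (collapse_tol <= 0)
    tca_stop("collapse_tol must be positive", "tcaflux_input_error")
  if (is.null(J))
    J <- switch(pool, glutamate = c(53, 34, 34, 51), lactate = c(55, 35))
  n <- length(J) + 1L
  structure(list(pool = pool, n_carbons = n, J = J,
                 prefix = switch(pool, glutamate = "C", lactate = "LC"),
                 collapse_tol = collapse_tol),
            class = "coupling_scheme")
}

# Neighbor positions of a carbon within the coupling chain.
scheme_neighbors <- function(scheme, position) {
  nb <- c(position - 1L, position + 1L)
  nb[nb >= 1L & nb <= scheme$n_carbons]
}

# Multiplet labels and the neighbor-labeling states they collect.
# Returns a list of list(label, states) where each state is a logical vector
# over the neighbors (TRUE = that neighbor labeled).
multiplet_states <- function(scheme, position) {
  nb <- scheme_neighbors(scheme, position)
  pre <- sprintf("%s%d", scheme$prefix, position)
  pair <- function(a, b) sprintf("D%d%d", min(a, b), max(a, b))
  if (length(nb) == 1L) {
    return(list(
      list(label = paste0(pre, "S"), states = list(c(FALSE))),
      list(label = paste0(pre, pair(position, nb)), states = list(c(TRUE)))))
  }
  j_left <- scheme$J[nb[1]]       # coupling to lower neighbor (nb[1], pos)
  j_right <- scheme$J[position]   # coupling to upper neighbor (pos, nb[2])
  merged <- abs(j_left - j_right) <= scheme$collapse_tol
  if (merged) {
    list(
      list(label = paste0(pre, "S"), states = list(c(FALSE, FALSE))),
      list(label = paste0(pre, "D"),
           states = list(c(TRUE, FALSE), c(FALSE, TRUE))),
      list(label = paste0(pre, "T"), states = list(c(TRUE, TRUE))))
  } else {
    list(
      list(label = paste0(pre, "S"), states = list(c(FALSE, FALSE))),
      list(label = paste0(pre, pair(nb[1], position)),
           states = list(c(TRUE, FALSE))),
      list(label = paste0(pre, pair(position, nb[2])),
           states = list(c(FALSE, TRUE))),
      list(label = paste0(pre, "Q"), states = list(c(TRUE, TRUE))))
  }
}

#' Multiplet area fractions at one carbon position
#'
#' Computes the singlet/doublet/triplet/quartet area fractions of the
#' resonance at `position`: the conditional probabilities of the
#' neighbor-labeling states among molecules that are 13C-labeled at the
#' position. Fractions sum to 1 per resonance.
#'
#' @param dist Isotopomer probability vector (length `2^n_carbons`).
#' @param position 1-based carbon index with at least one coupled neighbor.
#' @param scheme A [coupling_scheme()].
#' @return An object of class `"multiplet_pattern"`: list with `position`,
#'   `pool` and `components` (named fractions).
#' @examples
#' sch <- coupling_scheme("glutamate")
#' d <- numeric(32); d[bitwOr(8, 16) + 1] <- 1  # [4,5-13C2]glutamate
#' multiplet_pattern(d, 4, sch)$components
#' @export
multiplet_pattern <- function(dist, position, scheme) {
  if (!inherits(scheme, "coupling_scheme"))
    tca_stop("scheme must be a coupling_scheme", "tcaflux_input_error")
  n <- scheme$n_carbons
  if (length(dist) != 2^n)
    tca_stop("distribution length does not match the coupling scheme",
             "tcaflux_input_error")
  if (position < 1 || position > n)
    tca_stop("position outside the carbon chain", "tcaflux_input_error")
  nb <- scheme_neighbors(scheme, position)
  idx <- seq_along(dist) - 1L
  on_pos <- bitwAnd(idx, 2L^(position - 1L)) > 0L
  total <- sum(dist[on_pos])
  if (total <= 0)
    tca_stop(sprintf(
      "zero signal area at position %d (no molecules labeled there): multiplet ratios undefined",
      position), "tcaflux_zero_area_error")
  states <- multiplet_states(scheme, position)
  nb_on <- lapply(nb, function(p) bitwAnd(idx, 2L^(p - 1L)) > 0L)
  fractions <- vapply(states, function(st) {
    sum(vapply(st$states, function(s) {
      sel <- on_pos
      for (k in seq_along(nb)) sel <- sel & (nb_on[[k]] == s[k])
      sum(dist[sel])
    }, 0)) / total
  }, 0)
  names(fractions) <- vapply(states, `[[`, "", "label")
  structure(list(position = position, pool = scheme$pool,
                 components = fractions),
            class = "multiplet_pattern")
}

#' @export
print.multiplet_pattern <- function(x, ...) {
  cat(sprintf("%s C%d multiplet fractions:\n", x$pool, x$position))
  print(round(x$components, 4))
  invisible(x)
}

# Positions quantified per reporter pool: glutamate C2-C5, lactate C2.
quantified_positions <- function(pool) {
  switch(pool, glutamate = 2:5, lactate = 2L,
         tca_stop("unknown reporter pool", "tcaflux_input_error"))
}

#' Model-predicted multiplet signal-ratio table
#'
#' Converts steady-state isotopomer distributions into the noise-free
#' multiplet ratio table quantified in a 13C-NMR experiment: glutamate
#' C2-C5 and lactate C2, one row per (position, multiplet component), with
#' fractions normalized to the total area of the corresponding resonance.
#'
#' @param distributions Named list containing `AKG_GLU` and `LAC`
#'   isotopomer probability vectors, or a [steady_state()] result.
#' @param schemes List with entries `glutamate` and `lactate`
#'   ([coupling_scheme()] objects); defaults to the standard schemes.
#' @param sample_id,condition Labels written into the table.
#' @return A `data.frame` with columns `sample_id`, `condition`, `pool`,
#'   `position`, `multiplet`, `ratio`, `sem` (the canonical ratio-table
#'   layout; `sem` is `NA` for model predictions).
#' @export
signal_ratio_table <- function(distributions,
                               schemes = list(glutamate = coupling_scheme("glutamate"),
                                              lactate = coupling_scheme("lactate")),
                               sample_id = "model", condition = "model") {
  if (inherits(distributions, "tca_steady_state"))
    distributions <- distributions$distributions
  if (!all(c("AKG_GLU", "LAC") %in% names(distributions)))
    tca_stop("distributions must contain AKG_GLU and LAC pools",
             "tcaflux_input_error")
  src <- c(glutamate = "AKG_GLU", lactate = "LAC")
  rows <- list()
  for (pool in c("glutamate", "lactate")) {
    sch <- schemes[[pool]]
    d <- distributions[[src[[pool]]]]
    for (pos in quantified_positions(pool)) {
      mp <- multiplet_pattern(d, pos, sch)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_id, condition = condition, pool = pool,
        position = pos, multiplet = names(mp$components),
        ratio = unname(mp$components), sem = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# ---- fast extraction path used inside the fitting loop ------------------
#
# Precomputes, for each multiplet label, the 0/1 selector over isotopomer
# patterns (numerator) and the per-position labeled selector (denominator),
# so a predicted ratio vector is two small matrix products per pool. Kept
# separate from multiplet_pattern() and cross-checked against it in the
# tests.

ratio_extractors <- function(schemes = list(glutamate = coupling_scheme("glutamate"),
                                            lactate = coupling_scheme("lactate"))) {
  build <- function(sch) {
    n <- sch$n_carbons
    idx <- seq_len(2^n) - 1L
    labels <- character(0); num <- list(); den_pos <- integer(0)
    for (pos in quantified_positions(sch$pool)) {
      on_pos <- bitwAnd(idx, 2L^(pos - 1L)) > 0L
      nb <- scheme_neighbors(sch, pos)
      nb_on <- lapply(nb, function(p) bitwAnd(idx, 2L^(p - 1L)) > 0L)
      for (st in multiplet_states(sch, pos)) {
        sel <- Reduce(`+`, lapply(st$states, function(s) {
          v <- on_pos
          for (k in seq_along(nb)) v <- v & (nb_on[[k]] == s[k])
          as.numeric(v)
        }))
        labels <- c(labels, st$label)
        num[[length(num) + 1L]] <- sel
        den_pos <- c(den_pos, pos)
      }
    }
    positions <- sort(unique(den_pos))
    den <- t(vapply(positions, function(p)
      as.numeric(bitwAnd(idx, 2L^(p - 1L)) > 0L), numeric(2^n)))
    list(N = do.call(rbind, num), labels = labels,
         den = den, den_index = match(den_pos, positions),
         positions = positions, pool = sch$pool)
  }
  lapply(schemes, build)
}

# Predicted ratio vector (glutamate 13 + lactate 4 components) from the
# distributions; positions with vanishing signal take the unlabeled-neighbor
# limit (singlet -> 1) to keep the least-squares objective continuous.
extract_ratios <- function(distributions, extractors, eps = 1e-12) {
  out <- numeric(0)
  src <- c(glutamate = "AKG_GLU", lactate = "LAC")
  for (pool in names(extractors)) {
    ex <- extractors[[pool]]
    d <- distributions[[src[[pool]]]]
    num <- as.numeric(ex$N %*% d)
    den <- as.numeric(ex$den %*% d)[ex$den_index]
    r <- ifelse(den > eps, num / pmax(den, eps),
                as.numeric(endsWith(ex$labels, "S")))
    names(r) <- ex$labels
    out <- c(out, r)
  }
  out
}
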