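# Monte Carlo lineage-tracing oracle for the steady-state solver.
#
# Independent implementation: instead of iterating the distribution-level
# mixing map, each molecule of a pool is synthesized by stochastically
# back-tracing its biosynthetic lineage through the carbon-atom transition
# maps — choose an inflow term with probability equal to its mixing weight,
# recursively sample the source molecule(s), then assemble the product
# labeling pattern atom by atom. At steady state the marginal law of a
# molecule drawn this way equals the fixed point of the mixing map, so the
# empirical pattern frequencies cross-validate the algebraic solver.
#
# The recursion is run on an explicit work stack (lineages can span
# hundreds of pool visits when recycling weights are close to 1, which
# would exhaust the interpreter's call stack).

#' Sample molecules by stochastic lineage back-tracing
#'
#' @inheritParams steady_state
#' @param n_molecules Number of molecules to sample per pool (`>= 1`).
#' @param max_depth Bound on the depth of a single lineage, counted in
#'   recursive molecule visits (several visits per TCA turn). Beyond the
#'   bound a molecule is taken as unlabeled; the truncation bias is bounded
#'   by (largest recycling weight)^turns and is negligible at the default.
#' @param seed Integer seed; the caller's RNG state is restored on exit.
#' @param pools Character vector of pool names to sample (default: all).
#' @return An object of class `"tca_mc"`: list with `distributions` (named
#'   list of empirical probability vectors over labeling patterns) and
#'   `n_molecules`.
#' @examples
#' net <- build_tca_network("FULL")
#' mc <- sample_molecules(net, flux_params(0.6, 0.2, 0.1, 0.1),
#'                        tracer_spec(), n_molecules = 500, seed = 1,
#'                        pools = "AKG_GLU")
#' sum(mc$distributions$AKG_GLU)
#' @export
sample_molecules <- function(network, fluxes, tracer = tracer_spec(),
                             n_molecules, max_depth = 1000L, seed = 1L,
                             pools = NULL) {
  if (!inherits(network, "tca_network"))
    tca_stop("network must be a tca_network", "tcaflux_input_error")
  if (n_molecules < 1)
    tca_stop("n_molecules must be >= 1", "tcaflux_input_error")
  if (max_depth < 1)
    tca_stop("max_depth must be >= 1", "tcaflux_input_error")
  tr <- as_tracer_spec(tracer)
  w <- mixing_weights(network, fluxes, tr)
  pool_names <- names(network$pools)
  if (is.null(pools)) pools <- pool_names
  if (!all(pools %in% pool_names))
    tca_stop("unknown pool name(s) requested", "tcaflux_input_error")

  bit2 <- c(1L, 2L, 4L, 8L, 16L)
  n_pool <- length(pool_names)

  # Flattened per-pool term structure, indexed by pool id.
  targets <- vapply(network$terms, `[[`, "", "target")
  info <- lapply(pool_names, function(p) {
    ids <- which(targets == p)
    terms <- network$terms[ids]
    kind_code <- vapply(terms, function(t)
      switch(t$kind, unlabeled = 0L, tracer = 1L, map = 2L), 0L)
    list(
      cumw = cumsum(unname(w[ids])),
      kind = kind_code,
      srcs = lapply(terms, function(t) match(t$sources, pool_names)),
      vcum = lapply(terms, function(t)
        if (is.null(t$variants)) numeric(0)
        else cumsum(vapply(t$variants, `[[`, 0, "p"))),
      maps = lapply(terms, function(t)
        if (is.null(t$variants)) list() else lapply(t$variants, `[[`, "map")),
      n = network$pools[[p]],
      full = as.integer(2^network$pools[[p]] - 1)
    )
  })

  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(seed)

  cap <- 256L
  stk_map <- vector("list", cap)   # variant map of the open frame
  stk_srcs <- vector("list", cap)  # integer source pool ids
  stk_np <- integer(cap)           # product carbon count
  stk_depth <- integer(cap)
  stk_ci <- integer(cap)           # children completed
  stk_c1 <- integer(cap); stk_c2 <- integer(cap)

  # Resolve pool `p` at `depth`: either return the sampled pattern of a
  # leaf draw (tracer / unlabeled / truncation), or open a stack frame for
  # a carbon-map term and return NA.
  sp <- 0L
  open_or_draw <- function(p, depth) {
    if (depth > max_depth) return(0L)
    pi <- info[[p]]
    k <- findInterval(runif(1), pi$cumw, left.open = TRUE) + 1L
    kd <- pi$kind[k]
    if (kd == 0L) return(0L)
    if (kd == 1L) {
      if (runif(1) < tr$enrichment) return(pi$full) else return(0L)
    }
    vcum <- pi$vcum[[k]]
    v <- if (length(vcum) == 1L) 1L
         else findInterval(runif(1), vcum, left.open = TRUE) + 1L
    sp <<- sp + 1L
    if (sp > cap) {
      grow <- function(x) c(x, vector(mode(x), cap))
      length(stk_map) <<- cap * 2L
      length(stk_srcs) <<- cap * 2L
      stk_np <<- grow(stk_np); stk_depth <<- grow(stk_depth)
      stk_ci <<- grow(stk_ci); stk_c1 <<- grow(stk_c1); stk_c2 <<- grow(stk_c2)
      cap <<- cap * 2L
    }
    stk_map[[sp]] <<- pi$maps[[k]][[v]]
    stk_srcs[[sp]] <<- pi$srcs[[k]]
    stk_np[sp] <<- pi$n
    stk_depth[sp] <<- depth
    stk_ci[sp] <<- 0L
    NA_integer_
  }

  sample_one <- function(p) {
    sp <<- 0L
    res <- open_or_draw(p, 1L)
    if (!is.na(res)) return(res)
    repeat {
      srcs <- stk_srcs[[sp]]
      ci <- stk_ci[sp]
      if (ci < length(srcs)) {
        child <- open_or_draw(srcs[ci + 1L], stk_depth[sp] + 1L)
        if (!is.na(child)) {
          # leaf draw: record immediately
          if (ci == 0L) stk_c1[sp] <<- child else stk_c2[sp] <<- child
          stk_ci[sp] <<- ci + 1L
        }
        # else a frame was opened; descend
      } else {
        # all children sampled: assemble the product pattern
        map <- stk_map[[sp]]
        spat <- c(stk_c1[sp], stk_c2[sp])
        pat <- 0L
        for (cp in seq_len(stk_np[sp])) {
          slot <- map[cp, 1L]
          if (slot == 0L) next
          if (bitwAnd(spat[slot] %/% bit2[map[cp, 2L]], 1L) == 1L)
            pat <- pat + bit2[cp]
        }
        sp <<- sp - 1L
        if (sp == 0L) return(pat)
        ci <- stk_ci[sp]
        if (ci == 0L) stk_c1[sp] <<- pat else stk_c2[sp] <<- pat
        stk_ci[sp] <<- ci + 1L
      }
    }
  }

  dists <- lapply(pools, function(pname) {
    p <- match(pname, pool_names)
    n <- info[[p]]$n
    counts <- numeric(2L^n)
    for (m in seq_len(n_molecules)) {
      pat <- sample_one(p)
      if (tr$natural_abundance > 0) {
        for (c_i in seq_len(n)) {
          if (bitwAnd(pat %/% bit2[c_i], 1L) == 0L &&
              runif(1) < tr$natural_abundance)
            pat <- pat + bit2[c_i]
        }
      }
      counts[pat + 1L] <- counts[pat + 1L] + 1
    }
    setNames(counts / n_molecules, pattern_labels(n))
  })
  names(dists) <- pools

  structure(list(distributions = dists, n_molecules = n_molecules,
                 seed = seed, max_depth = max_depth),
            class = "tca_mc")
}
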