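# Shared fixtures: all data are generated in code at test time.

theta_star <- c(f_pdh = 0.7, y_pc = 0.35, pk = 0.25, y_s = 0.15)

flux_star <- function() flux_params(0.7, 0.35, 0.25, 0.15)

# index (1-based) of a labeling pattern given the labeled carbon positions
pat <- function(...) {
  carbons <- c(...)
  if (length(carbons) == 0) return(1L)
  sum(2L^(carbons - 1L)) + 1L
}

# reproducible admissible flux draw
random_fluxes <- function() {
  y_pc <- runif(1, 0.05, 0.5)
  y_s <- runif(1, 0.05, 0.4)
  flux_params(runif(1, 0.3, 0.9), y_pc, runif(1, 0, y_pc + y_s), y_s)
}

est_vec <- function(fit) unlist(fit$estimate[c("f_pdh", "y_pc", "pk", "y_s")])
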