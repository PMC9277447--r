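#!/usr/bin/env Rscript
# Stage 3: Welch comparisons of the per-sample flux estimates between
# conditions — the contrasts of interest are whether the MUL1 knockout
# raises pyruvate cycling (PK) and pyruvate carboxylase anaplerosis
# (Y_PC) relative to wild type, whether the inhibitors pull them back,
# and whether HIF-1a activation restores PK, Y_PC and Ys in the Akt2
# knockout. One-sided tests in the direction the presets encode.
# Output: results/contrasts.tsv.

suppressPackageStartupMessages(library(tcaflux))

tab <- read_ratio_table("results/ratios_all.tsv")
per_cond <- lapply(split(tab, tab$condition), fit_samples, seed = 1)
pull <- function(cond, fl)
  vapply(per_cond[[cond]]$fits, function(f) f$estimate[[fl]], 0)

contrasts <- list(
  list(a = "MUL1KO", b = "WT", fluxes = c("pk", "y_pc")),
  list(a = "MUL1KO", b = "MUL1KO_PERI", fluxes = c("pk", "y_pc")),
  list(a = "MUL1KO", b = "MUL1KO_CTM", fluxes = c("pk", "y_pc")),
  list(a = "WT", b = "AKT2KO", fluxes = "pk"),
  list(a = "AKT2KO_DMOG", b = "AKT2KO", fluxes = c("pk", "y_pc", "y_s")))

rows <- list()
for (ct in contrasts) {
  for (fl in ct$fluxes) {
    g <- group_compare(pull(ct$a, fl), pull(ct$b, fl),
                       alternative = "greater")
    rows[[length(rows) + 1L]] <- data.frame(
      flux = fl, higher = ct$a, lower = ct$b,
      mean_higher = g$mean_a, mean_lower = g$mean_b,
      t = g$statistic, df = g$df, p_one_sided = g$p_value)
    message(sprintf("%-5s %-12s > %-12s  t = %5.2f  p = %.2g %s",
                    fl, ct$a, ct$b, g$statistic, g$p_value,
                    ifelse(g$p_value <= 0.05, "*", "")))
  }
}
out <- do.call(rbind, rows)
utils::write.table(out, "results/contrasts.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
message("wrote results/contrasts.tsv")
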