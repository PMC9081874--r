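#!/usr/bin/env Rscript
# Single-node dynamics in the net-input coordinate: trace the bifurcation
# diagram of each nominal regime (fixed point, hysteresis, limit cycle),
# locate saddle-node and Hopf points, measure the limit-cycle envelope,
# and show how cell-density-style weight perturbations reshape the
# limit-cycle diagram. Exports TSV/JSON under results/bifurcation/ and, if
# ggplot2 is available, figures in results/figures/.

suppressPackageStartupMessages(library(wcnet))
out_dir <- "results/bifurcation"
fig_dir <- "results/figures"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
dir.create(fig_dir, showWarnings = FALSE, recursive = TRUE)

ranges <- list(fixed_point = c(-5, 6), hysteresis = c(-6, 4),
               limit_cycle = c(-5, 3))
diagrams <- list()
for (regime in names(ranges)) {
  d <- annotate_diagram(trace_branches(regime_params(regime), ranges[[regime]],
                                       161), envelope_points = 81)
  diagrams[[regime]] <- d
  r <- classify_regime(d)
  cat(sprintf("%-12s -> %s (%d folds, %d Hopf points)\n",
              regime, r$label, r$n_folds, r$n_hopfs))
  if (nrow(d$folds)) {
    cat("  folds at J_tot =", paste(round(d$folds$J_tot, 3), collapse = ", "), "\n")
  }
  if (nrow(d$hopfs)) {
    cat("  Hopf points at J_tot =",
        paste(round(d$hopfs$J_tot, 3), collapse = ", "),
        "(eigenfrequencies", paste(round(d$hopfs$im, 4), collapse = ", "),
        "rad/ms)\n")
  }
  write_diagram(d, file.path(out_dir, paste0(regime, ".tsv")))
  if (requireNamespace("ggplot2", quietly = TRUE)) {
    ggplot2::ggsave(file.path(fig_dir, paste0("bifurcation_", regime, ".png")),
                    plot_bifurcation(d), width = 6, height = 4, dpi = 150)
  }
}

# +/-10% weight perturbations of the limit-cycle regime, one mode per
# panel: excitatory outputs only, inhibitory outputs only, equal, opposed
cat("\nPerturbation study (limit-cycle regime, R = -0.1 .. 0.1):\n")
for (mode in c("e_only", "i_only", "equal", "opposed")) {
  st <- perturbation_study(regime_params("limit_cycle"),
                           seq(-0.1, 0.1, by = 0.05), mode = mode,
                           J_range = c(-4, 2), resolution = 101)
  hopfs <- t(vapply(st, function(d) range(d$hopfs$J_tot), numeric(2)))
  cat(sprintf("  mode %-8s Hopf window: %s\n", mode,
              paste(sprintf("[%.2f, %.2f]", hopfs[, 1], hopfs[, 2]),
                    collapse = " ")))
  for (nm in names(st)) {
    write_diagram(st[[nm]], file.path(out_dir,
                                      sprintf("perturbed_%s_%s.tsv", mode, nm)))
  }
}
cat("Diagrams exported to", out_dir, "\n")
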