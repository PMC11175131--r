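#!/usr/bin/env Rscript
# Regenerates the calibrated hazard-burst magnitudes packaged in
# R/presets.R. Run from the repository root after changing any generator
# default:
#   Rscript scripts/calibrate.R [--out scratch/calibration.csv]
# Uses the installed package if available, else loads the source tree.

args <- commandArgs(trailingOnly = TRUE)
out <- if (length(i <- which(args == "--out"))) args[i + 1] else "scratch/calibration.csv"

if (requireNamespace("gaitstab", quietly = TRUE)) {
  library(gaitstab)
} else {
  devtools::load_all(".", quiet = TRUE)
}

rows <- list()
for (env in c("A", "B", "C", "D")) {
  preset <- environment_preset(env)
  for (lev in 0:5) {
    s <- calibrate_hazard_magnitude(preset, lev, n_rep = 60, seed = 101)
    rows[[length(rows) + 1]] <- data.frame(
      environment = env, level = lev,
      target = preset$target_hazard_dtw_by_level[lev + 1],
      scale = round(as.numeric(s), 4),
      pilot_mean = round(attr(s, "pilot_mean"), 3))
    cat(sprintf("%s L%d: scale %.4f (pilot mean %.2f, target %.1f)\n",
                env, lev, as.numeric(s), attr(s, "pilot_mean"),
                preset$target_hazard_dtw_by_level[lev + 1]))
  }
}
tab <- do.call(rbind, rows)
dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
write.csv(tab, out, row.names = FALSE)

cat("\n.calibrated_magnitudes <- list(\n")
for (env in c("A", "B", "C", "D")) {
  v <- tab$scale[tab$environment == env]
  cat(sprintf("  %s = c(%s)%s\n", env, paste(sprintf("%.4f", v), collapse = ", "),
              if (env == "D") "" else ","))
}
cat(")\n")
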