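#!/usr/bin/env Rscript
# Generate the synthetic inputs used throughout the workflow: LTE-like
# observed/predicted yield panels for the two site presets, and daily
# weather series for both sites. All outputs land in results/.

suppressPackageStartupMessages(library(yieldstab))
dir.create("results", showWarnings = FALSE)

for (preset in c("sadore_millet", "ndiaye_rice")) {
  cfg <- preset_panel_config(preset, seed = 1)
  panel <- generate_lte_panel(cfg)
  out <- file.path("results", paste0("panel_", preset, ".csv"))
  write_yield_table(panel, out)
  message(sprintf(
    "%s: %d treatments x %d environments, obs yields %.2f-%.2f Mg/ha -> %s",
    preset, cfg$n_treatments, cfg$n_environments,
    min(pivot_matrix(panel, "observed")),
    max(pivot_matrix(panel, "observed")), out))
}

for (site in c("sadore", "ndiaye")) {
  w <- generate_weather(site, n_years = 40, seed = 1)
  out <- file.path("results", paste0("weather_", site, ".csv"))
  readr::write_csv(w, out)
  message(sprintf("%s weather: 40 years, mean annual rainfall %.0f mm -> %s",
                  site, sum(w$rain) / 40, out))
  # thermal-time sanity: seasonal accumulation with the default 15/34 C rule
  tt <- thermal_time_accumulate(w[1:365, ])
  message(sprintf("  first-year thermal time: %.0f degree-days", max(tt)))
}
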