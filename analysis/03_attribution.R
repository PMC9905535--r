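#!/usr/bin/env Rscript
# Drift attribution on the shifted phantom: Granger causality between the
# step-confounder indicator and the raw value stream (both directions),
# and recovery of the injected step from the window-750 MM curve.
#
# Findings with the shipped defaults (seed 20337): the confounder Granger-
# causes the stream (p ~ 1e-45), the reverse direction is not significant,
# and the recovered step magnitude is within a few tenths of the injected
# 5 ml, with the onset located within ~100 samples of 10,001.

library(cmrqc)

dir.create("results", showWarnings = FALSE)

config <- default_phantom_config()
injected <- inject_step(sample_bimodal(config), drift_spec(10001, 5))
med <- mixture_stats(config)$median

forward <- suppressWarnings(
  granger_test(injected$confounder, injected$series$value))
reverse <- suppressWarnings(
  granger_test(injected$series$value, injected$confounder))
print(forward)
print(reverse)

chart <- build_chart(injected$series, 750,
                     tolerance_interval("sv", med - 5, med + 5))
step <- estimate_step(chart)
print(step)

jsonlite::write_json(
  list(granger_forward = unclass(forward)[c("lag", "f_stat", "p_value", "n_obs")],
       granger_reverse = unclass(reverse)[c("lag", "f_stat", "p_value", "n_obs")],
       step = unclass(step),
       seed = config$seed),
  "results/03_attribution.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
message("written: results/03_attribution.json")
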