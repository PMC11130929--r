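#!/usr/bin/env Rscript
# Stage 1: synthetic survey generation.
#
# Generates one EMIS-like behavioural survey (n = 2763) per activity-group
# scenario, with categorical 12-month partner counts, ongoing-partnership
# status and PrEP-rule fields. Writes the surveys, their latent ground-truth
# counts and the generator configurations under results/surveys/.

library(msmnet)

out <- "results/surveys"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 2017

for (sc in names(scenario_targets())) {
  cfg <- generator_config(n_respondents = 2763, scenario = sc)
  sv <- generate_survey(cfg, seed = seed)
  write_survey(sv,
               file.path(out, paste0(sc, "_survey.csv")),
               file.path(out, paste0(sc, "_latent.csv")),
               file.path(out, paste0(sc, "_config.yaml")))
  lat <- attr(sv, "latent_counts")
  tot <- lat$steady + lat$casual
  cat(sprintf(
    "%-17s n=%d  latent totals: mean %.1f sd %.1f median %g IQR %g-%g\n",
    sc, nrow(sv), mean(tot), sd(tot), median(tot),
    quantile(tot, 0.25), quantile(tot, 0.75)))
}
cat("surveys written to", out, "\n")
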