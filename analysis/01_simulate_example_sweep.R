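#!/usr/bin/env Rscript
# Simulate one exemplar voltage-clamp sweep from the spinal P8-11 preset and
# export it in both container dialects together with its ground-truth event
# table. This is the entry point of the workflow: every downstream stage can
# be exercised against traces whose true kinetics are known.

library(minis)

seed <- 101
dir.create("results/example_sweep", recursive = TRUE, showWarnings = FALSE)

p <- preset("spinal_P8_11", events_per_cell = 40)
sim <- simulate_cell(p, cell_index = 1, seed = seed, sweep_duration = 30)

cat(sprintf("simulated %.0f s sweep: %d injected events, true tau_w %.2f ms\n",
            length(sim$trace$samples) / sim$trace$sampling_rate,
            nrow(sim$truth), tau_w_of(sim$config$kinetics)))

write_sweep_tsv(sim$trace, "results/example_sweep/sweep.tsv")
write_sweep_rds(sim$trace, "results/example_sweep/sweep.rds")
write_table_tsv(sim$truth, "results/example_sweep/truth.tsv")

# quick detection sanity check on the exemplar
ev <- detect_events(sim$trace, template_kinetics = sim$config$kinetics)
cat(sprintf("detected %d candidates, %d accepted (%d overlap-flagged)\n",
            nrow(ev), sum(ev$accepted), sum(ev$overlap)))
write_table_tsv(ev, "results/example_sweep/events.tsv")
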