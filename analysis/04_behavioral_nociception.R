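#!/usr/bin/env Rscript
# Behavioural nociception scoring: rotarod sensorimotor deficit, tail-flick
# thermal thresholds (as latencies and MPE), and von Frey mechanical response
# frequencies, each with the matching non-parametric test.

library(minis)

seed <- 101
dir.create("results", showWarnings = FALSE)

# rotarod: WT vs ob/ob, censored at 300 s
wt_rr <- simulate_behavior("rotarod_WT", n_subjects = 15, seed = seed)
ob_rr <- simulate_behavior("rotarod_obob", n_subjects = 15, seed = seed + 1)
mw <- compare_behavior(wt_rr$value, ob_rr$value, test = "mannwhitney")
cat(sprintf("rotarod: WT %.0f +- %.0f s, ob/ob %.0f +- %.0f s; Mann-Whitney p = %.2g\n",
            mean(wt_rr$value), sd(wt_rr$value),
            mean(ob_rr$value), sd(ob_rr$value), mw$p_value))

# tail flick at 50 C: latencies and MPE against the WT baseline mean
wt_tf <- simulate_behavior("tailflick_WT_50C", n_subjects = 20, seed = seed + 2)
ob_tf <- simulate_behavior("tailflick_obob_50C", n_subjects = 20, seed = seed + 3)
mw_tf <- compare_behavior(wt_tf$value, ob_tf$value, test = "mannwhitney")
cat(sprintf("tail flick 50C: WT %.1f s, ob/ob %.1f s; Mann-Whitney p = %.2g\n",
            mean(wt_tf$value), mean(ob_tf$value), mw_tf$p_value))
cat(sprintf("ob/ob MPE vs WT baseline: %.1f %%\n",
            mean(mpe(ob_tf$value, baseline = mean(wt_tf$value)))))

# von Frey response frequencies per filament
wt_vf <- simulate_behavior("vonfrey_WT", n_subjects = 20, seed = seed + 4)
ob_vf <- simulate_behavior("vonfrey_obob", n_subjects = 20, seed = seed + 5)
freq <- do.call(rbind, lapply(c(0.16, 0.4, 0.6, 1), function(f) {
  p_mw <- compare_behavior(wt_vf$value[wt_vf$filament_g == f],
                           ob_vf$value[ob_vf$filament_g == f],
                           test = "mannwhitney")$p_value
  data.frame(filament_g = f,
             wt_pct = vf_frequency(wt_vf$value[wt_vf$filament_g == f]),
             obob_pct = vf_frequency(ob_vf$value[ob_vf$filament_g == f]),
             mannwhitney_p = p_mw)
}))
print(freq)

trials <- rbind(wt_rr, ob_rr,
                wt_tf[setdiff(names(wt_tf), "temp_c")],
                ob_tf[setdiff(names(ob_tf), "temp_c")])
write_table_tsv(trials, "results/behavior_latency_trials.tsv")
write_table_tsv(rbind(wt_vf, ob_vf), "results/behavior_vonfrey_trials.tsv")
write_table_tsv(freq, "results/vonfrey_frequencies.tsv")
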