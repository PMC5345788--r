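#!/usr/bin/env Rscript
# Neurosteroid potentiation of mIPSC decay in the ob/ob cortex: simulate the
# control and allopregnanolone-incubation cohorts, run the pipeline, and
# express the treated weighted decay constants as a percentage of control
# (the scale on which the incubation effects are reported).

library(minis)

seed <- 101
dir.create("results", showWarnings = FALSE)

ctrl <- analyze_cohort("cortex_obob_ctrl", seed = seed)
cells <- list(ctrl)
effects <- list()
for (arm in c("cortex_obob_allo_100nM", "cortex_obob_allo_300nM")) {
  tre <- analyze_cohort(arm, seed = seed)
  cells[[length(cells) + 1L]] <- tre
  eff <- normalize_to_control(tre$tau_w[tre$included],
                              ctrl$tau_w[ctrl$included],
                              treatment_label = arm,
                              control_label = "cortex_obob_ctrl")
  print(eff)
  effects[[arm]] <- data.frame(treatment = arm,
                               percent_of_control = eff$percent_of_control,
                               dispersion = eff$dispersion,
                               n_treated = eff$n_treated,
                               n_control = eff$n_control)
}
all_cells <- do.call(rbind, cells)
write_table_tsv(all_cells, "results/cells_obob_allopregnanolone.tsv")
write_table_tsv(do.call(rbind, effects), "results/percent_of_control.tsv")

inc <- all_cells[all_cells$included, ]
omnibus <- cohort_compare(inc$tau_w, inc$preset, design = "anova_1way")
cat(sprintf("\nomnibus one-way ANOVA across arms: F = %.2f, p = %.3g\n",
            omnibus$statistic, omnibus$p_value))
if (!is.null(omnibus$posthoc)) print(omnibus$posthoc)
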