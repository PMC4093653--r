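#!/usr/bin/env Rscript
# Stage 5: map the EST pool against the representative library (E < 1e-5,
# best hit per read) and summarise expression per superfamily, with the
# DNA-transposon subtotal and a stacked-bar figure.

source("analysis/00_setup.R")

res <- run_pipeline(workflow_config(stage_upto("est")))

asg <- res$est_assignments
smry <- res$est_summary
message("ESTs mapped: ", sum(!is.na(asg$superfamily)), " of ", nrow(asg),
        " (total used as the percentage denominator: ",
        smry$total_te_ests, ")")
print(smry$per_superfamily)
message(sprintf("DNA-transposon subtotal: %d reads (%.1f%%)",
                smry$dna_te_subtotal$count, smry$dna_te_subtotal$percent))

plot_est_summary(smry, file.path(RESULTS_DIR, "est_summary.pdf"))

## truth check against the generator's source labels
truth_te <- res$ests$source != "background"
pred_te <- !is.na(asg$superfamily)
message(sprintf("TE/background separation: precision %.3f, recall %.3f",
                sum(truth_te & pred_te) / sum(pred_te),
                sum(truth_te & pred_te) / sum(truth_te)))
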