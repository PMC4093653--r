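#!/usr/bin/env Rscript
# Stage 1: build the truth-tracked synthetic genome and EST pool.
# Outputs: results/pipeline/sim/{genome.fa, truth.gff3, truth.tsv, ests.fa}

source("analysis/00_setup.R")

res <- run_pipeline(workflow_config(stage_upto("simulate")))

tr <- res$sim$truth
message("genome: ", nchar(res$sim$genome[[1]]), " bp on ",
        length(res$sim$genome), " sequence(s)")
message("planted elements by superfamily:")
print(table(tr$superfamily))
message("planted families: ", length(unique(tr$family)))
message("EST pool: ", nrow(res$ests), " reads, ",
        sum(res$ests$source != "background"), " from element bodies")
message("divergence range: ",
        paste(round(range(tr$divergence), 3), collapse = " - "))
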