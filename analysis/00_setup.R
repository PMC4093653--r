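# Shared configuration for the analysis workflow. Each numbered script
# sources this file, then runs one stage of the annotation over the same
# seeded synthetic genome; per-stage caching in results/pipeline makes the
# scripts independently re-runnable and cheap to iterate on.

library(beanTE)

RESULTS_DIR <- "results"
PIPELINE_DIR <- file.path(RESULTS_DIR, "pipeline")
SEED <- 2024L

dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

# Study conditions: a 1-Mb genome carrying intact elements of every
# supported superfamily (20 LTR retroelements among them), plus a 600-read
# EST pool with 30% of reads drawn from element bodies.
workflow_config <- function(stages) {
  pipeline_config(
    out_dir = PIPELINE_DIR,
    sim = sim_config(genome_length = 1e6, rng_seed = SEED),
    stages = stages
  )
}

ALL_STAGES <- c("simulate", "ltr", "homology", "classify", "families",
                "est", "orf", "phylo")

stage_upto <- function(stage) ALL_STAGES[seq_len(match(stage, ALL_STAGES))]
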