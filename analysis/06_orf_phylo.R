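#!/usr/bin/env Rscript
# Stage 6: ORF-layout annotation of the accepted LTR elements
# (retrotransposase-only vs envelope-like sense extra ORF vs antisense
# ORF2) and the neighbor-joining tree of reverse-transcriptase domains.

source("analysis/00_setup.R")

res <- run_pipeline(workflow_config(ALL_STAGES))

ann <- res$orf_annotations
message("annotated LTR elements: ", nrow(ann))
print(table(ann$superfamily, ann$layout_class))
print(layout_census(ann))

## clade report: do ORF2-carrying elements form their own clade?
if (!is.null(res$tree)) {
  message("RT tree with ", length(res$tree$tip.label), " leaves written to ",
          file.path(PIPELINE_DIR, "rt_tree.nwk"))
  orf2_el <- ann[ann$layout_class == "orf2_antisense", ]
  groups <- character(0)
  for (i in seq_len(nrow(orf2_el))) {
    hit <- grep(sprintf("^%s_", orf2_el$seq_id[i]), res$tree$tip.label,
                value = TRUE)
    inside <- hit[vapply(strsplit(hit, "_"), function(p) {
      as.integer(p[2]) >= orf2_el$start[i] &&
        as.integer(p[3]) <= orf2_el$end[i]
    }, TRUE)]
    groups[inside] <- "orf2"
  }
  if (length(groups) >= 2) {
    rep <- clade_report(res$tree, groups)
    print(rep)
    write_tsv(rep, file.path(RESULTS_DIR, "orf2_clade_report.tsv"))
  }
}
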