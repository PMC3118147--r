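#!/usr/bin/env Rscript
# PARE (degradome) cleavage profiling of the simulated tag library over
# the 1 kb precursor context, in TP10M units, with modal-site calling.
# The planted dominant cleavage site is the 5' end of the ACR3 product.

library(phasemir)

targets <- read_rna_fasta("results/inputs/pare_context.fa")
tags <- read_count_table("results/inputs/pare_tags.tsv")
lib <- pare_library("pare_1", tags, total_reads = sum(tags$count))

prof <- pare_profile(lib, targets)
agg <- aggregate_profiles(list(prof))
utils::write.table(as.data.frame(agg), "results/pare_profile.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

modal <- attr(agg, "modal_sites")
cat(sprintf("total mapped cleavage signal: %.0f TP10M over %d sites\n",
            sum(agg$tp10m_max), nrow(agg)))
cat(sprintf("modal cleavage site: position %d\n", modal[["context1"]]))

# restrict to the precursor interval for the stem-loop-local view
g <- gen_hairpin(hairpin_spec(seed = 20110512L + 1))
ctx <- embed_precursor(g$hairpin, 1000, seed = 20110512L + 200)
local <- profile_window(agg, "context1",
                        c(ctx$offset, ctx$offset + nchar(g$hairpin$seq)))
utils::write.table(local, "results/pare_profile_precursor.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("%d cleavage sites fall inside the stem-loop\n", nrow(local)))
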