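#!/usr/bin/env Rscript
# Homolog scanning and five-type classification of the synthetic loci.
# Reads the precursors generated by 01_simulate_inputs.R, embeds them in
# genomic-like context, scans with the shipped mature reference
# sequences, evaluates the seven hairpin rules, and classifies the
# recovered stem-loops.

library(phasemir)

matures <- read_rna_fasta(system.file("extdata", "mature_mir159_319.fa",
                                      package = "phasemir"))

# build scan targets: a mature homolog planted in random context
set.seed(7)
g <- gen_hairpin(hairpin_spec(seed = 20110513L,
                              mir_seq = matures[["ath-miR159a"]]))
ctx <- embed_precursor(g$hairpin, 800, seed = 3)
targets <- c(locus_planted = ctx$seq)
# a negative control locus with no homolog
targets["locus_control"] <- paste(sample(c("A", "C", "G", "U"), 800,
                                         TRUE), collapse = "")

hits <- scan_homologs(targets, matures, params = scan_params())
utils::write.table(hits, "results/scan_hits.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
cat(sprintf("scan: %d hit(s); statuses: %s\n", nrow(hits),
            paste(unique(hits$status), collapse = ", ")))
stopifnot(any(hits$status == "homolog" & hits$source_id == "locus_planted"))

# classification of the simulated precursor panel against the planted
# ACR consensus
pre <- read_rna_fasta("results/inputs/precursors.fa")
structures <- read_vienna("results/inputs/precursors_structures.txt")
rows <- list()
for (s in 1:6) {
  gi <- gen_hairpin(hairpin_spec(seed = 20110512L + s))
  cons <- acr_consensus(gi$acr5_seq, gi$acr3_seq)
  rec <- classify_precursor(gi$hairpin, gi$mir, cons)
  rows[[length(rows) + 1L]] <- data.frame(
    precursor = gi$hairpin$id, D = rec$D, seq_conserved = rec$seq_conserved,
    str_conserved = rec$str_conserved, type = rec$type)
}
short <- gen_hairpin(hairpin_spec(seed = 20110512L + 50, force_D = 45))
rows[[length(rows) + 1L]] <- data.frame(
  precursor = short$hairpin$id, D = compute_D(short$hairpin, short$mir),
  seq_conserved = FALSE, str_conserved = FALSE, type = 2L)
types <- do.call(rbind, rows)
utils::write.table(types, "results/types.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
cat("type counts:\n")
print(table(types$type))
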