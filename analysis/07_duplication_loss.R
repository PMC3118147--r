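#!/usr/bin/env Rscript
# Duplication/loss inference: LCA reconciliation of the simulated gene
# tree against its species tree, compared with the generator's true
# event log (reconciliation is a parsimony lower bound on the truth).

library(phasemir)
library(ape)

gt <- read.tree("results/inputs/gene_tree.nwk")
st <- read.tree("results/inputs/species_tree.nwk")
map_tab <- utils::read.delim("results/inputs/tip_map.tsv")
tip_map <- setNames(map_tab$species, map_tab$gene)

rec <- reconcile(gt, st, tip_map)
cat(sprintf("reconciliation: %d duplication(s), %d loss(es)\n",
            rec$n_dup, rec$n_loss))
nodes <- length(gt$tip.label) + seq_len(gt$Nnode)
events <- data.frame(
  gene_node = nodes,
  species_node = rec$mapping[nodes],
  event = ifelse(nodes %in% rec$duplications, "duplication", "speciation"))
utils::write.table(events, "results/reconciliation_events.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(rec$losses, "results/reconciliation_losses.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

fam_truth <- gen_family(st, dup_rate = 0.35, loss_rate = 0.15,
                        seed = 20110512L + 400)
cat(sprintf("true simulated history: %d duplication(s), %d loss(es)\n",
            fam_truth$n_dup_true, fam_truth$n_loss_true))
stopifnot(rec$n_dup <= fam_truth$n_dup_true,
          rec$n_loss <= fam_truth$n_loss_true)
cat("parsimony lower bound respected\n")
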