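#!/usr/bin/env Rscript
# Generates the synthetic study inputs used by the downstream analysis
# steps: stem-loop precursors with known geometry, small-RNA libraries
# with planted partition proportions, PARE tag libraries with planted
# cleavage hot-spots, an evolved structural alignment, and a gene family
# with a known duplication/loss history. Everything is seeded, so the
# whole workflow is reproducible end to end.

library(phasemir)
library(ape)

dir.create("results", showWarnings = FALSE)
dir.create("results/inputs", showWarnings = FALSE)
seed <- 20110512L  # workflow base seed

## precursors: one clean type-1 stem-loop per seed, plus degraded forms
precursors <- list()
schemes <- list()
for (s in 1:6) {
  g <- gen_hairpin(hairpin_spec(seed = seed + s))
  precursors[[g$hairpin$id]] <- g
  schemes[[g$hairpin$id]] <- g$scheme
}
short <- gen_hairpin(hairpin_spec(seed = seed + 50, force_D = 45))
precursors[[short$hairpin$id]] <- short

write_rna_fasta(vapply(precursors, function(g) g$hairpin$seq, character(1)),
                "results/inputs/precursors.fa")
write_vienna(lapply(precursors, function(g) {
  list(seq = g$hairpin$seq, structure = render_dotbracket(g$hairpin$ss))
}), "results/inputs/precursors_structures.txt")
write_partitions(Filter(Negate(is.null), schemes),
                 "results/inputs/partitions.bed")
cat(sprintf("wrote %d precursors (%d with nine-partition schemes)\n",
            length(precursors), length(Filter(Negate(is.null), schemes))))

## small-RNA libraries: wild type with canonical proportions, a mutant
## with the ACR3 product selectively up-regulated, two replicates each
g1 <- precursors[[1]]
wt_props <- c(miR = 0.70, `miR*` = 0.08, ACR5 = 0.05, ACR3 = 0.07,
              leak = 0.10)
mut_props <- c(miR = 0.45, `miR*` = 0.05, ACR5 = 0.05, ACR3 = 0.38,
               leak = 0.07)
manifest <- data.frame()
for (r in 1:2) {
  for (geno in c("wt", "mut")) {
    props <- if (geno == "wt") wt_props else mut_props
    gl <- gen_library(g1$hairpin, g1$scheme, props, depth = 5e4,
                      seed = seed + 100 + r * 10 + (geno == "mut"),
                      sample_id = sprintf("%s_rep%d", geno, r))
    f <- sprintf("results/inputs/srna_%s_rep%d.tsv", geno, r)
    utils::write.table(gl$library$records, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest <- rbind(manifest, data.frame(
      sample_id = gl$library$sample_id, file = basename(f),
      total_reads = gl$library$total_reads, genotype = geno, replicate = r))
  }
}
utils::write.table(manifest, "results/inputs/srna_manifest.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("wrote %d small-RNA libraries (planted wt miR %.0f%%, mut ACR3 %.0f%%)\n",
            nrow(manifest), 100 * wt_props[["miR"]], 100 * mut_props[["ACR3"]]))

## PARE library over a 1 kb context with the precursor at the centre
ctx <- embed_precursor(g1$hairpin, 1000, seed = seed + 200)
acr3_start <- ctx$offset + g1$scheme$start[g1$scheme$name == "ACR3"]
mir_start <- ctx$offset + g1$scheme$start[g1$scheme$name == "miR"]
hot <- setNames(c(0.55, 0.30, 0.15),
                c(acr3_start, mir_start, ctx$offset + 5))
gp <- gen_pare(ctx$seq, hot, depth = 2e4, seed = seed + 201)
write_rna_fasta(c(context1 = ctx$seq), "results/inputs/pare_context.fa")
utils::write.table(gp$library$tags, "results/inputs/pare_tags.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("wrote PARE library: planted modal 5' end at %d (ACR3 start)\n",
            gp$modal_site))

## structural alignment evolved on a 24-taxon tree
set.seed(seed + 300)
tree24 <- rtree(24, rooted = FALSE)
tree24$edge.length <- tree24$edge.length * 0.15
model <- subst_model(exch = c(1, 4, 1, 1, 4, 1),
                     base_freqs = c(0.28, 0.22, 0.24, 0.26),
                     doublet_freqs = doublet_freqs_canonical(), alpha = 1)
ev <- evolve_alignment(tree24, model, n_pairs = 30, n_unpaired = 60,
                       seed = seed + 301)
write_stockholm(ev$aln, "results/inputs/family_alignment.sto")
saveRDS_path <- "results/inputs/planted_pairs.tsv"
utils::write.table(data.frame(i = ev$partition$pairs[, 1],
                              j = ev$partition$pairs[, 2]),
                   saveRDS_path, sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("wrote evolved alignment: %d rows x %d columns, %d planted pairs\n",
            nrow(ev$aln), ncol(ev$aln), nrow(ev$partition$pairs)))

## gene family on a small land-plant-like species tree
sp_tree <- read.tree(text = "((((eudicot:1,monocot:1):1,gymnosperm:1.5):1,lycopod:2.5):1,moss:3.5);")
fam <- gen_family(sp_tree, dup_rate = 0.35, loss_rate = 0.15,
                  seed = seed + 400)
write.tree(fam$gene_tree, "results/inputs/gene_tree.nwk")
write.tree(sp_tree, "results/inputs/species_tree.nwk")
utils::write.table(data.frame(gene = names(fam$tip_map),
                              species = unname(fam$tip_map)),
                   "results/inputs/tip_map.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
cat(sprintf("wrote gene family: %d genes, true history %d duplications / %d losses\n",
            length(fam$gene_tree$tip.label), fam$n_dup_true, fam$n_loss_true))
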