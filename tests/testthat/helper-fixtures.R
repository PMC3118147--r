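# Shared fixtures: the canonical study conditions used across tests.

# fixed 6-taxon tree for the topology-recovery study (conserved-family
# divergence: tip branches ~0.1, internal branches >= 0.05)
fixture_tree6 <- function() {
  ape::read.tree(
    text = "((A:0.12,B:0.10):0.08,(C:0.11,D:0.09):0.07,(E:0.10,F:0.13):0.06);")
}

# simulation model for alignment evolution: mild transition bias, stem
# columns dominated by canonical pairs
fixture_model <- function(alpha = 1.0) {
  phasemir::subst_model(exch = c(1, 4, 1, 1, 4, 1),
                        base_freqs = c(0.28, 0.22, 0.24, 0.26),
                        doublet_freqs = phasemir::doublet_freqs_canonical(),
                        alpha = alpha)
}

# neutral starting model for inference (the sampler estimates the rest)
fixture_start_model <- function() {
  phasemir::subst_model(doublet_freqs = phasemir::doublet_freqs_canonical())
}

# random rooted species/gene instance for reconciliation tests
fixture_recon_instance <- function(seed) {
  set.seed(seed)
  nsp <- sample(3:5, 1)
  st <- ape::rtree(nsp, tip.label = LETTERS[seq_len(nsp)])
  repeat {
    fam <- try(phasemir::gen_family(st, dup_rate = runif(1, 0.1, 0.5),
                                    loss_rate = runif(1, 0.05, 0.3),
                                    seed = seed), silent = TRUE)
    if (!inherits(fam, "try-error") &&
        length(fam$gene_tree$tip.label) <= 8) {
      return(list(species = st, fam = fam))
    }
    seed <- seed + 10000L
  }
}

# mature miRNA reference sequences shipped with the package
fixture_matures <- function() {
  phasemir::read_rna_fasta(system.file("extdata", "mature_mir159_319.fa",
                                       package = "phasemir"))
}

# random point on the k-simplex
rdirichlet1 <- function(k) {
  x <- stats::rgamma(k, 1)
  x / sum(x)
}
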