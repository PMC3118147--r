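test_that("prior-only sampling is uniform over 4-taxon topologies", {
  # 4 taxa: three unrooted topologies, one non-trivial split each
  aln <- structural_alignment(c(a = "ACGUACGUAC", b = "ACGUACGUAC",
                                c = "ACGUACGUAC", d = "ACGUACGUAC"))
  res <- mcmc_run(aln, site_partition(10), fixture_start_model(),
                  mcmc_config(n_generations = 30000, sample_interval = 10,
                              n_runs = 1, burn_in = 0.2, seed = 5),
                  estimate = character(0), prior_only = TRUE)
  trees <- res$runs[[1]]$trees[res$keep]
  freq <- oracle_split_freqs(trees)
  expect_equal(length(freq), 3)
  expect_true(all(abs(freq - 1 / 3) < 0.06))
})

test_that("majority consensus counts splits correctly", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  # all identical -> that topology with pp 100
  cons <- majority_consensus(rep(c(t1), 10))
  expect_true(setequal(phasemir:::tree_splits(cons),
                       phasemir:::tree_splits(t1)))
  expect_true(all(setdiff(cons$node.label, "") == "100"))
  # 60/40 mixture: majority topology, contested split at 60
  t2 <- ape::read.tree(text = "((a,c),(b,d),e);")
  mix <- c(rep(c(t1), 6), rep(c(t2), 4))
  cons2 <- majority_consensus(mix)
  expect_true("a|b" %in% phasemir:::tree_splits(cons2) ||
                setequal(phasemir:::tree_splits(cons2),
                         phasemir:::tree_splits(t1)))
  expect_true("60" %in% cons2$node.label)
  # random samples: splits with freq > 0.5 match brute-force counting
  set.seed(9)
  samp <- lapply(1:30, function(i) ape::rtree(6, rooted = FALSE))
  class(samp) <- "multiPhylo"
  cons3 <- majority_consensus(samp)
  freqs <- oracle_split_freqs(samp)
  expect_true(setequal(phasemir:::tree_splits(cons3),
                       names(freqs)[freqs > 0.5]))
  # and agrees with ape's strict majority consensus topologically
  cons_ape <- ape::consensus(samp, p = 0.5)
  expect_true(setequal(phasemir:::tree_splits(cons3),
                       phasemir:::tree_splits(ape::unroot(cons_ape))))
})

test_that("duplicate taxa are collapsed and reinserted", {
  m <- unclass(structural_alignment(c(
    a = "ACGUACGU", b = "ACGUACGU", c = "ACGUACGU",
    d = "GGGGCCCC", e = "GGGACCCC", f = "AAAAUUUU")))
  dd <- dedup_rows(structural_alignment(m))
  expect_equal(nrow(dd$aln), 4)
  expect_equal(dd$map, list(a = c("a", "b", "c")))
  # no duplicates: identity
  dd2 <- dedup_rows(structural_alignment(m[4:6, ]))
  expect_equal(length(dd2$map), 0)
  tree <- ape::read.tree(text = "((a:0.2,d:0.1):0.05,(e:0.1,f:0.3):0.02);")
  back <- reinsert_taxa(tree, dd$map)
  expect_true(setequal(back$tip.label, c("a", "b", "c", "d", "e", "f")))
  ids <- match(c("a", "b", "c"), back$tip.label)
  bl <- back$edge.length[match(ids, back$edge[, 2])]
  expect_equal(bl, rep(0.001, 3))
  parent <- unique(back$edge[match(ids, back$edge[, 2]), 1])
  expect_equal(length(parent), 1)
  expect_true("100" %in% back$node.label)
})

test_that("internal branch lengths are recovered at the full study scale", {
  # a single 2000-column dataset carries per-branch sampling noise of a
  # few thousandths of a substitution/site, so the 15% recovery claim is
  # checked on posterior means averaged over three simulated datasets
  tru <- fixture_tree6()
  n <- length(tru$tip.label)
  true_int <- data.frame(
    split = vapply((n + 2L):(n + tru$Nnode), function(nd) {
      tips <- tru$tip.label[unlist(phangorn_free_desc(tru, nd))]
      taxa <- sort(tru$tip.label)
      side <- if (taxa[1] %in% tips) setdiff(taxa, tips) else tips
      paste(sort(side), collapse = "|")
    }, character(1)),
    bl = tru$edge.length[match((n + 2L):(n + tru$Nnode), tru$edge[, 2])])
  est <- matrix(NA_real_, 3, nrow(true_int),
                dimnames = list(NULL, true_int$split))
  for (d in 1:3) {
    ev <- evolve_alignment(tru, fixture_model(), n_pairs = 100,
                           n_unpaired = 1800, seed = 100 + d)
    res <- mcmc_run(ev$aln, ev$partition,
                    config = mcmc_config(n_generations = 100000,
                                         seed = 40 + d))
    post <- list()
    for (tr in res$pooled) {
      nn <- length(tr$tip.label)
      for (nd in (nn + 1L):(nn + tr$Nnode)) {
        tips <- tr$tip.label[unlist(phangorn_free_desc(tr, nd))]
        taxa <- sort(tr$tip.label)
        side <- if (taxa[1] %in% tips) setdiff(taxa, tips) else tips
        if (length(side) < 2 || length(side) > nn - 2) next
        key <- paste(sort(side), collapse = "|")
        e <- match(nd, tr$edge[, 2])
        if (!is.na(e)) post[[key]] <- c(post[[key]], tr$edge.length[e])
      }
    }
    for (k in seq_len(nrow(true_int))) {
      est[d, k] <- mean(post[[true_int$split[k]]])
    }
  }
  for (k in seq_len(nrow(true_int))) {
    mu <- mean(est[, k])
    expect_lt(abs(mu - true_int$bl[k]) / true_int$bl[k], 0.15,
              label = sprintf("split %s: %.3f vs %.3f",
                              true_int$split[k], mu, true_int$bl[k]))
  }
})

test_that("a short run recovers a strongly supported 4-taxon topology", {
  tru <- ape::read.tree(text = "((a:0.15,b:0.12):0.1,(c:0.13,d:0.11):0.1);")
  m <- fixture_model()
  ev <- evolve_alignment(tru, m, n_pairs = 20, n_unpaired = 300, seed = 3)
  res <- mcmc_run(ev$aln, ev$partition, fixture_start_model(),
                  mcmc_config(n_generations = 20000, n_runs = 2, seed = 11))
  cons <- majority_consensus(res$pooled)
  expect_true(setequal(phasemir:::tree_splits(cons),
                       phasemir:::tree_splits(ape::unroot(tru))))
  expect_lt(res$asdsf, 0.1)
  # alpha is sampled and stays in a sane range around the truth
  al <- unlist(lapply(res$runs, function(r) r$alpha[res$keep]))
  expect_gt(mean(al), 0.3)
  expect_lt(mean(al), 3)
})
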