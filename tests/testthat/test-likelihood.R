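test_that("pruning equals exhaustive state summation on 4-taxon data", {
  set.seed(50)
  for (case in 1:40) {
    tr <- ape::rtree(4, rooted = FALSE)
    tr$edge.length <- runif(nrow(tr$edge), 0.02, 1.5)
    m <- subst_model(exch = rexp(6) + 0.2,
                     base_freqs = as.numeric(rdirichlet1(4)),
                     doublet_freqs = as.numeric(rdirichlet1(16)),
                     alpha = runif(1, 0.3, 3))
    n_up <- sample(0:4, 1)
    n_pr <- sample(0:2, 1)
    if (n_up + n_pr == 0) n_up <- 1
    ev <- evolve_alignment(tr, m, n_pairs = n_pr, n_unpaired = n_up,
                           seed = case)
    got <- phylo_loglik(ev$aln, ev$partition, tr, m)
    st <- states_for_oracle(ev$aln, ev$partition, tr)
    want <- 0
    if (ncol(st$s4)) {
      want <- want + oracle_loglik(st$s4, tr, gtr_rate_matrix(m),
                                   m$base_freqs, m$alpha, m$ncat)
    }
    if (ncol(st$s16)) {
      want <- want + oracle_loglik(st$s16, tr, doublet_rate_matrix(m),
                                   m$doublet_freqs, m$alpha, m$ncat)
    }
    expect_lt(abs(got - want), 1e-10)
  }
})

test_that("two-sequence likelihood limits behave", {
  m <- subst_model(base_freqs = c(0.4, 0.2, 0.25, 0.15))
  two <- function(t) {
    ape::read.tree(text = sprintf("(a:%g,b:%g);", t / 2, t / 2))
  }
  aln_same <- structural_alignment(c(a = "A", b = "A"))
  sp <- site_partition(1)
  # t -> 0: per-site likelihood -> stationary frequency of the state
  ll0 <- phylo_loglik(aln_same, sp, two(1e-9), m)
  expect_equal(ll0, log(0.4), tolerance = 1e-6)
  # t -> infinity: likelihood -> product of stationary frequencies
  aln_diff <- structural_alignment(c(a = "A", b = "C"))
  llinf <- phylo_loglik(aln_diff, sp, two(500), m)
  expect_equal(llinf, log(0.4 * 0.2), tolerance = 1e-4)
})

test_that("doublet likelihood factorizes for independent uniform doublets", {
  # with uniform base frequencies, shared exchangeabilities and doublet
  # frequencies equal to the outer product, the normalized doublet chain
  # is two independent GTR coordinates running at half speed (one
  # doublet substitution = one nucleotide substitution); the likelihood
  # of a doublet column at branch length t equals the sum of the two
  # single-column likelihoods at t/2
  set.seed(60)
  for (case in 1:10) {
    exch <- rexp(6) + 0.2
    alpha <- runif(1, 0.5, 3)
    m <- subst_model(exch = exch, base_freqs = rep(0.25, 4), alpha = alpha,
                     ncat = 1L)  # single category: rates do not couple
    t <- runif(1, 0.05, 1.2)
    x <- sample(c("A", "C", "G", "U"), 2, TRUE)
    y <- sample(c("A", "C", "G", "U"), 2, TRUE)
    aln_pair <- structural_alignment(
      c(a = paste0(x[1], y[1]), b = paste0(x[2], y[2])))
    tr_t <- ape::read.tree(text = "(a:1,b:1);")
    tr_t$edge.length <- c(t / 2, t / 2)
    tr_h <- tr_t
    tr_h$edge.length <- c(t / 4, t / 4)
    ll_doublet <- phylo_loglik(aln_pair, site_partition(2, rbind(c(0, 1))),
                               tr_t, m)
    aln_1 <- structural_alignment(c(a = x[1], b = x[2]))
    aln_2 <- structural_alignment(c(a = y[1], b = y[2]))
    ll_single <- phylo_loglik(aln_1, site_partition(1), tr_h, m) +
      phylo_loglik(aln_2, site_partition(1), tr_h, m)
    expect_lt(abs(ll_doublet - ll_single), 1e-8)
  }
})

test_that("gaps are treated as missing data", {
  m <- subst_model()
  tr <- ape::read.tree(text = "((a:0.1,b:0.2):0.1,(c:0.1,d:0.3):0.05);")
  sp1 <- site_partition(1)
  base <- phylo_loglik(structural_alignment(
    c(a = "A", b = "A", c = "G", d = "G")), sp1, tr, m)
  # an all-gap column contributes zero log-likelihood
  aln2 <- structural_alignment(c(a = "A-", b = "A-", c = "G-", d = "G-"))
  with_gap <- phylo_loglik(aln2, site_partition(2), tr, m)
  expect_equal(with_gap, base, tolerance = 1e-9)
  # a gap at one tip marginalizes that tip: likelihood rises above the
  # fully observed mismatching state
  expect_error(phylo_loglik(structural_alignment(c(x = "A", y = "A")),
                            sp1, tr, m), "absent")
})
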