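test_that("rate matrices satisfy detailed balance and unit mean rate", {
  set.seed(2)
  for (case in 1:10) {
    exch <- rexp(6) + 0.1
    bf <- as.numeric(rdirichlet1(4))
    df <- as.numeric(rdirichlet1(16))
    m <- subst_model(exch = exch, base_freqs = bf, doublet_freqs = df)
    Q4 <- gtr_rate_matrix(m)
    Q16 <- doublet_rate_matrix(m)
    expect_equal(sum(m$base_freqs * -diag(Q4)), 1, tolerance = 1e-10)
    expect_equal(sum(m$doublet_freqs * -diag(Q16)), 1, tolerance = 1e-10)
    expect_lt(max(abs(m$base_freqs * Q4 - t(m$base_freqs * Q4))), 1e-10)
    expect_lt(max(abs(m$doublet_freqs * Q16 - t(m$doublet_freqs * Q16))),
              1e-10)
    expect_equal(unname(rowSums(Q4)), rep(0, 4), tolerance = 1e-12)
    expect_equal(unname(rowSums(Q16)), rep(0, 16), tolerance = 1e-12)
  }
})

test_that("the doublet matrix forbids simultaneous two-position changes", {
  m <- subst_model(doublet_freqs = doublet_freqs_canonical())
  Q <- doublet_rate_matrix(m)
  st <- doublet_states()
  for (a in 1:16) for (b in 1:16) {
    if (a == b) next
    both_change <- substr(st[a], 1, 1) != substr(st[b], 1, 1) &&
      substr(st[a], 2, 2) != substr(st[b], 2, 2)
    if (both_change) expect_identical(Q[a, b], 0)
  }
  # uniform frequencies + equal exchangeabilities: all allowed rates equal
  mu <- subst_model(exch = rep(1, 6), base_freqs = rep(0.25, 4))
  Qu <- doublet_rate_matrix(mu)
  off <- Qu[row(Qu) != col(Qu)]
  expect_equal(length(unique(round(off[off > 0], 12))), 1)
})

test_that("discrete gamma rates are exact bin means", {
  for (a in c(0.1, 0.5, 1, 2, 10)) {
    r <- discrete_gamma(a, 4)
    expect_equal(mean(r), 1, tolerance = 1e-10)
    expect_true(all(diff(r) > 0))
  }
  # alpha -> infinity: rates -> 1
  expect_equal(discrete_gamma(1e6, 4), rep(1, 4), tolerance = 1e-2)
  expect_error(discrete_gamma(0), "positive")
  # quadrature oracle at alpha = 0.5
  a <- 0.5
  b <- c(0, qgamma(1:3 / 4, a, a), Inf)
  oracle <- vapply(1:4, function(k) {
    4 * stats::integrate(function(x) x * dgamma(x, a, a),
                         b[k], b[k + 1], rel.tol = 1e-10)$value
  }, numeric(1))
  expect_equal(discrete_gamma(a, 4), oracle, tolerance = 1e-6)
})

test_that("transition probabilities agree with a dense matrix exponential", {
  skip_if_not_installed("Matrix")
  set.seed(3)
  m <- subst_model(exch = rexp(6) + 0.2,
                   base_freqs = as.numeric(rdirichlet1(4)),
                   doublet_freqs = doublet_freqs_canonical())
  for (t in c(0.01, 0.3, 2)) {
    P4 <- transition_prob(gtr_rate_matrix(m), m$base_freqs, t)
    E4 <- as.matrix(Matrix::expm(gtr_rate_matrix(m) * t))
    expect_equal(unname(P4), unname(E4), tolerance = 1e-8)
    P16 <- transition_prob(doublet_rate_matrix(m), m$doublet_freqs, t)
    E16 <- as.matrix(Matrix::expm(doublet_rate_matrix(m) * t))
    expect_equal(unname(P16), unname(E16), tolerance = 1e-8)
  }
})

test_that("site partitions validate structure", {
  sp <- site_partition(10, pairs = rbind(c(0, 9), c(1, 8)))
  expect_equal(sp$unpaired, 2:7)
  expect_error(site_partition(10, pairs = rbind(c(0, 5), c(0, 7))),
               "more than one pair")
  expect_error(site_partition(10, pairs = rbind(c(0, 6), c(3, 9))),
               "crossing")
  sp2 <- partition_from_structure("((....))..")
  expect_equal(sp2$pairs, rbind(c(0L, 7L), c(1L, 6L)))
})
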