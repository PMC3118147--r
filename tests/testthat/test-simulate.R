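test_that("generators are deterministic given their seed", {
  a <- gen_hairpin(hairpin_spec(seed = 12))
  b <- gen_hairpin(hairpin_spec(seed = 12))
  expect_identical(a$hairpin$seq, b$hairpin$seq)
  expect_identical(a$hairpin$ss$pairs, b$hairpin$ss$pairs)
  expect_false(identical(a$hairpin$seq,
                         gen_hairpin(hairpin_spec(seed = 13))$hairpin$seq))
  g <- gen_hairpin(hairpin_spec(seed = 3))
  l1 <- gen_library(g$hairpin, g$scheme, c(miR = 0.8, leak = 0.2),
                    depth = 500, seed = 4)
  l2 <- gen_library(g$hairpin, g$scheme, c(miR = 0.8, leak = 0.2),
                    depth = 500, seed = 4)
  expect_identical(l1$library$records, l2$library$records)
  tr <- fixture_tree6()
  e1 <- evolve_alignment(tr, fixture_model(), 5, 10, seed = 6)
  e2 <- evolve_alignment(tr, fixture_model(), 5, 10, seed = 6)
  expect_identical(unclass(e1$aln), unclass(e2$aln))
})

test_that("default hairpins pass every rule and carry a valid scheme", {
  for (s in 1:10) {
    g <- gen_hairpin(hairpin_spec(seed = s))
    rep <- evaluate_mircheck(g$hairpin, g$mir)
    expect_true(rep$overall, info = paste("seed", s))
    expect_true(rep$stable)
    expect_false(is.null(g$scheme))
    lens <- g$scheme$end - g$scheme$start
    cons <- g$scheme$name %in% c("miR", "miR*", "ACR5", "ACR3")
    expect_true(all(lens[cons] >= 18 & lens[cons] <= 26))
  }
})

test_that("library generator respects planted assignment classes", {
  g <- gen_hairpin(hairpin_spec(seed = 8))
  props <- c(miR = 1)
  gl <- gen_library(g$hairpin, g$scheme, props, depth = 300, seed = 1,
                    noise_fraction = 0)
  pre <- setNames(g$hairpin$seq, "p")
  e <- quantify(list(gl$library), pre, setNames(list(g$scheme), "p"))
  expect_equal(sum(e$unique[e$partition != "miR"]), 0)
  # all-leak library
  gl2 <- gen_library(g$hairpin, g$scheme, c(leak = 1), depth = 300,
                     seed = 2, noise_fraction = 0)
  e2 <- quantify(list(gl2$library), pre, setNames(list(g$scheme), "p"))
  expect_equal(sum(e2$unique[e2$partition != "leak"]), 0)
  expect_gt(sum(e2$unique[e2$partition == "leak"]), 0)
})

test_that("planted proportions converge with depth", {
  g <- gen_hairpin(hairpin_spec(seed = 9))
  props <- c(miR = 0.5, `miR*` = 0.2, ACR5 = 0.1, ACR3 = 0.15, leak = 0.05)
  gl <- gen_library(g$hairpin, g$scheme, props, depth = 2e4, seed = 3)
  pre <- setNames(g$hairpin$seq, "p")
  e <- quantify(list(gl$library), pre, setNames(list(g$scheme), "p"))
  tot <- sum(e$unique)
  for (part in names(props)) {
    got <- sum(e$unique[e$partition == part]) / tot
    sigma <- sqrt(props[[part]] * (1 - props[[part]]) / 2e4)
    expect_lt(abs(got - props[[part]]), 3 * sigma + 1e-6,
              label = paste(part, got))
  }
})

test_that("PARE generator produces the planted shapes", {
  g <- gen_hairpin(hairpin_spec(seed = 10))
  ctx <- embed_precursor(g$hairpin, 500, seed = 4)
  # delta distribution: single-peak profile
  gp <- gen_pare(ctx$seq, setNames(1, 250), depth = 500, seed = 5)
  prof <- pare_profile(gp$library, c(t = ctx$seq))
  expect_equal(unique(prof$position), 250)
  # uniform: flat within sampling error
  pos <- seq(100, 350, by = 10)
  gp2 <- gen_pare(ctx$seq, setNames(rep(1, length(pos)), pos),
                  depth = 26000, seed = 6)
  prof2 <- pare_profile(gp2$library, c(t = ctx$seq))
  expect_true(all(abs(prof2$tp10m_max / 1e7 * 26000 - 1000) < 150))
})

test_that("alignment evolution limits are correct", {
  tr0 <- fixture_tree6()
  m <- fixture_model()
  # zero branch lengths: identical rows
  trz <- tr0
  trz$edge.length[] <- 1e-12
  ev <- evolve_alignment(trz, m, 10, 30, seed = 7)
  rows <- apply(unclass(ev$aln), 1, paste, collapse = "")
  expect_equal(length(unique(rows)), 1)
  # very long branches: column frequencies approach stationarity
  trl <- tr0
  trl$edge.length[] <- 50
  evl <- evolve_alignment(trl, m, 0, 600, seed = 8)
  counts <- table(factor(unclass(evl$aln), levels = c("A", "C", "G", "U")))
  cs <- chisq.test(counts, p = m$base_freqs)
  expect_gt(cs$p.value, 1e-4)
})

test_that("evolved pair columns covary detectably", {
  set.seed(15)
  tr <- ape::rtree(20, rooted = FALSE)
  tr$edge.length <- tr$edge.length * 0.3
  ev <- evolve_alignment(tr, fixture_model(), 15, 20, seed = 9)
  res <- detect_pairs(ev$aln)
  planted <- paste(ev$partition$pairs[, 1], ev$partition$pairs[, 2])
  expect_gt(mean(planted %in% paste(res$i, res$j)), 0.8)
})
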