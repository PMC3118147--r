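aln_from <- function(...) structural_alignment(c(...))

test_that("gap-column filtering keeps exactly-75% columns", {
  rows <- c(rep("A-A", 2), rep("AAA", 2), rep("A-A", 6))
  # column 2: 8 of 10 gaps (0.8) -> removed
  aln <- structural_alignment(setNames(rows, paste0("r", 1:10)))
  flt <- filter_columns(aln)
  expect_equal(flt$column_map, c(0, 2))
  # 7/10 gaps kept
  rows2 <- c(rep("A-A", 7), rep("AAA", 3))
  flt2 <- filter_columns(structural_alignment(setNames(rows2, paste0("r", 1:10))))
  expect_equal(flt2$column_map, 0:2)
  # exactly 75%: kept (strictly-greater removed)
  rows3 <- c(rep("A-A", 3), "AAA")
  flt3 <- filter_columns(structural_alignment(setNames(rows3, paste0("r", 1:4))))
  expect_equal(flt3$column_map, 0:2)
  expect_error(filter_columns(structural_alignment(
    setNames(rep("---", 4), paste0("r", 1:4)))), "all columns")
})

test_that("consensus residues and information content", {
  aln <- structural_alignment(setNames(
    c("UA", "UC", "UG", "UU", "UA", "UC", "UG", "UU", "UA", "UC"),
    paste0("r", 1:10)))
  cons <- consensus_sequence(aln)
  expect_identical(cons$consensus[1], "U")
  expect_equal(cons$ic[1], 2)
  expect_true(is.na(cons$consensus[2]))
  # column {A:7, G:3}: no consensus at 0.8, IC = 2 - H(0.7, 0.3)
  aln2 <- structural_alignment(setNames(
    c(rep("AA", 7), rep("GA", 3)), paste0("r", 1:10)))
  cons2 <- consensus_sequence(aln2)
  expect_true(is.na(cons2$consensus[1]))
  H <- -(0.7 * log2(0.7) + 0.3 * log2(0.3))
  expect_equal(cons2$ic[1], 2 - H, tolerance = 1e-9)
  expect_equal(round(cons2$ic[1], 3), 1.119)
})

test_that("pair detection classifies consensus and covarying pairs", {
  # invariant G:C pair (min loop respected: columns 0 and 5)
  rows <- vapply(1:10, function(i) "GAAAAC", character(1))
  res <- detect_pairs(structural_alignment(setNames(rows, paste0("r", 1:10))))
  expect_equal(nrow(res), 1)
  expect_equal(c(res$i, res$j), c(0, 5))
  expect_identical(res$class, "consensus")
  # 5 G:C + 5 A:U -> covarying
  rows2 <- c(rep("GAAAAC", 5), rep("AAAAAU", 5))
  res2 <- detect_pairs(structural_alignment(setNames(rows2, paste0("r", 1:10))))
  expect_identical(res2$class, "covarying")
  expect_equal(res2$n_types, 2)
})

test_that("selected pairs equal the exhaustive optimum on small alignments", {
  set.seed(20)
  m <- fixture_model()
  for (case in 1:6) {
    tr <- ape::rtree(12, rooted = FALSE)
    tr$edge.length <- tr$edge.length * 0.4
    ev <- evolve_alignment(tr, m, n_pairs = sample(3:5, 1),
                           n_unpaired = sample(6:10, 1), seed = case)
    aln <- ev$aln
    expect_lte(ncol(aln), 20)
    params <- consensus_params()
    cand <- phasemir:::candidate_pairs(unclass(aln), params)
    sel <- detect_pairs(aln, params)
    opt <- oracle_best_pairset(cand, ncol(aln))
    expect_equal(selected_pairset_score(sel), opt,
                 tolerance = 1e-12, info = paste("case", case))
    if (nrow(cand) <= 12) {
      expect_equal(opt, oracle_best_pairset_mask(cand, ncol(aln)),
                   tolerance = 1e-12)
    }
    # non-crossing
    if (nrow(sel) > 1) {
      expect_silent(secondary_structure(cbind(sel$i, sel$j), ncol(aln),
                                        min_loop = 0))
    }
  }
})

test_that("planted helices are recovered from evolved alignments", {
  m <- fixture_model()
  sens <- numeric(0)
  for (s in 1:5) {
    set.seed(s)
    tr <- ape::rtree(30, rooted = FALSE)
    tr$edge.length <- tr$edge.length * 0.15
    ev <- evolve_alignment(tr, m, n_pairs = 40, n_unpaired = 70, seed = s)
    res <- detect_pairs(filter_columns(ev$aln)$aln)
    planted <- paste(ev$partition$pairs[, 1], ev$partition$pairs[, 2])
    found <- paste(res$i, res$j)
    sens <- c(sens, mean(planted %in% found))
    expect_silent(secondary_structure(cbind(res$i, res$j), ncol(ev$aln),
                                      min_loop = 0))
  }
  expect_gte(mean(sens), 0.95)
})

test_that("consensus analysis is invariant to row permutation", {
  m <- fixture_model()
  set.seed(77)
  tr <- ape::rtree(12, rooted = FALSE)
  ev <- evolve_alignment(tr, m, n_pairs = 8, n_unpaired = 30, seed = 3)
  a1 <- consensus_analysis(ev$aln)
  perm <- unclass(ev$aln)[sample(nrow(ev$aln)), , drop = FALSE]
  a2 <- consensus_analysis(structural_alignment(perm))
  expect_equal(a1$columns, a2$columns)
  expect_equal(a1$pairs, a2$pairs)
  expect_identical(a1$ss_cons, a2$ss_cons)
})

test_that("Stockholm round trip preserves rows and SS_cons", {
  m <- fixture_model()
  set.seed(5)
  tr <- ape::rtree(8, rooted = FALSE)
  ev <- evolve_alignment(tr, m, n_pairs = 6, n_unpaired = 20, seed = 4)
  ca <- consensus_analysis(ev$aln)
  path <- tempfile(fileext = ".sto")
  write_stockholm(ca$aln, path, ss_cons = ca$ss_cons)
  back <- read_stockholm(path)
  expect_equal(unclass(back)[rownames(ca$aln), ], unclass(ca$aln))
  expect_identical(attr(back, "ss_cons"), ca$ss_cons)
  # the SS_cons line parses into the same pair set
  sp <- partition_from_structure(attr(back, "ss_cons"))
  expect_equal(sp$pairs[order(sp$pairs[, 1]), , drop = FALSE],
               cbind(ca$pairs_filtered$i, ca$pairs_filtered$j)[
                 order(ca$pairs_filtered$i), , drop = FALSE])
})
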