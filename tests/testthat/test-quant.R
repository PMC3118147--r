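make_lib <- function(id, seqs, counts, total = NULL, pre = FALSE) {
  srna_library(id, data.frame(sequence = seqs, count = counts,
                              stringsAsFactors = FALSE),
               total_reads = total, pre_normalized = pre)
}

test_that("read mapping reports every exact occurrence", {
  pre <- c(p1 = "AAAACCCCGGGGUUUUAAAACCCCGGGG",
           p2 = "GGGGUUUUAAAACCCC")
  lib <- make_lib("s1", c("AAAACCCCGGGG", "GGGGUUUU", "CCCCAAAA"),
                  c(10, 5, 2))
  pl <- map_reads(lib, pre)
  # twice within p1 only: abundance split equally, not shared
  r1 <- pl[pl$sequence == "AAAACCCCGGGG", ]
  expect_equal(sort(r1$start), c(0, 16))
  expect_equal(unique(r1$precursor), "p1")
  expect_false(any(r1$shared))
  expect_equal(r1$weight, c(0.5, 0.5))
  # present in both precursors: shared, multiplicity 2, full weight each
  r2 <- pl[pl$sequence == "GGGGUUUU", ]
  expect_setequal(r2$precursor, c("p1", "p2"))
  expect_true(all(r2$shared))
  expect_equal(unique(r2$multiplicity), 2)
  expect_equal(r2$weight, c(1, 1))
  expect_false(any(pl$sequence == "CCCCAAAA"))  # unmapped absent
})

test_that("read mapping equals a naive substring oracle", {
  set.seed(14)
  pre <- setNames(vapply(1:3, function(i)
    paste(sample(c("A", "C", "G", "U"), 80, TRUE), collapse = ""),
    character(1)), paste0("p", 1:3))
  reads <- unique(c(
    vapply(1:20, function(i) {
      p <- sample(3, 1); s <- sample(60, 1)
      substr(pre[[p]], s, s + sample(18:22, 1))
    }, character(1)),
    vapply(1:5, function(i)
      paste(sample(c("A", "C", "G", "U"), 21, TRUE), collapse = ""),
      character(1))))
  lib <- make_lib("s", reads, rep(1, length(reads)))
  pl <- map_reads(lib, pre)
  for (rd in reads) {
    for (p in names(pre)) {
      naive <- integer(0)
      L <- nchar(rd)
      for (s in 0:(nchar(pre[[p]]) - L)) {
        if (substr(pre[[p]], s + 1, s + L) == rd) naive <- c(naive, s)
      }
      got <- sort(pl$start[pl$sequence == rd & pl$precursor == p])
      expect_equal(got, naive, info = paste(rd, p))
    }
  }
})

test_that("mean-total normalization and its invariances", {
  l1 <- make_lib("a", "AAAA", 10, total = 100)
  l2 <- make_lib("b", "AAAA", 10, total = 300)
  f <- normalize_libraries(list(l1, l2))
  expect_equal(unname(f), c(2, 2 / 3))
  expect_equal(10 * f[["a"]], 20)
  # normalized totals preserve the mean
  expect_equal(mean(c(100, 300) * f), mean(c(100, 300)))
  # single library => factor 1
  expect_equal(unname(normalize_libraries(list(l1))), 1)
  # pre-normalized => factor 1
  l3 <- make_lib("c", "AAAA", 10, total = 50, pre = TRUE)
  expect_equal(normalize_libraries(list(l1, l3))[["c"]], 1)
  # scale invariance of normalized values
  l1x <- make_lib("a", "AAAA", 70, total = 700)
  l2x <- make_lib("b", "AAAA", 70, total = 2100)
  fx <- normalize_libraries(list(l1x, l2x))
  expect_equal(10 * f[["a"]] / 100, 70 * fx[["a"]] / 700)
  expect_error(normalize_libraries(list(make_lib("z", "AA", 1, total = 0))))
})

test_that("partition assignment uses the 80% overlap boundary", {
  g <- gen_hairpin(hairpin_spec(seed = 6))
  sch <- g$scheme
  acr3 <- c(sch$start[sch$name == "ACR3"], sch$end[sch$name == "ACR3"])
  # full overlap
  expect_identical(assign_partition(c(acr3[1], acr3[1] + 21), sch), "ACR3")
  # 16/21 = 76.2% => leak; 17/21 = 81% => assigned
  expect_identical(assign_partition(c(acr3[2] - 16, acr3[2] + 5), sch),
                   "leak")
  expect_identical(assign_partition(c(acr3[2] - 17, acr3[2] + 4), sch),
                   "ACR3")
})

test_that("at most one partition can satisfy an overlap above one half", {
  g <- gen_hairpin(hairpin_spec(seed = 6))
  sch <- g$scheme
  n <- nchar(g$hairpin$seq)
  for (L in c(20, 21, 22)) {
    for (a in 0:(n - L)) {
      ov <- pmin(a + L, sch$end) - pmax(a, sch$start)
      expect_lte(sum(ov / L >= 0.8), 1)
    }
  }
})

test_that("quantification conserves mass and splits unique/max_possible", {
  g <- gen_hairpin(hairpin_spec(seed = 5))
  props <- c(miR = 0.55, `miR*` = 0.2, ACR3 = 0.15, leak = 0.1)
  gl <- gen_library(g$hairpin, g$scheme, props, depth = 5000, seed = 2)
  pre <- setNames(g$hairpin$seq, g$hairpin$id)
  schemes <- setNames(list(g$scheme), g$hairpin$id)
  e <- quantify(list(gl$library), pre, schemes)
  pl <- map_reads(gl$library, pre)
  f <- normalize_libraries(list(gl$library))
  expect_equal(sum(e$unique),
               sum(pl$count[pl$multiplicity == 1] * f * pl$weight),
               tolerance = 1e-9)
  # paralog sharing: duplicate the precursor under a second name
  pre2 <- c(pre, paralog = unname(pre))
  schemes2 <- c(schemes, list(paralog = g$scheme))
  e2 <- quantify(list(gl$library), pre2, schemes2)
  expect_equal(sum(e2$unique), 0)  # every read now matches both copies
  expect_equal(sum(e2$max_possible), 2 * sum(e$max_possible))
  # grouped quantification counts each shared read once per group
  e3 <- quantify(list(gl$library), pre2, schemes2,
                 groups = list(fam = names(pre2)))
  grp <- e3[e3$precursor == "fam", ]
  expect_equal(sum(grp$max_possible), sum(e$max_possible))
})

test_that("empty libraries quantify to zero", {
  g <- gen_hairpin(hairpin_spec(seed = 5))
  lib <- make_lib("empty", "GGGGGGGGGGGGGGGGGGGGG", 3)  # unmappable
  e <- quantify(list(lib), setNames(g$hairpin$seq, "p"),
                setNames(list(g$scheme), "p"))
  expect_true(all(e$unique == 0) && all(e$max_possible == 0))
})

test_that("mutant/wild-type ratios follow floor and replicate rules", {
  tab <- function(vals, sample) {
    data.frame(sample = sample, precursor = "p",
               partition = names(vals), unique = NA,
               max_possible = unname(vals))
  }
  # plain ratio
  r <- ratio_mut_wt(tab(c(miR = 200), "m1"), tab(c(miR = 20), "w1"))
  expect_equal(r$ratio, 10)
  expect_identical(r$flag, "")
  # both below floor -> 1, absent
  r2 <- ratio_mut_wt(tab(c(ACR3 = 0.2), "m1"), tab(c(ACR3 = 0.1), "w1"))
  expect_equal(r2$ratio, 1)
  expect_identical(r2$flag, "absent")
  # only denominator below floor -> floored
  r3 <- ratio_mut_wt(tab(c(miR = 50), "m1"), tab(c(miR = 0.5), "w1"))
  expect_equal(r3$ratio, 50)
  expect_identical(r3$flag, "floored")
  # replicates averaged before the ratio
  rm <- rbind(tab(c(miR = 10), "m1"), tab(c(miR = 30), "m2"))
  rw <- rbind(tab(c(miR = 5), "w1"), tab(c(miR = 15), "w2"))
  r4 <- ratio_mut_wt(rm, rw)
  expect_equal(r4$ratio, 2)
})

test_that("length-class ratios recover planted size-class changes", {
  mk <- function(id, n21, n24, total) {
    make_lib(id, c("AAAACCCCGGGGUUUUAAACC", "AAAACCCCGGGGUUUUAAACCGGG"),
             c(n21, n24), total = total)
  }
  bins <- list(`20-21` = 20:21, `24` = 24)
  r <- length_class_ratio(list(mk("m", 200, 10, 1000)),
                          list(mk("w", 100, 100, 1000)), bins)
  expect_equal(r$ratio[r$bin == "20-21"], 2)
  expect_equal(r$ratio[r$bin == "24"], 0.1)
  expect_error(length_class_ratio(list(mk("m", 1, 1, 10)),
                                  list(mk("w", 1, 1, 10)),
                                  list(a = 20:21, b = 21:22)),
               "disjoint")
})
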