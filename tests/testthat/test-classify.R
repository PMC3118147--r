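# fixtures for degraded conservation: rebuild a type-1 precursor with
# its ACR duplex re-randomized (type 4), unpaired (type 3), or both
# (type 5); pairing partners and all other segments stay put
degrade_acr <- function(g, what = c("shuffle", "unpair", "both"), seed = 99) {
  what <- match.arg(what)
  set.seed(seed)
  h <- g$hairpin
  pm <- h$ss$pairs
  acr5 <- c(56, 77)  # default geometry
  in_acr <- pm[, 1] >= acr5[1] & pm[, 1] < acr5[2]
  chars <- strsplit(h$seq, "")[[1]]
  if (what %in% c("shuffle", "both")) {
    canon <- list(c("A", "U"), c("U", "A"), c("G", "C"), c("C", "G"),
                  c("G", "U"), c("U", "G"))
    for (r in which(in_acr)) {
      pr <- canon[[sample(6, 1)]]
      chars[pm[r, 1] + 1] <- pr[1]
      chars[pm[r, 2] + 1] <- pr[2]
    }
  }
  keep <- if (what %in% c("unpair", "both")) !in_acr else rep(TRUE, nrow(pm))
  hairpin(paste(chars, collapse = ""),
          secondary_structure(pm[keep, , drop = FALSE], length(chars)),
          id = paste0(h$id, "_", what))
}

test_that("D is the loop-spanning miR-to-miR* distance", {
  g <- gen_hairpin(hairpin_spec(seed = 2))
  expect_equal(compute_D(g$hairpin, g$mir), 90)  # 20+21+8+21+20 planted
  g2 <- gen_hairpin(hairpin_spec(seed = 2, force_D = 4))
  expect_equal(compute_D(g2$hairpin, g2$mir), 4)
  g3 <- gen_hairpin(hairpin_spec(seed = 2, force_D = 60))
  expect_equal(compute_D(g3$hairpin, g3$mir), 60)
})

test_that("the five-type decision table is exact on the factorial grid", {
  for (D in c(59, 60, 61)) {
    for (seq_c in c(TRUE, FALSE)) {
      for (str_c in c(TRUE, FALSE)) {
        got <- type_from_flags(D, seq_c, str_c)
        want <- if (D <= 60) 2L else if (seq_c && str_c) 1L else
          if (seq_c) 3L else if (str_c) 4L else 5L
        expect_identical(got, want, info = paste(D, seq_c, str_c))
      }
    }
  }
})

test_that("planted fixtures classify into all five types", {
  g <- gen_hairpin(hairpin_spec(seed = 7))
  cons <- acr_consensus(g$acr5_seq, g$acr3_seq)
  expect_identical(classify_precursor(g$hairpin, g$mir, cons)$type, 1L)
  r4 <- classify_precursor(degrade_acr(g, "shuffle"), g$mir, cons)
  expect_equal(c(r4$seq_conserved, r4$str_conserved, r4$type),
               c(FALSE, TRUE, 4))
  r3 <- classify_precursor(degrade_acr(g, "unpair"), g$mir, cons)
  expect_equal(c(r3$seq_conserved, r3$str_conserved, r3$type),
               c(TRUE, FALSE, 3))
  r5 <- classify_precursor(degrade_acr(g, "both"), g$mir, cons)
  expect_equal(c(r5$seq_conserved, r5$str_conserved, r5$type),
               c(FALSE, FALSE, 5))
  g2 <- gen_hairpin(hairpin_spec(seed = 7, force_D = 55))
  expect_identical(classify_precursor(g2$hairpin, g2$mir, cons)$type, 2L)
  expect_error(detect_acr(g2$hairpin, g2$mir, cons), "type 2")
})

test_that("ACR detection ignores unpaired flanking sequence", {
  g <- gen_hairpin(hairpin_spec(seed = 13))
  cons <- acr_consensus(g$acr5_seq, g$acr3_seq)
  base <- detect_acr(g$hairpin, g$mir, cons)
  set.seed(1)
  pad <- paste(sample(c("A", "C", "G", "U"), 40, TRUE), collapse = "")
  shifted <- hairpin(paste0(pad, g$hairpin$seq),
                     secondary_structure(g$hairpin$ss$pairs + 40L,
                                         nchar(g$hairpin$seq) + 40L))
  ext <- detect_acr(shifted, g$mir + 40L, cons)
  expect_identical(ext$seq_conserved, base$seq_conserved)
  expect_identical(ext$str_conserved, base$str_conserved)
  expect_equal(ext$acr5, base$acr5 + 40L)
  expect_equal(ext$acr3, base$acr3 + 40L)
})

test_that("partition schemes tile the precursor exactly", {
  for (s in 1:10) {
    g <- gen_hairpin(hairpin_spec(seed = s))
    sch <- g$scheme
    expect_identical(sch$name,
                     c("sp1", "miR*", "sp2", "ACR5", "sp3", "ACR3", "sp4",
                       "miR", "sp5"))
    expect_equal(sch$start[1], 0)
    expect_equal(sch$end[nrow(sch)], nchar(g$hairpin$seq))
    expect_equal(sch$start[-1], sch$end[-nrow(sch)])  # no gaps, no overlap
    expect_identical(attr(sch, "orientation"), "mir_3p")
  }
  # mirrored orientation
  g5 <- gen_hairpin(hairpin_spec(seed = 4, mir_arm = "5p"))
  expect_identical(attr(g5$scheme, "orientation"), "mir_5p")
  expect_identical(g5$scheme$name[2], "miR")
  expect_equal(sum(g5$scheme$end - g5$scheme$start), nchar(g5$hairpin$seq))
})

test_that("zero-length space partitions are permitted", {
  g <- gen_hairpin(hairpin_spec(seed = 9, lengths = c(
    sp1 = 15, `miR*` = 21, sp2 = 0, ACR5 = 21, sp3 = 8, ACR3 = 21,
    sp4 = 0, miR = 21, sp5 = 15)))
  # sp2/sp4 empty: ACR5 abuts miR*, miR abuts ACR3
  sch <- build_partitions(g$hairpin, g$mir, c(36, 57), c(65, 86),
                          star = g$star)
  lens <- sch$end - sch$start
  expect_equal(lens[sch$name == "sp2"], 0)
  expect_equal(sum(lens), nchar(g$hairpin$seq))
})
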