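test_that("find_matches reports exact and near matches", {
  query <- "AAAACCCCGGGGUUUUAACC"
  target <- paste0("GUGUGUGUGU", query, "GAGAGAGAGA")
  hits <- find_matches(target, query, 0)
  plus <- hits[hits$strand == "+", ]
  expect_equal(nrow(plus), 1)
  expect_equal(c(plus$start, plus$end, plus$edit_distance), c(10, 30, 0))
  # one substitution
  t2 <- target
  substr(t2, 15, 15) <- "G"
  h2 <- find_matches(t2, query, 2)
  h2 <- h2[h2$strand == "+", ]
  expect_equal(h2$edit_distance, 1)
  # empty target
  expect_equal(nrow(find_matches("", query, 3)), 0)
})

test_that("find_matches equals the exhaustive window oracle", {
  set.seed(7)
  for (case in 1:25) {
    target <- paste(sample(c("A", "C", "G", "U"), 150, TRUE), collapse = "")
    query <- paste(sample(c("A", "C", "G", "U"), 20, TRUE), collapse = "")
    # plant a mutated copy half the time
    if (case %% 2 == 0) {
      q2 <- strsplit(query, "")[[1]]
      q2[sample(20, 2)] <- sample(c("A", "C", "G", "U"), 2, TRUE)
      pos <- sample(120, 1)
      substr(target, pos, pos + 19) <- paste(q2, collapse = "")
    }
    got <- find_matches(target, query, 3)
    got_plus <- got[got$strand == "+", c("start", "end", "edit_distance")]
    exp_plus <- oracle_merge_windows(oracle_window_hits(target, query, 3))
    rownames(got_plus) <- rownames(exp_plus) <- NULL
    expect_equal(as.data.frame(got_plus), as.data.frame(exp_plus),
                 info = paste("case", case))
  }
})

test_that("find_matches is strand-symmetric", {
  set.seed(8)
  for (case in 1:10) {
    target <- paste(sample(c("A", "C", "G", "U"), 120, TRUE), collapse = "")
    query <- paste(sample(c("A", "C", "G", "U"), 21, TRUE), collapse = "")
    a <- find_matches(target, query, 3)
    b <- find_matches(rna_revcomp(target), query, 3)
    n <- nchar(target)
    # mirrored coordinates, opposite strand labels
    mirror <- data.frame(start = n - b$end, end = n - b$start,
                         strand = as.character(chartr("+-", "-+", b$strand)),
                         edit_distance = b$edit_distance,
                         stringsAsFactors = FALSE)
    mirror <- mirror[order(mirror$start, mirror$strand), ]
    a <- a[order(a$start, a$strand), ]
    rownames(a) <- rownames(mirror) <- NULL
    expect_equal(a, mirror, info = paste("case", case))
  }
})

test_that("flank extraction truncates at ends", {
  target <- paste(rep("A", 1000), collapse = "")
  e1 <- extract_flanks(target, c(400, 421), 350)
  expect_equal(c(e1$offset, nchar(e1$seq)), c(50, 721))
  expect_equal(e1$hit_local, c(350, 371))
  e2 <- extract_flanks(target, c(10, 31), 350)
  expect_equal(c(e2$offset, nchar(e2$seq)), c(0, 381))
  e3 <- extract_flanks(target, c(0, 1000), 350)
  expect_equal(nchar(e3$seq), 1000)
})

test_that("miR* location follows the 2-nt 3'-overhang convention", {
  g <- gen_hairpin(hairpin_spec(seed = 21))
  star <- locate_star(g$hairpin, g$mir)
  expect_equal(c(star), g$star)
  expect_equal(star[2] - star[1], 21)
  # one 2-nt star-side bulge lengthens the star by 2
  g2 <- gen_hairpin(hairpin_spec(seed = 21, star_insert = 2L))
  star2 <- locate_star(g2$hairpin, g2$mir)
  expect_equal(star2[2] - star2[1], 23)
  # miR overlapping the loop is a precondition error
  expect_error(locate_star(g$hairpin, c(g$hairpin$loop_span[1] - 3,
                                        g$hairpin$loop_span[1] + 3)),
               "overlaps the terminal loop")
})

test_that("miRcheck rules match the independent checker on planted cases", {
  for (v in c("none", paste0("rule", 1:7))) {
    for (s in 1:8) {
      g <- gen_hairpin(hairpin_spec(seed = s, violate = v))
      rep <- evaluate_mircheck(g$hairpin, g$mir)
      orc <- oracle_mircheck(g$hairpin, g$mir)
      for (k in paste0("rule", c(1:7))) {
        expect_identical(rep$rules[[k]]$pass, orc[[k]],
                         info = paste(v, s, k))
      }
      expect_identical(rep$overall, orc$overall, info = paste(v, s))
      if (v != "none" && v != "rule1") {
        expect_false(rep$rules[[v]]$pass, info = paste(v, s))
      }
    }
  }
})

test_that("status calls follow the homolog/candidate edit thresholds", {
  g <- gen_hairpin(hairpin_spec(seed = 3))
  rep_pass <- evaluate_mircheck(g$hairpin, g$mir)
  g2 <- gen_hairpin(hairpin_spec(seed = 3, violate = "rule7"))
  rep_fail <- evaluate_mircheck(g2$hairpin, g2$mir)
  expect_identical(call_status(0, rep_pass), "homolog")
  expect_identical(call_status(3, rep_pass), "homolog")
  expect_identical(call_status(4, rep_pass), "candidate")
  expect_identical(call_status(5, rep_pass), "rejected")
  expect_identical(call_status(2, rep_fail), "rejected")
  # monotone: increasing distance never upgrades
  rank <- c(homolog = 3, candidate = 2, rejected = 1)
  st <- rank[vapply(0:6, call_status, character(1), report = rep_pass)]
  expect_true(all(diff(st) <= 0))
})

test_that("family naming picks the nearest reference", {
  refs <- c(X = "AAAACCCCGGGGUUUUAAGG", Y = "UUUUGGGGCCCCAAAAGGCC")
  expect_identical(assign_name(refs[["X"]], refs), "X")
  mut <- refs[["X"]]
  substr(mut, 3, 3) <- "G"
  expect_identical(assign_name(mut, refs), "X")
  set.seed(10)
  refs10 <- setNames(
    vapply(1:10, function(i)
      paste(sample(c("A", "C", "G", "U"), 21, TRUE), collapse = ""),
      character(1)),
    paste0("ref", sprintf("%02d", 1:10)))
  for (case in 1:30) {
    probe <- paste(sample(c("A", "C", "G", "U"), 21, TRUE), collapse = "")
    d <- utils::adist(probe, refs10)[1, ]
    want <- names(refs10)[order(d, names(refs10))][1]
    expect_identical(assign_name(probe, refs10), want)
  }
})

test_that("alignment identity matches a scored pairwise aligner", {
  mats <- fixture_matures()
  ident <- alignment_identity(mats[["ath-miR159a"]], mats[["ath-miR319a"]])
  expect_equal(c(ident), 17L, ignore_attr = TRUE)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, type = "RNA")
  set.seed(11)
  for (case in 1:20) {
    a <- paste(sample(c("A", "C", "G", "U"), 21, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "U"), sample(19:23, 1), TRUE),
               collapse = "")
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::RNAString(a), Biostrings::RNAString(b),
      substitutionMatrix = submat, gapOpening = 0, gapExtension = 2)
    got <- alignment_identity(a, b)
    # the optimal score must agree exactly; the match count can only be
    # at least the one realized by the aligner's arbitrary co-optimum
    expect_equal(attr(got, "score"), Biostrings::score(pa),
                 info = paste(a, b))
    expect_gte(c(got), Biostrings::nmatch(pa))
  }
})

test_that("the end-to-end scan finds a planted homolog", {
  set.seed(33)
  mats <- fixture_matures()
  g <- gen_hairpin(hairpin_spec(seed = 5, mir_seq = mats[["ath-miR159a"]]))
  flank <- paste(sample(c("A", "C", "G", "U"), 120, TRUE), collapse = "")
  target <- c(locus1 = paste0(flank, g$hairpin$seq, flank))
  # supply the true structure for the extract the scanner will cut out
  hit_start <- 120 + g$mir[1]
  res <- scan_homologs(target, mats["ath-miR159a"],
                       params = scan_params(flank_len = 150))
  expect_true(any(res$status == "homolog" & res$edit_distance == 0))
})
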