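# Seeded synthetic-data generators with machine-readable ground truth.
# Each generator seeds R's RNG once at entry (the seed is part of the
# spec and recorded in the output), so outputs are bit-identical across
# runs for a fixed seed.

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

#' Specification of a synthetic stem-loop precursor
#'
#' Default geometry mirrors a type-1 precursor: nine partitions
#' sp1(15) miR*(21) sp2(20) ACR5(21) sp3/loop(8) ACR3(21) sp4(20)
#' miR(21) sp5(15), miR on the 3' arm, miR:miR* and ACR5:ACR3 duplexes
#' fully paired (apart from requested violations), spacers sp2/sp4
#' partially paired into a connecting stem.
#'
#' `violate` presets plant one rule violation: `"rule1"` (miR interval
#' straddles the loop), `"rule2"` (7 unpaired miR bases in runs 3+3+1),
#' `"rule3"` (4 single-base symmetric bulges), `"rule4"` (4 extra
#' miR*-side bases), `"rule5"` (runs 3+3 with star gaps 1+1 plus a 2-nt
#' star bulge to keep lengths legal), `"rule6"` (one 4-base run),
#' `"rule7"` (D = 4).
#'
#' @param seed RNG seed.
#' @param lengths named lengths of the nine partitions.
#' @param mir_seq,acr3_seq optional planted sequences (random otherwise).
#' @param mir_arm `"3p"` (default) or `"5p"`.
#' @param force_D numeric; when <= 60 builds the short (type-2) form
#'   with a loop of this size and no ACRs.
#' @param violate one of `"none"`, `"rule1"` .. `"rule7"`.
#' @param mir_bulge_runs,star_gap_runs,star_insert low-level duplex
#'   controls overriding the presets: miR-side unpaired run lengths, the
#'   matching star-side gap sizes, and extra star-side inserted bases.
#' @param sp_pair_prob pairing probability of the sp2/sp4 connecting
#'   stem (default 0.7).
#' @return list of class `hairpin_spec`.
#' @export
hairpin_spec <- function(seed = 1L,
                         lengths = c(sp1 = 15, `miR*` = 21, sp2 = 20,
                                     ACR5 = 21, sp3 = 8, ACR3 = 21,
                                     sp4 = 20, miR = 21, sp5 = 15),
                         mir_seq = NULL, acr3_seq = NULL, mir_arm = "3p",
                         force_D = NULL, violate = "none",
                         mir_bulge_runs = integer(0),
                         star_gap_runs = integer(0), star_insert = 0L,
                         sp_pair_prob = 0.7) {
  stopifnot(mir_arm %in% c("3p", "5p"),
            violate %in% c("none", paste0("rule", 1:7)))
  preset <- switch(violate,
    rule2 = list(mir_bulge_runs = c(3L, 3L, 1L), star_gap_runs = c(3L, 3L, 1L)),
    rule3 = list(mir_bulge_runs = rep(1L, 4), star_gap_runs = rep(1L, 4)),
    rule4 = list(star_insert = 4L),
    rule5 = list(mir_bulge_runs = c(3L, 3L), star_gap_runs = c(1L, 1L),
                 star_insert = 2L),
    rule6 = list(mir_bulge_runs = 4L, star_gap_runs = 4L),
    rule7 = list(force_D = 4),
    list())
  if (!is.null(preset$mir_bulge_runs)) {
    mir_bulge_runs <- preset$mir_bulge_runs
    star_gap_runs <- preset$star_gap_runs
  }
  if (!is.null(preset$star_insert)) star_insert <- preset$star_insert
  if (!is.null(preset$force_D)) force_D <- preset$force_D
  structure(list(seed = as.integer(seed), lengths = lengths,
                 mir_seq = mir_seq, acr3_seq = acr3_seq, mir_arm = mir_arm,
                 force_D = force_D, violate = violate,
                 mir_bulge_runs = as.integer(mir_bulge_runs),
                 star_gap_runs = as.integer(star_gap_runs),
                 star_insert = as.integer(star_insert),
                 sp_pair_prob = sp_pair_prob),
            class = "hairpin_spec")
}

# build the miR:miR* duplex: star sequence 5'->3' plus the pairing map in
# offsets (mir offset 5'->3' vs star offset 5'->3', antiparallel).
# The miR's 3'-terminal two bases stay unpaired (3' overhang) and the
# star gains a 2-base 3' overhang.
build_duplex <- function(mir_seq, runs, gaps, star_insert) {
  L <- nchar(mir_seq)
  stopifnot(length(runs) == length(gaps), sum(runs) + 2L * length(runs) < L - 4L)
  mirc <- strsplit(mir_seq, "")[[1]]
  unpaired <- rep(FALSE, L)
  # place runs interleaved from position 4, two paired bases between runs
  pos <- 4L
  for (k in seq_along(runs)) {
    unpaired[pos:(pos + runs[k] - 1L)] <- TRUE
    pos <- pos + runs[k] + 2L
  }
  unpaired[c(L - 1L, L)] <- TRUE        # miR 3' overhang (never a bulge)
  star <- character(0)
  pairs <- list()                        # (mir offset, star offset) 0-based
  gap_queue <- gaps
  insert_at <- 4L  # star bulge sits in the first paired stretch, clear
                   # of any planted miR-side run
  paired_seen <- 0L
  run_id <- 0L
  k <- L - 2L                            # walk miR from 3' paired end
  while (k >= 1L) {
    if (unpaired[k]) {
      # emit the star-side gap for this run (runs met in reverse order)
      while (k >= 1L && unpaired[k]) k <- k - 1L
      run_id <- run_id + 1L
      g <- gap_queue[length(gap_queue) - run_id + 1L]
      if (!is.na(g) && g > 0) star <- c(star, strsplit(random_rna(g), "")[[1]])
    } else {
      star <- c(star, comp_base(mirc[k]))
      pairs[[length(pairs) + 1L]] <- c(k - 1L, length(star) - 1L)
      paired_seen <- paired_seen + 1L
      if (star_insert > 0L && paired_seen == insert_at) {
        star <- c(star, strsplit(random_rna(star_insert), "")[[1]])
      }
      k <- k - 1L
    }
  }
  star <- c(star, strsplit(random_rna(2), "")[[1]])  # star 3' overhang
  list(star_seq = paste(star, collapse = ""),
       pairs = do.call(rbind, pairs))
}

comp_base <- function(x) c(A = "U", C = "G", G = "C", U = "A")[[x]]

#' Generate a synthetic stem-loop with ground truth
#'
#' Builds the precursor sequence and its true structure from a
#' [hairpin_spec()]
#' (reverse-complement pairing for the miR:miR* and ACR5:ACR3 duplexes,
#' a partially paired connecting stem, unpaired flanks), applies the
#' requested rule violations, and returns the hairpin together with the
#' planted intervals, partition scheme and type.
#'
#' @param spec a [hairpin_spec()].
#' @return list with `hairpin`, `mir`, `star` (0-based half-open
#'   intervals; `star` is `NULL` for the rule-1 geometry), `scheme`
#'   (`partition_scheme` for the type-1 geometry, else `NULL`),
#'   `type` (1 or 2), `acr5_seq`, `acr3_seq`, `violate`, `seed`.
#' @export
gen_hairpin <- function(spec = hairpin_spec()) {
  set.seed(spec$seed)
  len <- spec$lengths
  mir_seq <- spec$mir_seq %||% random_rna(len[["miR"]])
  if (!is.null(spec$force_D) || spec$violate == "rule1") {
    return(gen_hairpin_short(spec, mir_seq))
  }
  acr3_seq <- spec$acr3_seq %||% random_rna(len[["ACR3"]])
  acr5_seq <- rna_revcomp(acr3_seq)
  dup <- build_duplex(mir_seq, spec$mir_bulge_runs, spec$star_gap_runs,
                      spec$star_insert)
  star_seq <- dup$star_seq
  sp4_seq <- random_rna(len[["sp4"]])
  sp2c <- strsplit(rna_revcomp(sp4_seq), "")[[1]]
  sp_paired <- stats::runif(length(sp2c)) < spec$sp_pair_prob
  sp2c[!sp_paired] <- vapply(which(!sp_paired), function(i) {
    sample(setdiff(c("A", "C", "G", "U"), comp_base(sp2c[i])), 1)
  }, character(1))
  # a substituted base may still pair by chance; drop it from the truth
  sp2_seq <- paste(sp2c, collapse = "")
  sp1_seq <- random_rna(len[["sp1"]])
  sp3_seq <- random_rna(len[["sp3"]])
  sp5_seq <- random_rna(len[["sp5"]])

  if (spec$mir_arm == "3p") {
    segs <- c(sp1 = sp1_seq, `miR*` = star_seq, sp2 = sp2_seq,
              ACR5 = acr5_seq, sp3 = sp3_seq, ACR3 = acr3_seq,
              sp4 = sp4_seq, miR = mir_seq, sp5 = sp5_seq)
  } else {
    segs <- c(sp1 = sp1_seq, miR = mir_seq, sp2 = sp4_seq,
              ACR5 = acr5_seq, sp3 = sp3_seq, ACR3 = acr3_seq,
              sp4 = sp2_seq, miR_star = star_seq, sp5 = sp5_seq)
  }
  starts <- cumsum(c(0, nchar(segs)))[seq_along(segs)]
  names(starts) <- names(segs)
  seq <- paste(segs, collapse = "")
  iv <- function(nm) c(starts[[nm]], starts[[nm]] + nchar(segs[[nm]]))
  chars <- strsplit(seq, "")[[1]]

  pairs <- list()
  # miR:miR* duplex (antiparallel offsets from build_duplex)
  if (spec$mir_arm == "3p") {
    mir_iv <- iv("miR"); star_iv <- iv("miR*")
    pairs <- c(pairs, lapply(seq_len(nrow(dup$pairs)), function(r) {
      c(star_iv[1] + dup$pairs[r, 2], mir_iv[1] + dup$pairs[r, 1])
    }))
    sp5p <- iv("sp2"); sp3p <- iv("sp4")
  } else {
    mir_iv <- iv("miR"); star_iv <- iv("miR_star")
    # mirrored: star offsets run 5'->3' on the 3' arm; the duplex map is
    # reused with roles swapped (mir offset ascends with coordinates)
    pairs <- c(pairs, lapply(seq_len(nrow(dup$pairs)), function(r) {
      c(mir_iv[1] + dup$pairs[r, 1], star_iv[1] + dup$pairs[r, 2])
    }))
    sp5p <- iv("sp2"); sp3p <- iv("sp4")
  }
  # ACR duplex: full reverse-complement pairing
  a5 <- iv("ACR5"); a3 <- iv("ACR3")
  La <- nchar(acr5_seq)
  pairs <- c(pairs, lapply(seq_len(La), function(k) {
    c(a5[1] + k - 1L, a3[2] - k)
  }))
  # connecting stem sp2:sp4 (or mirrored)
  Ls <- nchar(sp4_seq)
  for (k in seq_len(Ls)) {
    if (!sp_paired[k]) next
    if (spec$mir_arm == "5p" && k <= 2L) next  # reserved for the overhang
    p5 <- sp5p[1] + k - 1L
    p3 <- sp3p[2] - k
    if (is_canonical_pair(chars[p5 + 1L], chars[p3 + 1L])) {
      pairs[[length(pairs) + 1L]] <- c(p5, p3)
    }
  }
  # continue the stem across the duplex ends so that the miR's 3'
  # overhang is paired in the hairpin (as in real precursors, where the
  # lower / connecting stem continues past the duplex)
  mirc <- strsplit(mir_seq, "")[[1]]
  Lm <- length(mirc)
  if (spec$mir_arm == "3p") {
    # miR 3' end (base side) pairs the tail of sp1
    ov <- rbind(c(star_iv[1] - 1L, mir_iv[1] + Lm - 2L),
                c(star_iv[1] - 2L, mir_iv[1] + Lm - 1L))
  } else {
    # miR 3' end (loop side) pairs the tail of the 3'-arm spacer
    ov <- rbind(c(mir_iv[1] + Lm - 2L, sp3p[2] - 1L),
                c(mir_iv[1] + Lm - 1L, sp3p[2] - 2L))
  }
  for (r in 1:2) {
    mir_side <- if (spec$mir_arm == "3p") ov[r, 2] else ov[r, 1]
    other <- if (spec$mir_arm == "3p") ov[r, 1] else ov[r, 2]
    chars[other + 1L] <- comp_base(chars[mir_side + 1L])
    pairs[[length(pairs) + 1L]] <- ov[r, ]
  }
  seq <- paste(chars, collapse = "")
  pm <- do.call(rbind, pairs)
  pm <- pm[pm[, 1] < pm[, 2], , drop = FALSE]
  ss <- secondary_structure(pm, nchar(seq))
  h <- hairpin(seq, ss, id = sprintf("synth_h%d", spec$seed))

  scheme <- NULL
  if (spec$violate == "none" && !length(spec$mir_bulge_runs) &&
      spec$star_insert == 0L) {
    scheme <- build_partitions(h, unname(mir_iv), unname(a5), unname(a3),
                               star = unname(star_iv))
  }
  list(hairpin = h, mir = unname(mir_iv), star = unname(star_iv),
       scheme = scheme, type = 1L, acr5_seq = acr5_seq,
       acr3_seq = acr3_seq, violate = spec$violate, seed = spec$seed)
}

is_canonical_pair <- function(a, b) {
  paste0(a, b) %in% canonical_pair_types
}

# short form: [sp1][miR*][loop(D)][miR][sp5]; used for force_D (type 2 /
# rule 7) and for the rule-1 geometry (reported miR straddles the loop)
gen_hairpin_short <- function(spec, mir_seq) {
  len <- spec$lengths
  D <- as.integer(spec$force_D %||% 30)
  dup <- build_duplex(mir_seq, integer(0), integer(0), 0L)
  star_seq <- dup$star_seq
  segs <- c(sp1 = random_rna(len[["sp1"]]), `miR*` = star_seq,
            loop = random_rna(max(D, 4L)), miR = mir_seq,
            sp5 = random_rna(len[["sp5"]]))
  starts <- cumsum(c(0, nchar(segs)))[seq_along(segs)]
  names(starts) <- names(segs)
  seq <- paste(segs, collapse = "")
  mir_iv <- c(starts[["miR"]], starts[["miR"]] + nchar(mir_seq))
  star_iv <- c(starts[["miR*"]], starts[["miR*"]] + nchar(star_seq))
  pairs <- lapply(seq_len(nrow(dup$pairs)), function(r) {
    c(star_iv[1] + dup$pairs[r, 2], mir_iv[1] + dup$pairs[r, 1])
  })
  # pair the miR 3' overhang into the lower stem (tail of sp1)
  chars <- strsplit(seq, "")[[1]]
  Lm <- nchar(mir_seq)
  for (r in 1:2) {
    mir_pos <- mir_iv[1] + Lm - r
    sp1_pos <- star_iv[1] - 3L + r
    chars[sp1_pos + 1L] <- comp_base(chars[mir_pos + 1L])
    pairs[[length(pairs) + 1L]] <- c(sp1_pos, mir_pos)
  }
  seq <- paste(chars, collapse = "")
  ss <- secondary_structure(do.call(rbind, pairs), nchar(seq))
  h <- hairpin(seq, ss, id = sprintf("synth_h%d", spec$seed))
  if (spec$violate == "rule1") {
    mid <- h$loop_span[1]
    mir_iv <- c(mid - 10L, mid + 11L)   # straddles the terminal loop
    star_iv <- NULL
  }
  list(hairpin = h, mir = unname(mir_iv),
       star = if (is.null(star_iv)) NULL else unname(star_iv),
       scheme = NULL, type = 2L, acr5_seq = NULL, acr3_seq = NULL,
       violate = spec$violate, seed = spec$seed)
}

#' Generate a small-RNA library over a partitioned precursor
#'
#' Draws `depth` reads multinomially over the named partition
#' proportions (which may include `"leak"`), samples each read as an
#' exact substring overlapping its partition by at least
#' `overlap_fraction` (leak reads straddle partition boundaries below
#' the threshold), and adds off-precursor noise reads that inflate
#' `total_reads` without mapping.
#'
#' @param h a `hairpin`.
#' @param scheme its `partition_scheme`.
#' @param proportions named numeric vector over partitions (and
#'   optionally `"leak"`), summing to 1.
#' @param depth number of precursor-derived reads.
#' @param seed RNG seed.
#' @param sample_id library name.
#' @param read_lens,read_len_probs read-length distribution (default
#'   21 +/- 1).
#' @param noise_fraction fraction of the final library that is
#'   off-precursor noise (default 0.05).
#' @param params [quant_params()] used to verify planted assignments.
#' @return list with `library` (an [srna_library()]), `proportions`
#'   (the planted truth), `depth` and `seed`.
#' @export
gen_library <- function(h, scheme, proportions, depth = 1e5, seed = 1L,
                        sample_id = sprintf("synthlib%d", seed),
                        read_lens = 20:22,
                        read_len_probs = c(0.2, 0.6, 0.2),
                        noise_fraction = 0.05,
                        params = quant_params()) {
  set.seed(seed)
  stopifnot(abs(sum(proportions) - 1) < 1e-9)
  n <- nchar(h$seq)
  counts <- stats::rmultinom(1, depth, proportions)[, 1]
  names(counts) <- names(proportions)
  reads <- character(0)
  for (part in names(proportions)) {
    k <- counts[[part]]
    if (k == 0) next
    lens <- sample(read_lens, k, replace = TRUE, prob = read_len_probs)
    for (L in unique(lens)) {
      kk <- sum(lens == L)
      pool <- start_pool(scheme, part, L, n, params)
      starts <- pool[sample.int(length(pool), kk, replace = TRUE)]
      reads <- c(reads, substring(h$seq, starts + 1L, starts + L))
    }
  }
  n_noise <- round(depth * noise_fraction / (1 - noise_fraction))
  noise <- vapply(seq_len(n_noise), function(i) {
    repeat {
      s <- random_rna(sample(read_lens, 1, prob = read_len_probs))
      if (!grepl(s, h$seq, fixed = TRUE)) return(s)
    }
  }, character(1))
  all_reads <- c(reads, noise)
  tab <- table(all_reads)
  rec <- data.frame(sequence = names(tab), count = as.numeric(tab),
                    stringsAsFactors = FALSE)
  list(library = srna_library(sample_id, rec,
                              total_reads = length(all_reads)),
       proportions = proportions, depth = depth, seed = seed)
}

# all start positions whose L-nt read is assigned to `part` (or to leak)
start_pool <- function(scheme, part, L, n, params) {
  cand <- 0:(n - L)
  assigned <- vapply(cand, function(a) {
    assign_partition(c(a, a + L), scheme, params)
  }, character(1))
  ok <- cand[assigned == part]
  if (!length(ok)) stop("partition '", part, "' cannot host a ", L, "-nt read")
  ok
}

#' Generate a PARE tag library with planted cleavage hot-spots
#'
#' @param target sense-strand target sequence (e.g. a ~1 kb context from
#'   [embed_precursor()]).
#' @param hotspots named numeric vector: 0-based position -> probability
#'   (positions are 5'-end sites; names are the positions).
#' @param depth number of tags drawn.
#' @param seed RNG seed.
#' @param sample_id library name.
#' @param tag_lens tag lengths sampled uniformly (default 20:21).
#' @return list with `library` (a [pare_library()]), `truth` (expected
#'   TP10M per planted site) and `modal_site`.
#' @export
gen_pare <- function(target, hotspots, depth = 1e4, seed = 1L,
                     sample_id = sprintf("synthpare%d", seed),
                     tag_lens = 20:21) {
  set.seed(seed)
  pos <- as.integer(names(hotspots))
  p <- hotspots / sum(hotspots)
  n <- nchar(target)
  stopifnot(all(pos >= 0), all(pos + max(tag_lens) <= n))
  draws <- sample(seq_along(pos), depth, replace = TRUE, prob = p)
  lens <- sample(tag_lens, depth, replace = TRUE)
  tags <- substring(target, pos[draws] + 1L, pos[draws] + lens)
  tab <- table(tags)
  lib <- pare_library(sample_id,
                      data.frame(sequence = names(tab),
                                 count = as.numeric(tab),
                                 stringsAsFactors = FALSE),
                      total_reads = depth)
  truth <- p * depth * 1e7 / depth
  names(truth) <- pos
  list(library = lib, truth = truth,
       modal_site = pos[which.max(p)], seed = seed)
}

#' Embed a precursor at the centre of a random context
#'
#' @param h a `hairpin`.
#' @param context_len total context length (default 1000).
#' @param seed RNG seed.
#' @return list with `seq`, `offset` (0-based precursor start).
#' @export
embed_precursor <- function(h, context_len = 1000L, seed = 1L) {
  set.seed(seed)
  n <- nchar(h$seq)
  stopifnot(context_len >= n)
  left <- (context_len - n) %/% 2L
  list(seq = paste0(random_rna(left), h$seq,
                    random_rna(context_len - n - left)),
       offset = left)
}

#' Evolve a structural alignment down a tree
#'
#' Simulates characters under the partitioned model: a 4-state CTMC for
#' unpaired columns and the 16-state doublet CTMC for planted pairs,
#' with discrete-gamma site rates and exact (spectral) transition
#' probabilities. Substitutions only; the alignment (no indels) is the
#' simulation frame.
#'
#' @param tree rooted or unrooted `ape` phylo with branch lengths.
#' @param model a [subst_model()].
#' @param n_pairs number of doublet column pairs.
#' @param n_unpaired number of unpaired columns.
#' @param seed RNG seed.
#' @return list with `aln` (a `structural_alignment`; pair columns form
#'   a nested helix block followed by the unpaired block), `partition`
#'   (the true [site_partition()]), `rates` (per-column-category draw)
#'   and `seed`.
#' @export
evolve_alignment <- function(tree, model, n_pairs, n_unpaired, seed = 1L) {
  set.seed(seed)
  ncol_total <- 2L * n_pairs + n_unpaired
  pair_cols <- if (n_pairs > 0) {
    # a nested helix with a terminal loop of unpaired columns between
    # the arms, so every planted pair respects the minimum loop size
    loop_len <- min(4L, n_unpaired)
    i <- seq_len(n_pairs) - 1L
    cbind(i, 2L * n_pairs + loop_len - 1L - i)
  } else matrix(integer(0), ncol = 2)
  partition <- site_partition(ncol_total, pairs = pair_cols)
  Q4 <- gtr_rate_matrix(model)
  Q16 <- doublet_rate_matrix(model)
  rates <- discrete_gamma(model$alpha, model$ncat)
  cat4 <- sample(model$ncat, n_unpaired, replace = TRUE)
  cat16 <- sample(model$ncat, n_pairs, replace = TRUE)

  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  N <- ntip + tr$Nnode
  state4 <- matrix(NA_integer_, N, n_unpaired)
  state16 <- matrix(NA_integer_, N, n_pairs)
  if (n_unpaired) state4[root, ] <- sample(4, n_unpaired, TRUE,
                                           prob = model$base_freqs)
  if (n_pairs) {
    # the ancestral structure is real: planted pairs start canonical,
    # with frequencies proportional to the stationary canonical mass
    canon16 <- which(doublet_states() %in% canonical_pair_types)
    p16 <- model$doublet_freqs[canon16]
    state16[root, ] <- canon16[sample(length(canon16), n_pairs, TRUE,
                                      prob = p16 / sum(p16))]
  }
  # preorder: reverse postorder edge order
  edges <- tr$edge[rev(seq_len(nrow(tr$edge))), , drop = FALSE]
  elen <- tr$edge.length[rev(seq_len(nrow(tr$edge)))]
  for (k in seq_len(nrow(edges))) {
    par <- edges[k, 1]; ch <- edges[k, 2]; t <- elen[k]
    if (n_unpaired) {
      for (c in unique(cat4)) {
        P <- transition_prob(Q4, model$base_freqs, t * rates[c])
        cols <- which(cat4 == c)
        state4[ch, cols] <- vapply(cols, function(j) {
          sample(4, 1, prob = P[state4[par, j], ])
        }, integer(1))
      }
    }
    if (n_pairs) {
      for (c in unique(cat16)) {
        P <- transition_prob(Q16, model$doublet_freqs, t * rates[c])
        cols <- which(cat16 == c)
        state16[ch, cols] <- vapply(cols, function(j) {
          sample(16, 1, prob = P[state16[par, j], ])
        }, integer(1))
      }
    }
  }
  m <- matrix("-", ntip, ncol_total)
  rownames(m) <- tr$tip.label
  nuc <- c("A", "C", "G", "U")
  for (tp in seq_len(ntip)) {
    if (n_unpaired) m[tp, partition$unpaired + 1L] <- nuc[state4[tp, ]]
    if (n_pairs) {
      s <- state16[tp, ]
      m[tp, pair_cols[, 1] + 1L] <- nuc[(s - 1L) %/% 4L + 1L]
      m[tp, pair_cols[, 2] + 1L] <- nuc[(s - 1L) %% 4L + 1L]
    }
  }
  list(aln = structural_alignment(m), partition = partition,
       cat4 = cat4, cat16 = cat16, seed = seed)
}

#' Generate a gene family by birth-death on a species tree
#'
#' One gene lineage enters the species root; along every species-tree
#' edge each lineage duplicates a Poisson(dup_rate x length) number of
#' times and each resulting copy is lost with probability
#' `1 - exp(-loss_rate x length)`. The complete event log is retained,
#' so reconciliation counts (a parsimony lower bound) can be compared
#' with the true counts.
#'
#' @param species_tree rooted `ape` phylo (branch lengths default to 1
#'   when absent).
#' @param dup_rate,loss_rate per-unit-length event rates (>= 0).
#' @param seed RNG seed.
#' @param max_tries regeneration attempts when every lineage dies.
#' @return list with `gene_tree` (rooted phylo), `tip_map`, `events`
#'   (data.frame: type, species edge child node), `n_dup_true`,
#'   `n_loss_true`, `seed` and `tries`.
#' @export
gen_family <- function(species_tree, dup_rate = 0.2, loss_rate = 0.1,
                       seed = 1L, max_tries = 100L) {
  stopifnot(dup_rate >= 0, loss_rate >= 0, ape::is.rooted(species_tree))
  st <- species_tree
  if (is.null(st$edge.length)) st$edge.length <- rep(1, nrow(st$edge))
  ntip <- length(st$tip.label)
  children <- split(seq_len(nrow(st$edge)), st$edge[, 1])
  for (try in seq_len(max_tries)) {
    set.seed(seed + (try - 1L) * 1000L)
    events <- list()
    counter <- new.env()
    counter$tip <- stats::setNames(rep(0L, ntip), st$tip.label)
    grow <- function(edge_idx) {
      # a lineage entering species edge edge_idx; returns newick or NULL
      ch <- st$edge[edge_idx, 2]
      t <- st$edge.length[edge_idx]
      ndup <- stats::rpois(1, dup_rate * t)
      copies <- 1L + ndup
      if (ndup > 0) {
        for (i in seq_len(ndup)) {
          events[[length(events) + 1L]] <<- data.frame(type = "dup",
                                                       species_node = ch)
        }
      }
      subtrees <- character(0)
      for (i in seq_len(copies)) {
        if (stats::runif(1) < 1 - exp(-loss_rate * t)) {
          events[[length(events) + 1L]] <<- data.frame(type = "loss",
                                                       species_node = ch)
          next
        }
        nk <- descend(ch)
        if (!is.null(nk)) subtrees <- c(subtrees, nk)
      }
      if (!length(subtrees)) return(NULL)
      if (length(subtrees) == 1) return(subtrees)
      # join surviving copies as a caterpillar of duplication nodes
      Reduce(function(a, b) sprintf("(%s,%s)", a, b), subtrees)
    }
    descend <- function(node) {
      if (node <= ntip) {
        lbl <- st$tip.label[node]
        counter$tip[lbl] <- counter$tip[lbl] + 1L
        return(sprintf("%s_g%d", lbl, counter$tip[lbl]))
      }
      kid_edges <- children[[as.character(node)]]
      parts <- character(0)
      for (e in kid_edges) {
        sub <- grow(e)
        if (!is.null(sub)) parts <- c(parts, sub)
      }
      if (!length(parts)) return(NULL)
      if (length(parts) == 1) return(parts)
      sprintf("(%s)", paste(parts, collapse = ","))
    }
    root <- ntip + 1L
    txt <- descend(root)
    ntips_out <- if (is.null(txt)) 0L else
      lengths(regmatches(txt, gregexpr("_g", txt)))
    if (ntips_out >= 2L) {
      gt <- ape::read.tree(text = paste0(txt, ";"))
      gt <- ape::multi2di(gt, random = FALSE)
      tip_map <- sub("_g\\d+$", "", gt$tip.label)
      names(tip_map) <- gt$tip.label
      ev <- if (length(events)) do.call(rbind, events) else
        data.frame(type = character(0), species_node = integer(0))
      return(list(gene_tree = gt, tip_map = tip_map, events = ev,
                  n_dup_true = sum(ev$type == "dup"),
                  n_loss_true = sum(ev$type == "loss"),
                  seed = seed, tries = try))
    }
  }
  stop("all gene lineages lost in ", max_tries, " attempts")
}
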