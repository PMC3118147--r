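# Mature-miRNA homolog scanning and the seven modified miRcheck rules.

#' Scan parameters for homolog search
#'
#' @param flank_len flanking sequence retrieved on either side of a hit
#'   (nt); 350 by default, truncated at sequence ends ("as long as
#'   possible").
#' @param max_edit_homolog maximum edit distance for full homolog status.
#' @param edit_candidate edit distance at which a hit is only a candidate
#'   homolog; hits with larger distance are rejected.
#' @return list of class `scan_params`.
#' @export
scan_params <- function(flank_len = 350L, max_edit_homolog = 3L,
                        edit_candidate = 4L) {
  stopifnot(flank_len > 0, max_edit_homolog < edit_candidate)
  structure(list(flank_len = as.integer(flank_len),
                 max_edit_homolog = as.integer(max_edit_homolog),
                 edit_candidate = as.integer(edit_candidate)),
            class = "scan_params")
}

#' miRcheck rule thresholds
#'
#' Thresholds of the seven hairpin-filtering rules: (1) miR and miR* each
#' on a single arm; (2) at most `max_unpaired_mir` unpaired miR bases;
#' (3) at most `max_bulges_mir` maximal runs of unpaired miR bases;
#' (4) miR/miR* length difference at most `max_len_diff`; (5) at most
#' `max_asym_unpaired` asymmetrically unpaired miR bases; (6) longest run
#' of unpaired miR bases at most `max_contig_unpaired`; (7) the
#' loop-spanning miR-to-miR* distance within
#' `[min_mir_star_dist, max_mir_star_dist]`.
#'
#' `stability_min` is the machine replacement for the manual
#' loose-structure screen: at least this fraction of miR and miR*
#' positions must be paired.
#'
#' @param max_unpaired_mir,max_bulges_mir,max_len_diff,max_asym_unpaired,max_contig_unpaired,min_mir_star_dist,max_mir_star_dist rule thresholds.
#' @param stability_min minimum paired fraction over miR plus miR*.
#' @return list of class `mircheck_params`.
#' @export
mircheck_params <- function(max_unpaired_mir = 6L, max_bulges_mir = 3L,
                            max_len_diff = 3L, max_asym_unpaired = 3L,
                            max_contig_unpaired = 3L,
                            min_mir_star_dist = 5L,
                            max_mir_star_dist = 300L,
                            stability_min = 0.5) {
  p <- list(max_unpaired_mir = max_unpaired_mir,
            max_bulges_mir = max_bulges_mir,
            max_len_diff = max_len_diff,
            max_asym_unpaired = max_asym_unpaired,
            max_contig_unpaired = max_contig_unpaired,
            min_mir_star_dist = min_mir_star_dist,
            max_mir_star_dist = max_mir_star_dist,
            stability_min = stability_min)
  stopifnot(all(unlist(p) >= 0), min_mir_star_dist <= max_mir_star_dist)
  structure(p, class = "mircheck_params")
}

# unit-cost Levenshtein distance; used by the scanner's verification step
# and by assign_name (tests compare against utils::adist independently)
lev_dist <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  m <- length(a); n <- length(b)
  prev <- 0:n
  for (i in seq_len(m)) {
    cur <- c(i, rep(0L, n))
    for (j in seq_len(n)) {
      cur[j + 1L] <- min(prev[j] + (a[i] != b[j]), prev[j + 1L] + 1L,
                         cur[j] + 1L)
    }
    prev <- cur
  }
  prev[n + 1L]
}

# semi-global DP (free start, free end scored per end column): returns the
# minimum edit distance of query against any window of target ending at
# each target position
semiglobal_end_dist <- function(query, target) {
  q <- strsplit(query, "")[[1]]
  t <- strsplit(target, "")[[1]]
  n <- length(t)
  idx <- seq_len(n)
  row <- rep(0L, n + 1L)
  for (i in seq_along(q)) {
    sub <- as.integer(q[i] != t)
    tmp <- pmin(row[idx] + sub, row[idx + 1L] + 1L)
    row <- cummin_relax(c(i, tmp))
  }
  row[-1L]
}

# exact left-to-right relaxation x[j] = min(x[j], x[j-1] + 1), vectorized:
# min_k<=j (x[k] + j - k) = (cummin of x[k] - k) + j
cummin_relax <- function(x) {
  j <- seq_along(x)
  pmin(x, cummin(x - j) + j)
}

#' Find approximate matches of a mature-miRNA query in a target
#'
#' Reports every cluster of target windows whose Levenshtein distance to
#' the query is at most `max_edits`, on both the given strand and its
#' reverse complement. Overlapping qualifying windows are merged to a
#' single representative: the window with the smallest edit distance,
#' ties broken by leftmost start, then by shortest interval. `N` bases in
#' the target never match (unit cost).
#'
#' @param target RNA string (may contain `N`).
#' @param query mature miRNA RNA string, length 18-26.
#' @param max_edits maximum edit distance (mismatches plus indels).
#' @return data.frame with columns `start`, `end` (0-based half-open, on
#'   the input strand), `strand` (`+`/`-`), `edit_distance`.
#' @export
find_matches <- function(target, query, max_edits) {
  stopifnot(max_edits >= 0)
  query <- normalize_rna(query)
  m <- nchar(query)
  if (m < 18L || m > 26L) stop("mature query length must be in [18, 26]")
  if (!nzchar(target)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), edit_distance = integer(0)))
  }
  target <- normalize_rna(target, allow_n = TRUE)
  scan1 <- function(tgt, strand) {
    tgt_mask <- chartr("N", "?", tgt)  # '?' never equals a query base
    n <- nchar(tgt_mask)
    dend <- semiglobal_end_dist(query, tgt_mask)
    ends <- which(dend <= max_edits)  # 1-based inclusive == 0-based exclusive
    if (!length(ends)) return(NULL)
    wins <- do.call(rbind, lapply(ends, function(e) {
      ss <- max(0L, e - m - max_edits):max(0L, min(e - 1L, e - m + max_edits))
      ss <- unique(ss[ss < e])
      d <- vapply(ss, function(s) {
        lev_dist(query, substr(tgt_mask, s + 1L, e))
      }, numeric(1))
      keep <- d <= max_edits
      if (!any(keep)) return(NULL)
      cbind(start = ss[keep], end = e, d = d[keep])
    }))
    if (is.null(wins)) return(NULL)
    if (strand == "-") {  # map back to input-strand coordinates
      wins <- cbind(start = n - wins[, "end"], end = n - wins[, "start"],
                    d = wins[, "d"])
    }
    data.frame(start = wins[, "start"], end = wins[, "end"],
               strand = strand, edit_distance = wins[, "d"])
  }
  wins <- rbind(scan1(target, "+"), scan1(rna_revcomp(target), "-"))
  if (is.null(wins) || !nrow(wins)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), edit_distance = integer(0)))
  }
  merge_hit_windows(wins)
}

# cluster overlapping windows per strand; keep the representative with the
# best edit distance, then leftmost start, then shortest interval
merge_hit_windows <- function(wins) {
  out <- lapply(split(wins, wins$strand), function(w) {
    w <- w[order(w$start, w$end), , drop = FALSE]
    cl <- integer(nrow(w)); cl[1] <- 1L
    hi <- w$end[1]
    for (i in seq_len(nrow(w))[-1]) {
      if (w$start[i] < hi) cl[i] <- cl[i - 1L]
      else cl[i] <- cl[i - 1L] + 1L
      hi <- max(hi, w$end[i])
    }
    do.call(rbind, lapply(split(w, cl), function(g) {
      g <- g[order(g$edit_distance, g$start, g$end - g$start), , drop = FALSE]
      g[1, , drop = FALSE]
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Extract a hit with flanking sequence
#'
#' Retrieves `flank_len` nucleotides on either side of the hit, truncated
#' at the sequence ends.
#'
#' @param target RNA string.
#' @param hit 0-based half-open interval of the hit on `target`.
#' @param flank_len flank length (nt).
#' @return list with `seq` (the extract), `offset` (0-based start of the
#'   extract on the target) and `hit_local` (hit interval within the
#'   extract).
#' @export
extract_flanks <- function(target, hit, flank_len = 350L) {
  n <- nchar(target)
  stopifnot(hit[1] >= 0, hit[2] <= n, hit[1] < hit[2])
  s <- max(0L, hit[1] - flank_len)
  e <- min(n, hit[2] + flank_len)
  list(seq = substr(target, s + 1L, e), offset = s,
       hit_local = c(hit[1] - s, hit[2] - s))
}

#' Locate the miRNA* interval for a miR on a hairpin
#'
#' The miR* is the minimal interval on the opposite arm containing the
#' pairing partners of the miR with the standard 2-nt 3'-overhang offset:
#' the miR's own 3'-terminal two nucleotides are excluded from the
#' partner set and the miR* 3' end is extended two nucleotides past the
#' partner of the miR 5' end (clipped at the terminal loop and at the
#' sequence ends). For a perfectly paired duplex this reproduces the
#' familiar miRNA/miRNA* duplex with two-nucleotide 3' overhangs on both
#' strands.
#'
#' @param h a `hairpin`.
#' @param mir 0-based half-open miR interval; must not overlap the loop.
#' @return 0-based half-open miR* interval.
#' @export
locate_star <- function(h, mir) {
  if (arm_of(h, mir) == "spans_loop") {
    stop("miR interval overlaps the terminal loop")
  }
  idx <- (mir[1] + 1L):mir[2]           # 1-based positions of miR
  partners <- h$partner[idx]
  if (all(is.na(partners))) stop("miR entirely unpaired")
  core_idx <- idx[seq_len(max(0L, length(idx) - 2L))]  # drop miR 3' 2 nt
  core <- h$partner[core_idx]
  core <- core[!is.na(core)]
  if (!length(core)) core <- partners[!is.na(partners)]
  star <- c(min(core), min(max(core) + 1L + 2L, nchar(h$seq)))
  # the +2 extension is the star's 3' overhang; the paired core is kept
  # for arm classification (the overhang may protrude into the loop)
  attr(star, "core") <- c(min(core), max(core) + 1L)
  star
}

#' Evaluate the seven hairpin-filtering (miRcheck) rules
#'
#' @param h a `hairpin`.
#' @param mir 0-based half-open miR interval.
#' @param params a [mircheck_params()] object.
#' @return list of class `mircheck_report`: per-rule measured `value` and
#'   `pass` flag (`rule1` .. `rule7`), `overall` (AND of the seven),
#'   `mir`, `star` intervals, `arm` of the miR, and `stable` (the
#'   paired-fraction screen, reported separately from the seven rules).
#' @export
evaluate_mircheck <- function(h, mir, params = mircheck_params()) {
  rules <- vector("list", 7)
  names(rules) <- paste0("rule", 1:7)

  # rules 2, 3 and 6 depend on the miR interval alone
  idx <- (mir[1] + 1L):mir[2]
  unpaired <- is.na(h$partner[idx])
  rules$rule2 <- list(value = sum(unpaired),
                      pass = sum(unpaired) <= params$max_unpaired_mir)
  r <- rle(unpaired)
  runs <- r$lengths[r$values]
  rules$rule3 <- list(value = length(runs),
                      pass = length(runs) <= params$max_bulges_mir)
  maxrun <- if (length(runs)) max(runs) else 0L
  rules$rule6 <- list(value = maxrun,
                      pass = maxrun <= params$max_contig_unpaired)

  arm_mir <- arm_of(h, mir)
  star <- tryCatch(locate_star(h, mir), error = function(e) e)
  if (inherits(star, "error")) {
    # no miR* can be located: the duplex-dependent rules fail
    rules$rule1 <- list(value = conditionMessage(star), pass = FALSE)
    for (k in c("rule4", "rule5", "rule7")) {
      rules[[k]] <- list(value = NA, pass = FALSE)
    }
    return(structure(list(rules = rules, overall = FALSE, mir = mir,
                          star = NULL, arm = arm_mir, stable = FALSE),
                     class = "mircheck_report"))
  }
  arm_star <- arm_of(h, attr(star, "core"))
  rules$rule1 <- list(value = paste(arm_mir, arm_star),
                      pass = arm_mir != "spans_loop" &&
                             arm_star != "spans_loop" && arm_mir != arm_star)
  len_diff <- abs((mir[2] - mir[1]) - (star[2] - star[1]))
  rules$rule4 <- list(value = len_diff, pass = len_diff <= params$max_len_diff)
  asym <- asym_unpaired_count(h, mir)
  rules$rule5 <- list(value = asym, pass = asym <= params$max_asym_unpaired)
  D <- loop_gap(mir, star)
  rules$rule7 <- list(value = D, pass = D >= params$min_mir_star_dist &&
                        D <= params$max_mir_star_dist)
  duplex_idx <- c(idx, (star[1] + 1L):star[2])
  paired_frac <- mean(!is.na(h$partner[duplex_idx]))
  structure(list(rules = rules,
                 overall = all(vapply(rules, `[[`, logical(1), "pass")),
                 mir = mir, star = c(star), arm = arm_mir,
                 stable = paired_frac >= params$stability_min),
            class = "mircheck_report")
}

# count of unpaired miR bases not mirrored by unpaired miR*-side bases
# between the same flanking pairs; edge runs (no flanking pair within the
# miR on one side) are duplex-end overhangs, not bulges, and are skipped
asym_unpaired_count <- function(h, mir) {
  idx <- (mir[1] + 1L):mir[2]
  unpaired <- is.na(h$partner[idx])
  if (!any(unpaired)) return(0L)
  r <- rle(unpaired)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  total <- 0L
  for (k in which(r$values)) {
    if (starts[k] == 1L || ends[k] == length(idx)) next
    pL <- idx[starts[k] - 1L]; pR <- idx[ends[k] + 1L]
    qL <- h$partner[pL]; qR <- h$partner[pR]
    gap_star <- abs(qL - qR) - 1L
    total <- total + max(0L, r$lengths[k] - gap_star)
  }
  total
}

# nucleotides strictly between the loop-proximal ends of two intervals on
# opposite arms (the D statistic; also the rule-7 distance)
loop_gap <- function(a, b) {
  five <- if (a[2] <= b[1]) a else b
  three <- if (identical(five, a)) b else a
  three[1] - five[2]
}

#' Call homolog status from edit distance and a miRcheck report
#'
#' Rejected whenever the seven rules do not all pass; otherwise homolog at
#' edit distance up to `max_edit_homolog`, candidate at up to
#' `edit_candidate`, rejected beyond.
#'
#' @param edit_distance integer edit distance of the hit.
#' @param report a `mircheck_report`.
#' @param params a [scan_params()] object.
#' @return `"homolog"`, `"candidate"` or `"rejected"`.
#' @export
call_status <- function(edit_distance, report, params = scan_params()) {
  if (!isTRUE(report$overall)) return("rejected")
  if (edit_distance <= params$max_edit_homolog) return("homolog")
  if (edit_distance <= params$edit_candidate) return("candidate")
  "rejected"
}

#' Assign a family name by the nearest reference mature miRNA
#'
#' Returns the id of the reference with the smallest Levenshtein distance
#' to the hit; ties are broken by lexicographic reference id.
#'
#' @param residues RNA string of the hit miR.
#' @param references named character vector of reference mature miRNAs.
#' @return the selected reference id.
#' @export
assign_name <- function(residues, references) {
  stopifnot(length(references) > 0, !is.null(names(references)))
  d <- vapply(references, function(r) lev_dist(residues, r), numeric(1))
  ids <- names(references)
  ids[order(d, ids)][1]
}

#' Identical positions in an optimal global alignment
#'
#' Number of identical aligned positions in an optimal
#' Needleman-Wunsch global alignment with the standard nucleotide
#' scoring match = +1, mismatch = -1, gap = -2 per gapped column
#' (maximizing the match count among co-optimal alignments). This is
#' the sense in which two mature miRNAs "share k identical
#' nucleotides": gaps are penalized enough that spurious gap-rich
#' alignments do not inflate the identity count.
#'
#' @param a,b RNA strings.
#' @return integer match count.
#' @export
alignment_identity <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  m <- length(x); n <- length(y)
  gp <- -2L
  D <- matrix(0L, m + 1L, n + 1L)
  M <- matrix(0L, m + 1L, n + 1L)
  D[, 1] <- gp * (0:m); D[1, ] <- gp * (0:n)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      sub <- ifelse(x[i] == y[j], 1L, -1L)
      cands <- c(D[i, j] + sub, D[i, j + 1L] + gp, D[i + 1L, j] + gp)
      best <- max(cands)
      D[i + 1L, j + 1L] <- best
      mm <- -1L
      if (cands[1] == best) mm <- max(mm, M[i, j] + as.integer(sub > 0))
      if (cands[2] == best) mm <- max(mm, M[i, j + 1L])
      if (cands[3] == best) mm <- max(mm, M[i + 1L, j])
      M[i + 1L, j + 1L] <- mm
    }
  }
  structure(M[m + 1L, n + 1L], score = D[m + 1L, n + 1L])
}

#' Scan targets for MIR159/319-style homologs end to end
#'
#' For every approximate match of any query in any target: extract the
#' flanked context, fold it (or use a supplied structure), evaluate the
#' seven hairpin rules, call homolog/candidate status (hits failing the
#' paired-fraction stability screen are rejected) and assign the family
#' name of the nearest reference.
#'
#' @param targets named character vector of scan targets (may contain `N`).
#' @param queries named character vector of mature reference miRNAs.
#' @param params a [scan_params()].
#' @param mc a [mircheck_params()].
#' @param structures optional named list of dot-bracket strings per target
#'   extract id (`<target>|<start>-<end>`); extracts without one are
#'   folded with [fold_rna()].
#' @return data.frame with one row per merged hit: source id, strand, hit
#'   interval, edit distance, the seven rule flags, stability flag,
#'   status and assigned name; attribute `extracts` holds the precursor
#'   extracts as a named character vector.
#' @export
scan_homologs <- function(targets, queries, params = scan_params(),
                          mc = mircheck_params(), structures = NULL) {
  rows <- list()
  extracts <- character(0)
  for (tid in names(targets)) {
    for (qid in names(queries)) {
      hits <- find_matches(targets[[tid]], queries[[qid]],
                           params$edit_candidate)
      if (!nrow(hits)) next
      for (k in seq_len(nrow(hits))) {
        strand <- hits$strand[k]
        tgt <- if (strand == "+") targets[[tid]] else rna_revcomp(targets[[tid]])
        hit <- if (strand == "+") c(hits$start[k], hits$end[k]) else
          c(nchar(tgt) - hits$end[k], nchar(tgt) - hits$start[k])
        ext <- extract_flanks(tgt, hit, params$flank_len)
        eid <- sprintf("%s|%d-%d%s", tid, hits$start[k], hits$end[k], strand)
        seq_clean <- gsub("N", "A", ext$seq)  # fold over N-free proxy
        h <- tryCatch({
          ss <- structures[[eid]]
          hairpin(seq_clean, ss = ss, id = eid)
        }, error = function(e) NULL)
        if (is.null(h)) next
        rep <- evaluate_mircheck(h, ext$hit_local, mc)
        status <- call_status(hits$edit_distance[k], rep, params)
        if (!rep$stable) status <- "rejected"
        mir_seq <- substr(ext$seq, ext$hit_local[1] + 1L, ext$hit_local[2])
        rows[[length(rows) + 1L]] <- data.frame(
          source_id = tid, query_id = qid, strand = strand,
          hit_start = hits$start[k], hit_end = hits$end[k],
          edit_distance = hits$edit_distance[k],
          t(vapply(rep$rules, function(r) isTRUE(r$pass), logical(1))),
          stable = rep$stable, status = status,
          assigned_name = assign_name(mir_seq, queries),
          stringsAsFactors = FALSE)
        extracts[[eid]] <- ext$seq
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source_id = character(0))
  attr(out, "extracts") <- extracts
  out
}
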