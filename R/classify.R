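# Five-type precursor classification and the nine-partition scheme.
#
# Type decision table (D = loop-spanning miR-to-miR* distance;
# seq/str = sequence / structure conservation of the loop-proximal ACRs):
#   type 2:  D <= 60
#   type 1:  D > 60, seq yes, str yes
#   type 3:  D > 60, seq yes, str no
#   type 4:  D > 60, seq no,  str yes
#   type 5:  D > 60, seq no,  str no

#' ACR consensus input for conservation calls
#'
#' The consensus sequences of the two Alternative Conserved Regions are a
#' user input (typically derived from [consensus_sequence()] on a type-1
#' alignment), keeping the classifier family-agnostic.
#'
#' @param acr5,acr3 consensus RNA strings for the 5'-arm and 3'-arm ACR.
#' @param identity_min minimum best-window identity to call the sequence
#'   conserved (default 0.6).
#' @param pairing_min minimum fraction of ACR positions pairing into the
#'   opposite ACR window to call the structure conserved (default 0.6).
#' @return list of class `acr_consensus`.
#' @export
acr_consensus <- function(acr5, acr3, identity_min = 0.6, pairing_min = 0.6) {
  stopifnot(identity_min > 0, identity_min <= 1,
            pairing_min > 0, pairing_min <= 1)
  structure(list(acr5 = normalize_rna(acr5), acr3 = normalize_rna(acr3),
                 identity_min = identity_min, pairing_min = pairing_min),
            class = "acr_consensus")
}

#' Loop-spanning distance between miR and miR*
#'
#' Number of nucleotides strictly between the loop-proximal ends of the
#' miR and its miR* (the quantity bounded by rule 7, and the D column of
#' the type decision table: D at most 60 marks the short, type-2 form).
#'
#' @param h a `hairpin`.
#' @param mir 0-based half-open miR interval.
#' @return integer distance in nt.
#' @export
compute_D <- function(h, mir) {
  star <- locate_star(h, mir)
  loop_gap(mir, star)
}

# best ungapped identity of a consensus against windows of a region;
# window lengths len(cons) +/- 2, identity denominator = len(cons)
best_window_identity <- function(region_seq, cons) {
  L <- nchar(cons)
  cchars <- strsplit(cons, "")[[1]]
  n <- nchar(region_seq)
  best <- 0; best_win <- NULL
  for (wl in max(1L, L - 2L):(L + 2L)) {
    if (wl > n) next
    for (s in 0:(n - wl)) {
      w <- strsplit(substr(region_seq, s + 1L, s + wl), "")[[1]]
      k <- min(wl, L)
      ident <- sum(w[seq_len(k)] == cchars[seq_len(k)]) / L
      if (ident > best) { best <- ident; best_win <- c(s, s + wl) }
    }
  }
  list(identity = best, window = best_win)
}

#' Detect the Alternative Conserved Regions on an elongated stem
#'
#' Evaluates sequence and structure conservation of the loop-proximal
#' region between the miR/miR* duplex ends. Sequence conservation needs
#' a 5'-arm window at identity at least `identity_min` to the ACR5
#' consensus and a 3'-arm window likewise for ACR3 (ungapped sliding
#' windows with two nucleotides of length slack). Structure conservation
#' needs the candidate ACR windows to pair with each other at a pairing
#' fraction of at least `pairing_min`, with no multiloop in the
#' connecting stem: no position between the ACR duplex and the miR duplex
#' may pair outside that span.
#'
#' @param h a `hairpin`.
#' @param mir 0-based half-open miR interval.
#' @param cons an [acr_consensus()].
#' @return list with `seq_conserved`, `str_conserved`, `acr5`, `acr3`
#'   (0-based half-open intervals or `NULL` when not located).
#' @export
detect_acr <- function(h, mir, cons) {
  star <- locate_star(h, mir)
  D <- loop_gap(mir, star)
  if (D <= 60L) {
    stop("no elongated loop-proximal region (D <= 60): classify as type 2")
  }
  five <- if (mir[2] <= star[1]) mir else star   # element on the 5' arm
  three <- if (identical(five, mir)) star else mir
  gap <- c(five[2], three[1])                    # loop-proximal region
  gap_seq <- substr(h$seq, gap[1] + 1L, gap[2])

  # the identity search runs over the whole gap (when the second duplex
  # is disrupted the structure-derived loop is unreliable), requiring
  # the ACR5 window 5' of the ACR3 window
  m5 <- best_window_identity(gap_seq, cons$acr5)
  win5 <- if (!is.null(m5$window)) m5$window + gap[1] else NULL
  seq3_from <- if (is.null(win5)) gap[1] else win5[2]
  m3 <- best_window_identity(substr(h$seq, seq3_from + 1L, gap[2]),
                             cons$acr3)
  win3 <- if (!is.null(m3$window)) m3$window + seq3_from else NULL
  seq_conserved <- m5$identity >= cons$identity_min &&
    m3$identity >= cons$identity_min

  if (seq_conserved) {
    # the consensus-located windows must form the second duplex, and the
    # stem connecting them to the miR duplex must not branch
    frac <- pairing_fraction(h, win5, win3)
    str_conserved <- frac >= cons$pairing_min &&
      no_multiloop_between(h, win5, win3, five, three)
  } else {
    # without sequence evidence the criterion is elongated-stem
    # integrity: the loop-proximal region pairs through as one
    # (possibly bulged) stem closed by a terminal loop, rather than
    # being opened up or branched into multiloops
    p <- h$partner[(gap[1] + 1L):gap[2]]
    within <- !is.na(p) & p >= gap[1] & p < gap[2]
    frac <- mean(within)
    str_conserved <- frac >= cons$pairing_min
  }
  list(seq_conserved = seq_conserved, str_conserved = str_conserved,
       acr5 = if (seq_conserved) win5 else NULL,
       acr3 = if (seq_conserved) win3 else NULL,
       identity5 = m5$identity, identity3 = m3$identity,
       pairing = frac)
}

# fraction of positions of the two windows pairing into each other
pairing_fraction <- function(h, w5, w3) {
  i5 <- (w5[1] + 1L):w5[2]
  i3 <- (w3[1] + 1L):w3[2]
  p5 <- h$partner[i5]
  p3 <- h$partner[i3]
  into <- sum(!is.na(p5) & p5 >= w3[1] & p5 < w3[2]) +
    sum(!is.na(p3) & p3 >= w5[1] & p3 < w5[2])
  into / (length(i5) + length(i3))
}

# the connecting stem between the outer (miR:miR*) and inner (ACR) duplex
# must not branch: every paired position in the two spacer regions must
# pair into the opposite spacer region
no_multiloop_between <- function(h, acr5, acr3, five, three) {
  regA <- c(five[2], acr5[1])    # 5'-arm spacer (sp2-like)
  regB <- c(acr3[2], three[1])   # 3'-arm spacer (sp4-like)
  ok_region <- function(reg, opp) {
    if (reg[2] <= reg[1]) return(TRUE)
    p <- h$partner[(reg[1] + 1L):reg[2]]
    p <- p[!is.na(p)]
    all(p >= opp[1] & p < opp[2])
  }
  ok_region(regA, regB) && ok_region(regB, regA)
}

#' Classify a precursor into the five conservation types
#'
#' @param h a `hairpin` (assumed to have passed the seven hairpin rules).
#' @param mir 0-based half-open miR interval.
#' @param cons an [acr_consensus()].
#' @return list of class `type_record` with `id`, `D`, `seq_conserved`,
#'   `str_conserved`, `type` (1-5) and the located `acr5`/`acr3`
#'   intervals (type 1 only).
#' @export
classify_precursor <- function(h, mir, cons) {
  D <- compute_D(h, mir)
  if (D <= 60L) {
    rec <- list(id = h$id, D = D, seq_conserved = FALSE,
                str_conserved = FALSE, type = 2L, acr5 = NULL, acr3 = NULL)
    return(structure(rec, class = "type_record"))
  }
  acr <- detect_acr(h, mir, cons)
  type <- type_from_flags(D, acr$seq_conserved, acr$str_conserved)
  structure(list(id = h$id, D = D, seq_conserved = acr$seq_conserved,
                 str_conserved = acr$str_conserved, type = type,
                 acr5 = if (type == 1L) acr$acr5 else NULL,
                 acr3 = if (type == 1L) acr$acr3 else NULL),
            class = "type_record")
}

#' The five-type decision table
#'
#' Pure mapping from (D, seq, str) to the type label; exposed so the
#' decision table can be exercised on its own.
#'
#' @param D loop-spanning miR-to-miR* distance (nt).
#' @param seq_conserved,str_conserved logical conservation flags.
#' @return integer type in 1..5.
#' @export
type_from_flags <- function(D, seq_conserved, str_conserved) {
  if (D <= 60L) return(2L)
  if (seq_conserved && str_conserved) return(1L)
  if (seq_conserved) return(3L)
  if (str_conserved) return(4L)
  5L
}

#' Build the nine-partition scheme of a type-1 precursor
#'
#' The four conserved partitions (miR, miR*, ACR5, ACR3) are the located
#' intervals; the five space partitions sp1..sp5 fill the remaining gaps
#' in 5'-to-3' order (sp3 spans the terminal loop). Zero-length space
#' partitions are permitted. When the miR lies on the 5' arm the
#' conserved labels appear in mirrored order and the `orientation`
#' attribute records it.
#'
#' @param h a `hairpin`.
#' @param mir 0-based half-open miR interval.
#' @param acr5,acr3 located ACR intervals.
#' @param star optional; computed with [locate_star()] when missing.
#' @return a `partition_scheme`: data.frame with columns `name`, `start`,
#'   `end` tiling `[0, nchar(seq))`, attributes `orientation`
#'   (`"mir_3p"` or `"mir_5p"`) and `precursor_id`.
#' @export
build_partitions <- function(h, mir, acr5, acr3, star = NULL) {
  if (is.null(star)) star <- locate_star(h, mir)
  mir_on_3p <- arm_of(h, mir) == "three_prime"
  conserved <- if (mir_on_3p) {
    list(`miR*` = star, ACR5 = acr5, ACR3 = acr3, miR = mir)
  } else {
    list(miR = mir, ACR5 = acr5, ACR3 = acr3, `miR*` = star)
  }
  ord <- order(vapply(conserved, `[`, numeric(1), 1))
  conserved <- conserved[ord]
  starts <- vapply(conserved, `[`, numeric(1), 1)
  ends <- vapply(conserved, `[`, numeric(1), 2)
  if (any(starts[-1] < ends[-length(ends)])) {
    stop("conserved partitions overlap")
  }
  n <- nchar(h$seq)
  rows <- list()
  sp_bounds <- cbind(c(0, ends), c(starts, n))
  for (k in 1:5) {
    rows[[2 * k - 1]] <- data.frame(name = paste0("sp", k),
                                    start = sp_bounds[k, 1],
                                    end = sp_bounds[k, 2])
    if (k <= 4) {
      rows[[2 * k]] <- data.frame(name = names(conserved)[k],
                                  start = starts[k], end = ends[k])
    }
  }
  scheme <- do.call(rbind, rows)
  rownames(scheme) <- NULL
  lens <- scheme$end - scheme$start
  if (any(lens < 0) || sum(lens) != n) stop("partitions do not tile precursor")
  cl <- scheme$name %in% c("miR", "miR*", "ACR5", "ACR3")
  if (any(lens[cl] < 18 | lens[cl] > 26)) {
    stop("conserved partition length outside [18, 26]")
  }
  attr(scheme, "orientation") <- if (mir_on_3p) "mir_3p" else "mir_5p"
  attr(scheme, "precursor_id") <- h$id
  class(scheme) <- c("partition_scheme", "data.frame")
  scheme
}

#' Write partition schemes as BED-like TSV
#'
#' Columns: precursor_id, start, end, partition_name (0-based half-open).
#'
#' @param schemes list of `partition_scheme` objects.
#' @param path output file.
#' @export
write_partitions <- function(schemes, path) {
  rows <- do.call(rbind, lapply(schemes, function(s) {
    data.frame(precursor_id = attr(s, "precursor_id"),
               start = s$start, end = s$end, partition_name = s$name)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
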