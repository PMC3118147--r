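# Stem-loop precursor representation.
#
# Coordinate convention used across the whole package: 0-based, half-open
# intervals c(start, end) on the 5'->3' precursor strand.

#' Construct a validated secondary structure
#'
#' A secondary structure is a set of base pairs `(i, j)`, `i < j`, 0-based,
#' on a sequence of length `length`. Pairs must be mutually exclusive (each
#' position in at most one pair), non-crossing, and separated by at least
#' `min_loop` unpaired positions (`j - i >= min_loop + 1`).
#'
#' @param pairs two-column integer matrix of 0-based pair positions (may
#'   have zero rows).
#' @param length sequence length.
#' @param min_loop minimum hairpin-loop size (default 3).
#' @return object of class `secondary_structure` with elements `pairs`
#'   (ordered by `i`) and `length`.
#' @export
secondary_structure <- function(pairs, length, min_loop = 3L) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  length <- as.integer(length)
  stopifnot(length >= 1L)
  if (nrow(pairs)) {
    if (any(pairs < 0L) || any(pairs >= length)) stop("pair position out of bounds")
    if (any(pairs[, 1] >= pairs[, 2])) stop("pairs must have i < j")
    if (any(pairs[, 2] - pairs[, 1] < min_loop + 1L)) {
      stop("pair violates minimum loop size ", min_loop)
    }
    if (anyDuplicated(as.vector(pairs))) stop("position in more than one pair")
    ord <- order(pairs[, 1])
    pairs <- pairs[ord, , drop = FALSE]
    # non-crossing: for pairs sorted by i, any pair opening inside another
    # must also close inside it
    if (nrow(pairs) > 1L) {
      for (k in seq_len(nrow(pairs) - 1L)) {
        inside <- pairs[, 1] > pairs[k, 1] & pairs[, 1] < pairs[k, 2]
        if (any(pairs[inside, 2] > pairs[k, 2])) stop("crossing pairs (pseudoknot)")
      }
    }
  }
  structure(list(pairs = pairs, length = length),
            class = "secondary_structure")
}

#' Partner lookup vector for a structure
#'
#' @param ss a `secondary_structure`.
#' @return integer vector of length `ss$length`; `partner[i + 1]` is the
#'   0-based partner of position `i`, or `NA` if unpaired.
#' @export
partner_vector <- function(ss) {
  p <- rep(NA_integer_, ss$length)
  if (nrow(ss$pairs)) {
    p[ss$pairs[, 1] + 1L] <- ss$pairs[, 2]
    p[ss$pairs[, 2] + 1L] <- ss$pairs[, 1]
  }
  p
}

#' Parse a dot-bracket string
#'
#' @param text string over `.`, `(`, `)` (the WUSS angle brackets `<`/`>`
#'   are accepted as synonyms).
#' @return a `secondary_structure`.
#' @export
parse_dotbracket <- function(text) {
  text <- chartr("<>", "()", text)
  chars <- strsplit(text, "")[[1]]
  if (!all(chars %in% c(".", "(", ")"))) {
    stop("dot-bracket text may contain only '.', '(' and ')'")
  }
  open <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      open <- c(open, i - 1L)
    } else if (chars[i] == ")") {
      if (!length(open)) {
        stop("unbalanced dot-bracket: unmatched ')' at index ", i - 1L)
      }
      pairs <- rbind(pairs, c(open[length(open)], i - 1L))
      open <- open[-length(open)]
    }
  }
  if (length(open)) {
    stop("unbalanced dot-bracket: unclosed '(' at index ", open[1])
  }
  secondary_structure(pairs, length(chars))
}

#' Render a structure as dot-bracket text
#'
#' Inverse of [parse_dotbracket()]: `render_dotbracket(parse_dotbracket(x))`
#' is the identity on valid input.
#'
#' @param ss a `secondary_structure`.
#' @return dot-bracket string.
#' @export
render_dotbracket <- function(ss) {
  chars <- rep(".", ss$length)
  if (nrow(ss$pairs)) {
    chars[ss$pairs[, 1] + 1L] <- "("
    chars[ss$pairs[, 2] + 1L] <- ")"
  }
  paste(chars, collapse = "")
}

# canonical pair score used by the folder: GC=3, AU=2, GU=1, else 0
pair_score_matrix <- function() {
  m <- matrix(0L, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                        c("A", "C", "G", "U")))
  m["G", "C"] <- m["C", "G"] <- 3L
  m["A", "U"] <- m["U", "A"] <- 2L
  m["G", "U"] <- m["U", "G"] <- 1L
  m
}

#' Fold an RNA sequence with a deterministic stacking-aware DP
#'
#' Maximizes a stacking-aware score over all non-crossing structures:
#' each canonical pair contributes GC = 3, AU = 2, GU = 1, and every
#' stacked pair (a pair `(i, j)` directly enclosing the pair
#' `(i + 1, j - 1)`) earns a +1 bonus. Ties are broken deterministically:
#' at each decomposition step the 5'-most position is paired whenever an
#' optimal structure allows it, to the smallest admissible partner.
#' External dot-bracket structures (e.g. from a thermodynamic folder) can
#' be supplied everywhere a structure is consumed; this folder exists so
#' that no stage of the pipeline requires an external binary.
#'
#' @param seq RNA string (A/C/G/U).
#' @param min_loop minimum loop size (default 3).
#' @return a `secondary_structure` with attribute `score`.
#' @export
fold_rna <- function(seq, min_loop = 3L) {
  seq <- normalize_rna(seq)
  n <- nchar(seq)
  if (n < min_loop + 2L) stop("sequence too short to fold (need >= min_loop + 2)")
  codes <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "U")) - 1L
  res <- fold_dp_cpp(codes, as.integer(min_loop))
  ss <- secondary_structure(matrix(res$pairs, ncol = 2, byrow = TRUE),
                            n, min_loop = min_loop)
  attr(ss, "score") <- res$score
  ss
}

#' Score an explicit structure under the folder's objective
#'
#' Used by tests to compare [fold_rna()] with exhaustive enumeration; kept
#' exported because it is also the "stability" score surfaced in scan
#' reports.
#'
#' @param seq RNA string.
#' @param ss a `secondary_structure` on `seq`.
#' @return numeric score.
#' @export
score_structure <- function(seq, ss) {
  if (!nrow(ss$pairs)) return(0)
  chars <- strsplit(normalize_rna(seq), "")[[1]]
  psm <- pair_score_matrix()
  ps <- sum(psm[cbind(chars[ss$pairs[, 1] + 1L], chars[ss$pairs[, 2] + 1L])])
  key <- paste(ss$pairs[, 1], ss$pairs[, 2])
  stacked <- sum(paste(ss$pairs[, 1] + 1L, ss$pairs[, 2] - 1L) %in% key)
  ps + stacked
}

#' Construct a hairpin (stem-loop precursor)
#'
#' A hairpin couples an RNA sequence with a secondary structure and the
#' span of the terminal loop of its main stem. If no structure is given
#' the sequence is folded with [fold_rna()]. When the structure contains
#' several hairpin loops (multiloop branches, as in type-5 precursors)
#' the main stem is taken to be the loop enclosed by the most pairs, ties
#' to the 5'-most.
#'
#' @param seq RNA string.
#' @param ss optional `secondary_structure` or dot-bracket string.
#' @param id precursor identifier.
#' @return object of class `hairpin` with elements `id`, `seq`, `ss`,
#'   `loop_span` (0-based half-open interval strictly inside the
#'   loop-closing pair) and `partner` (see [partner_vector()]).
#' @export
hairpin <- function(seq, ss = NULL, id = "hairpin") {
  seq <- normalize_rna(seq)
  if (is.null(ss)) {
    ss <- fold_rna(seq)
  } else if (is.character(ss)) {
    ss <- parse_dotbracket(ss)
  }
  stopifnot(inherits(ss, "secondary_structure"), ss$length == nchar(seq))
  if (!nrow(ss$pairs)) stop("structure has no pairs: not a stem-loop")
  partner <- partner_vector(ss)
  # hairpin loops: pairs with no paired position strictly inside
  closes_loop <- vapply(seq_len(nrow(ss$pairs)), function(k) {
    i <- ss$pairs[k, 1]; j <- ss$pairs[k, 2]
    inside <- which(!is.na(partner)) - 1L
    !any(inside > i & inside < j)
  }, logical(1))
  loops <- ss$pairs[closes_loop, , drop = FALSE]
  depth <- vapply(seq_len(nrow(loops)), function(k) {
    sum(ss$pairs[, 1] <= loops[k, 1] & ss$pairs[, 2] >= loops[k, 2])
  }, integer(1))
  main <- loops[order(-depth, loops[, 1])[1], ]
  structure(list(id = id, seq = seq, ss = ss,
                 loop_span = c(main[1] + 1L, main[2]),
                 partner = partner),
            class = "hairpin")
}

#' @export
print.hairpin <- function(x, ...) {
  cat(sprintf("<hairpin> %s: %d nt, %d pairs, loop [%d,%d)\n",
              x$id, nchar(x$seq), nrow(x$ss$pairs),
              x$loop_span[1], x$loop_span[2]))
  invisible(x)
}

#' Classify an interval relative to the terminal loop
#'
#' @param h a `hairpin`.
#' @param interval 0-based half-open `c(start, end)`.
#' @return one of `"five_prime"`, `"three_prime"`, `"spans_loop"`.
#' @export
arm_of <- function(h, interval) {
  stopifnot(interval[1] >= 0, interval[2] <= nchar(h$seq),
            interval[1] < interval[2])
  if (interval[2] <= h$loop_span[1]) return("five_prime")
  if (interval[1] >= h$loop_span[2]) return("three_prime")
  "spans_loop"
}
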