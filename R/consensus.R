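# Structural-alignment post-processing: gap-column filtering, consensus
# sequence/information content, and covariation-scored consensus pairs.

#' Construct a structural alignment
#'
#' @param rows character matrix (rows x columns) over `A C G U -`, or a
#'   named character vector of equal-length aligned strings.
#' @return character matrix of class `structural_alignment`.
#' @export
structural_alignment <- function(rows) {
  if (is.character(rows) && is.null(dim(rows))) {
    if (length(unique(nchar(rows))) != 1L) stop("rows must have equal length")
    nm <- names(rows)
    rows <- matrix(unlist(strsplit(rows, "")), nrow = length(rows),
                   byrow = TRUE, dimnames = list(nm, NULL))
  }
  stopifnot(is.matrix(rows), nrow(rows) >= 2)
  ok <- rows %in% c("A", "C", "G", "U", "-")
  if (!all(ok)) stop("alignment may contain only A, C, G, U and '-'")
  class(rows) <- c("structural_alignment", class(rows))
  rows
}

as_aln_strings <- function(aln) {
  out <- apply(unclass(aln), 1, paste, collapse = "")
  names(out) <- rownames(aln)
  out
}

#' Consensus-analysis parameters
#'
#' @param max_gap_fraction columns with a gap fraction strictly greater
#'   than this are removed (default 0.75: a column with exactly 75% gaps
#'   is kept).
#' @param consensus_residue_fraction minimum fraction of non-gap entries
#'   for a column consensus residue (default 0.8).
#' @param min_pair_support minimum fraction of gap-free rows forming a
#'   canonical pair for a candidate pair column (default 0.75).
#' @param min_covary_types distinct canonical pair types required to call
#'   a selected pair covarying (default 2).
#' @param stack_bonus score bonus for each stacked pair (a selected pair
#'   directly enclosing another selected pair; default 1). Real helices
#'   are contiguous stacks, so the bonus lets a conserved helix outrank
#'   isolated accidental complementarity between conserved columns.
#' @return list of class `consensus_params`.
#' @export
consensus_params <- function(max_gap_fraction = 0.75,
                             consensus_residue_fraction = 0.8,
                             min_pair_support = 0.75,
                             min_covary_types = 2L,
                             stack_bonus = 1) {
  stopifnot(max_gap_fraction > 0, max_gap_fraction <= 1,
            consensus_residue_fraction > 0, consensus_residue_fraction <= 1,
            min_pair_support > 0, min_pair_support <= 1, stack_bonus >= 0)
  structure(list(max_gap_fraction = max_gap_fraction,
                 consensus_residue_fraction = consensus_residue_fraction,
                 min_pair_support = min_pair_support,
                 min_covary_types = as.integer(min_covary_types),
                 stack_bonus = stack_bonus),
            class = "consensus_params")
}

#' Remove gappy alignment columns
#'
#' Keeps a column iff its gap fraction is at most `max_gap_fraction`
#' (strictly-greater removed).
#'
#' @param aln a `structural_alignment`.
#' @param params a [consensus_params()].
#' @return list with `aln` (filtered alignment) and `column_map`
#'   (0-based original index of each kept column).
#' @export
filter_columns <- function(aln, params = consensus_params()) {
  gf <- colMeans(unclass(aln) == "-")
  keep <- gf <= params$max_gap_fraction
  if (!any(keep)) stop("all columns removed by the gap filter")
  out <- unclass(aln)[, keep, drop = FALSE]
  list(aln = structural_alignment(out), column_map = which(keep) - 1L)
}

#' Per-column consensus residues and information content
#'
#' The consensus residue of a column is its most frequent non-gap residue
#' if that residue's fraction among non-gap entries reaches
#' `consensus_residue_fraction`, else none. Information content is
#' `(2 - H) * (non-gap fraction)` bits, with `H` the Shannon entropy of
#' the non-gap residue distribution; it is 2 exactly for an invariant
#' gap-free column.
#'
#' @param aln a (filtered) `structural_alignment`.
#' @param params a [consensus_params()].
#' @return data.frame with `column` (0-based), `consensus` (residue or
#'   `NA`), `ic` (bits).
#' @export
consensus_sequence <- function(aln, params = consensus_params()) {
  m <- unclass(aln)
  res <- lapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    nz <- col[col != "-"]
    if (!length(nz)) return(data.frame(column = j - 1L,
                                       consensus = NA_character_, ic = 0))
    tab <- table(factor(nz, levels = c("A", "C", "G", "U")))
    p <- tab / length(nz)
    H <- -sum(ifelse(p > 0, p * log2(p), 0))
    ic <- (2 - H) * length(nz) / length(col)
    top <- names(tab)[which.max(tab)]
    cons <- if (max(p) >= params$consensus_residue_fraction) top else
      NA_character_
    data.frame(column = j - 1L, consensus = cons, ic = ic)
  })
  do.call(rbind, res)
}

canonical_pair_types <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Detect consensus base-pair columns with covariation classes
#'
#' For every column pair, the support is the fraction of rows whose two
#' residues form a canonical pair (Watson-Crick or GU wobble), computed
#' over rows without a gap in either column; a column pair is eligible
#' only if at least half the rows are gap-free in both columns. Candidate
#' pairs at support >= `min_pair_support` are assembled into the
#' maximum-total-support non-crossing set by dynamic programming with
#' minimum loop 3, scored by support plus a covariation term (the
#' expected Hamming distance between the doublets of two supporting
#' rows), so compensatory pairs outrank accidental complementarity of
#' conserved columns. A selected pair is `covarying` when at least
#' `min_covary_types` distinct canonical pair types occur among its
#' supporting rows (compensatory substitution evidence), else
#' `consensus`.
#'
#' @param aln a (filtered) `structural_alignment`.
#' @param params a [consensus_params()].
#' @return data.frame with `i`, `j` (0-based columns), `support`,
#'   `covar`, `n_types`, `class` (`"consensus"`/`"covarying"`),
#'   non-crossing.
#' @export
detect_pairs <- function(aln, params = consensus_params()) {
  m <- unclass(aln)
  n <- ncol(m); R <- nrow(m)
  cand <- candidate_pairs(m, params)
  if (!nrow(cand)) {
    return(data.frame(i = integer(0), j = integer(0), support = numeric(0),
                      n_types = integer(0), class = character(0)))
  }
  sel <- max_noncrossing_pairs(cand, n, params$stack_bonus)
  sel$class <- ifelse(sel$n_types >= params$min_covary_types,
                      "covarying", "consensus")
  sel[order(sel$i), , drop = FALSE]
}

candidate_pairs <- function(m, params) {
  n <- ncol(m); R <- nrow(m)
  code <- matrix(match(m, c("A", "C", "G", "U")), nrow = R)  # NA = gap
  canon_tab <- matrix(FALSE, 4, 4)
  canon_tab[cbind(c(1, 4, 3, 2, 3, 4), c(4, 1, 2, 3, 4, 3))] <- TRUE
  out <- list()
  for (i in seq_len(max(0L, n - 4L))) {
    js <- (i + 4L):n                 # min loop 3 => j - i >= 4 (1-based)
    A <- code[, i]
    B <- code[, js, drop = FALSE]
    ok <- !is.na(A) & !is.na(B)
    nok <- colSums(ok)
    Af <- ifelse(is.na(A), 1L, A)
    Bf <- ifelse(is.na(B), 1L, B)
    canon <- matrix(canon_tab[cbind(rep(Af, length(js)), as.vector(Bf))],
                    nrow = R) & ok
    support <- colSums(canon) / pmax(nok, 1L)
    eligible <- nok / R >= 0.5 & support >= params$min_pair_support
    for (k in which(eligible)) {
      j <- js[k]
      pt <- paste0(m[canon[, k], i], m[canon[, k], j])
      f <- table(pt) / length(pt)
      # covariation: expected Hamming distance between the doublets of
      # two random supporting rows (compensatory-substitution evidence;
      # 0 for an invariant pair, approaching 2 for full covariation)
      types <- names(f)
      ham <- outer(types, types, function(a, b) {
        (substr(a, 1, 1) != substr(b, 1, 1)) +
          (substr(a, 2, 2) != substr(b, 2, 2))
      })
      covar <- sum(outer(as.numeric(f), as.numeric(f)) * ham)
      out[[length(out) + 1L]] <- data.frame(
        i = i - 1L, j = j - 1L, support = support[k], covar = covar,
        n_types = length(unique(pt)))
    }
  }
  if (!length(out)) return(data.frame(i = integer(0), j = integer(0),
                                      support = numeric(0),
                                      covar = numeric(0),
                                      n_types = integer(0)))
  do.call(rbind, out)
}

# maximum-total-score non-crossing subset of candidate pairs: interval
# DP over score = support + covariation, with a stacking bonus for a
# selected pair directly enclosing another selected pair (so conserved
# helices outrank isolated accidental complementarity).
# W[i, j]: best score on columns i..j; V[i, j]: best given (i, j) paired.
max_noncrossing_pairs <- function(cand, n, stack_bonus = 1) {
  S <- matrix(-Inf, n, n)
  S[cbind(cand$i + 1L, cand$j + 1L)] <- cand$support + cand$covar
  cand_by_i <- split(cand$j + 1L, factor(cand$i + 1L, levels = seq_len(n)))
  W <- matrix(0, n, n)
  V <- matrix(-Inf, n, n)
  choice <- matrix(0L, n, n)        # W: 0 = i unpaired; k>0 = pair (i, k)
  vstack <- matrix(FALSE, n, n)     # V: TRUE = inner pair stacked
  at <- function(M, i, j, empty) if (i > j || i < 1 || j > n) empty else M[i, j]
  for (len in 2:n) {
    for (i in seq_len(n - len + 1L)) {
      j <- i + len - 1L
      if (is.finite(S[i, j])) {
        inner_w <- at(W, i + 1L, j - 1L, 0)
        inner_v <- at(V, i + 1L, j - 1L, -Inf) + stack_bonus
        if (inner_v > inner_w + 1e-12) {
          V[i, j] <- S[i, j] + inner_v
          vstack[i, j] <- TRUE
        } else {
          V[i, j] <- S[i, j] + inner_w
        }
      }
      b <- at(W, i + 1L, j, 0)
      ch <- 0L
      for (k in cand_by_i[[i]]) {
        if (k > j) break
        v <- V[i, k] + at(W, k + 1L, j, 0)
        if (v > b + 1e-12) { b <- v; ch <- k }
      }
      W[i, j] <- b
      choice[i, j] <- ch
    }
  }
  pairs <- list()
  trace_v <- function(i, k) {
    pairs[[length(pairs) + 1L]] <<- c(i, k)
    if (vstack[i, k]) trace_v(i + 1L, k - 1L)
    else if (i + 1L <= k - 1L) trace_w(i + 1L, k - 1L)
  }
  trace_w <- function(i, j) {
    while (i < j) {
      k <- choice[i, j]
      if (k == 0L) { i <- i + 1L; next }
      trace_v(i, k)
      i <- k + 1L
    }
  }
  trace_w(1L, n)
  if (!length(pairs)) {
    return(data.frame(i = integer(0), j = integer(0), support = numeric(0),
                      covar = numeric(0), n_types = integer(0)))
  }
  pm <- do.call(rbind, pairs)
  sel <- merge(data.frame(i = pm[, 1] - 1L, j = pm[, 2] - 1L), cand,
               by = c("i", "j"))
  sel
}

#' Full consensus analysis of a structural alignment
#'
#' Gap-column filtering, per-column consensus/information content, and
#' consensus pair detection, reported in original column coordinates.
#'
#' @param aln a `structural_alignment`.
#' @param params a [consensus_params()].
#' @return list of class `consensus_result`: `column_map`, `columns`
#'   (consensus/IC table, original 0-based coordinates), `pairs` (with
#'   original coordinates), `ss_cons` (dot-bracket over the *filtered*
#'   columns), `aln` (the filtered alignment).
#' @export
consensus_analysis <- function(aln, params = consensus_params()) {
  flt <- filter_columns(aln, params)
  cols <- consensus_sequence(flt$aln, params)
  prs <- detect_pairs(flt$aln, params)
  ss <- rep(".", ncol(flt$aln))
  if (nrow(prs)) {
    ss[prs$i + 1L] <- "("
    ss[prs$j + 1L] <- ")"
  }
  cols$column <- flt$column_map[cols$column + 1L]
  prs_orig <- prs
  if (nrow(prs)) {
    prs_orig$i <- flt$column_map[prs$i + 1L]
    prs_orig$j <- flt$column_map[prs$j + 1L]
  }
  structure(list(column_map = flt$column_map, columns = cols,
                 pairs = prs_orig, pairs_filtered = prs,
                 ss_cons = paste(ss, collapse = ""), aln = flt$aln),
            class = "consensus_result")
}
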