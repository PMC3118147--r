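# Felsenstein pruning likelihood over a partitioned alignment.

# integer tip-state codes for the pruning engine
# 4-state: A=0 C=1 G=2 U=3, gap/missing=4
# 16-state: 4*x + y; 16+x first base known only; 20+y second known only;
# 24 both missing
encode_states <- function(aln, partition) {
  m <- unclass(aln)
  code1 <- matrix(match(m, c("A", "C", "G", "U")) - 1L, nrow = nrow(m))
  code1[is.na(code1)] <- 4L
  up <- partition$unpaired
  s4 <- code1[, up + 1L, drop = FALSE]
  if (nrow(partition$pairs)) {
    i <- partition$pairs[, 1] + 1L
    j <- partition$pairs[, 2] + 1L
    a <- code1[, i, drop = FALSE]
    b <- code1[, j, drop = FALSE]
    s16 <- 4L * a + b
    s16[a == 4L & b == 4L] <- 24L
    s16[a == 4L & b < 4L] <- 20L + b[a == 4L & b < 4L]
    s16[a < 4L & b == 4L] <- 16L + a[a < 4L & b == 4L]
  } else {
    s16 <- matrix(integer(0), nrow = nrow(m), ncol = 0)
  }
  list(s4 = s4, s16 = s16)
}

# collapse identical site columns into patterns with weights
compress_patterns <- function(states) {
  if (ncol(states) == 0) {
    return(list(pat = states, w = numeric(0)))
  }
  key <- apply(states, 2, paste, collapse = ",")
  tab <- table(key)
  first <- match(names(tab), key)
  list(pat = states[, first, drop = FALSE], w = as.numeric(tab))
}

# ape phylo -> parent/branch-length arrays rooted at ape's root node;
# node i (0-based) = ape node i+1, tips first
phylo_to_arrays <- function(tree) {
  n <- length(tree$tip.label)
  N <- n + tree$Nnode
  parent <- rep(-1L, N)
  bl <- rep(0, N)
  parent[tree$edge[, 2]] <- tree$edge[, 1] - 1L
  if (!is.null(tree$edge.length)) bl[tree$edge[, 2]] <- tree$edge.length
  list(parent = parent, bl = bl, ntip = n)
}

#' Partitioned pruning log-likelihood
#'
#' Felsenstein pruning per unpaired column (4-state GTR) and per doublet
#' column pair (16-state doublet model), each averaged over the discrete
#' gamma categories; gaps are missing data. Deterministic for fixed
#' inputs; numerically rescaled to avoid underflow on large trees.
#'
#' @param aln a `structural_alignment` (rows named by taxa).
#' @param partition a [site_partition()].
#' @param tree an `ape` phylo with branch lengths; tips must be a subset
#'   of the alignment rows (the alignment is subset to the tree's tips).
#' @param model a [subst_model()].
#' @return log-likelihood (natural log).
#' @export
phylo_loglik <- function(aln, partition, tree, model) {
  m <- unclass(aln)
  if (!all(tree$tip.label %in% rownames(m))) {
    stop("tree tip(s) absent from the alignment: ",
         paste(setdiff(tree$tip.label, rownames(m)), collapse = ", "))
  }
  m <- m[tree$tip.label, , drop = FALSE]
  st <- encode_states(structural_alignment(m), partition)
  p4 <- compress_patterns(st$s4)
  p16 <- compress_patterns(st$s16)
  arr <- phylo_to_arrays(tree)
  loglik_cpp(arr$parent, arr$bl, arr$ntip,
             p4$pat, p4$w, p16$pat, p16$w,
             model$exch / sum(model$exch), model$base_freqs,
             model$doublet_freqs, model$alpha, model$ncat)
}
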