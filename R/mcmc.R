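# Bayesian sampling of trees under the partitioned GTR + doublet model,
# majority-rule consensus, and duplicate-taxon handling.

#' MCMC configuration
#'
#' Desk-scale defaults: 100,000 generations, 2 independent runs, samples
#' every 100 generations, 25% burn-in.
#'
#' @param n_generations generations per run.
#' @param sample_interval record a sample every this many generations.
#' @param n_runs number of independent runs.
#' @param burn_in fraction of samples discarded from the start of each
#'   run, in `[0, 1)`.
#' @param seed integer seed; run `r` uses `seed + r - 1`.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_generations = 100000L, sample_interval = 100L,
                        n_runs = 2L, burn_in = 0.25, seed = 1L) {
  stopifnot(n_generations > 0, sample_interval > 0, n_runs > 0,
            burn_in >= 0, burn_in < 1)
  structure(list(n_generations = as.integer(n_generations),
                 sample_interval = as.integer(sample_interval),
                 n_runs = as.integer(n_runs), burn_in = burn_in,
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Metropolis-Hastings MCMC over trees and model parameters
#'
#' Moves: branch-length multipliers, nearest-neighbour interchange on
#' internal edges, a gamma-shape multiplier and Dirichlet proposals for
#' the stationary frequencies and shared exchangeabilities. Priors:
#' exponential(10) branch lengths, exponential(1) gamma shape, flat
#' Dirichlet on simplex parameters, uniform topology. Runs are
#' independently seeded; the average standard deviation of split
#' frequencies (ASDSF) between runs is reported as the convergence
#' diagnostic.
#'
#' @param aln a `structural_alignment`.
#' @param partition a [site_partition()].
#' @param model a [subst_model()] giving the starting parameter values;
#'   by default the empirical model of the data
#'   ([empirical_subst_model()]).
#' @param config an [mcmc_config()].
#' @param estimate character subset of
#'   `c("alpha", "base_freqs", "doublet_freqs", "exch")` to sample;
#'   others stay fixed at the starting values.
#' @param prior_only sample the prior (data ignored); used to validate
#'   the sampler against the uniform topology prior.
#' @return list of class `mcmc_result`: per-run samples (`trees` as
#'   `multiPhylo`, `loglik`, `alpha`, acceptance counts), `pooled`
#'   post-burn-in trees across runs, and `asdsf`.
#' @export
mcmc_run <- function(aln, partition, model = NULL,
                     config = mcmc_config(),
                     estimate = c("alpha", "base_freqs", "doublet_freqs",
                                  "exch"),
                     prior_only = FALSE) {
  m <- unclass(aln)
  ntip <- nrow(m)
  if (ntip < 4) stop("MCMC needs at least 4 taxa")
  if (is.null(model)) model <- empirical_subst_model(aln, partition)
  taxa <- rownames(m)
  st <- encode_states(aln, partition)
  p4 <- compress_patterns(st$s4)
  p16 <- compress_patterns(st$s16)
  est <- c("alpha", "base_freqs", "doublet_freqs", "exch") %in% estimate
  runs <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    set.seed(config$seed + r - 1L)
    start <- ape::rtree(ntip, rooted = FALSE, tip.label = sample(taxa),
                        br = function(k) stats::rexp(k, 10))
    arr <- phylo_to_arrays(start)
    # reorder tip rows to ape tip numbering
    ord <- match(start$tip.label, taxa)
    res <- mcmc_cpp(arr$parent, arr$bl, arr$ntip, start$tip.label,
                    p4$pat[ord, , drop = FALSE], p4$w,
                    p16$pat[ord, , drop = FALSE], p16$w,
                    model$exch / sum(model$exch), model$base_freqs,
                    model$doublet_freqs, model$alpha, model$ncat,
                    config$n_generations, config$sample_interval,
                    !prior_only, est)
    trees <- ape::read.tree(text = paste(res$trees, collapse = "\n"))
    if (inherits(trees, "phylo")) trees <- c(trees)
    runs[[r]] <- list(trees = trees, loglik = res$loglik,
                      alpha = res$alpha,
                      acceptance = res$accepted / pmax(res$tried, 1),
                      moves_tried = res$tried)
  }
  nsamp <- length(runs[[1]]$trees)
  keep <- seq.int(floor(config$burn_in * nsamp) + 1L, nsamp)
  pooled <- do.call(c, lapply(runs, function(r) r$trees[keep]))
  structure(list(runs = runs, pooled = pooled, keep = keep,
                 asdsf = asdsf(lapply(runs, function(r) r$trees[keep])),
                 config = config),
            class = "mcmc_result")
}

# canonical split keys of an unrooted tree: for every internal edge, the
# tip-label set on the side not containing the reference (alphabetically
# first) taxon
tree_splits <- function(tree, taxa = NULL) {
  taxa <- sort(taxa %||% tree$tip.label)
  ref <- taxa[1]
  n <- length(tree$tip.label)
  out <- character(0)
  desc <- descendant_tips(tree)
  for (node in (n + 1L):(n + tree$Nnode)) {
    tips <- tree$tip.label[desc[[node]]]
    side <- if (ref %in% tips) setdiff(taxa, tips) else tips
    if (length(side) >= 2 && length(side) <= length(taxa) - 2) {
      out <- c(out, paste(sort(side), collapse = "|"))
    }
  }
  unique(out)
}

# tip indices below each node (ape numbering)
descendant_tips <- function(tree) {
  n <- length(tree$tip.label)
  N <- n + tree$Nnode
  desc <- vector("list", N)
  for (i in seq_len(n)) desc[[i]] <- i
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edges))) {
    p <- edges[k, 1]; ch <- edges[k, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

# average standard deviation of split frequencies across runs
asdsf <- function(tree_sets, min_freq = 0.1) {
  if (length(tree_sets) < 2) return(NA_real_)
  taxa <- sort(tree_sets[[1]][[1]]$tip.label)
  freqs <- lapply(tree_sets, function(ts) {
    sp <- unlist(lapply(ts, tree_splits, taxa = taxa))
    table(sp) / length(ts)
  })
  all_splits <- unique(unlist(lapply(freqs, names)))
  fmat <- vapply(freqs, function(f) {
    v <- as.numeric(f[all_splits]); v[is.na(v)] <- 0; v
  }, numeric(length(all_splits)))
  if (is.null(dim(fmat))) fmat <- matrix(fmat, nrow = 1)
  keep <- apply(fmat, 1, max) >= min_freq
  if (!any(keep)) return(0)
  mean(apply(fmat[keep, , drop = FALSE], 1, stats::sd))
}

#' Majority-rule consensus tree with split posteriors
#'
#' Includes exactly the non-trivial splits present in more than
#' `threshold` of the samples (all such splits are mutually compatible
#' for thresholds of at least 0.5) and annotates each retained split
#' with its sample frequency as a percentage node label.
#'
#' @param trees `multiPhylo` (or list) of sampled trees over one taxon
#'   set.
#' @param threshold split-frequency threshold (default 0.5, strict).
#' @return an unrooted `phylo`; `node.label` carries the split
#'   posteriors (percent, root label empty).
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  stopifnot(length(trees) >= 1)
  taxa <- sort(trees[[1]]$tip.label)
  sp <- unlist(lapply(trees, tree_splits, taxa = taxa))
  freq <- table(sp) / length(trees)
  keep <- freq[freq > threshold]
  clades <- lapply(names(keep), function(k) strsplit(k, "|", fixed = TRUE)[[1]])
  pp <- round(100 * as.numeric(keep), 1)
  # splits are stored as the side away from the reference taxon, so they
  # nest as clades of a tree rooted at the reference taxon
  ord <- order(-lengths(clades))
  clades <- clades[ord]; pp <- pp[ord]
  build <- function(tipset, avail) {
    kids <- list()
    used <- character(0)
    for (i in avail) {
      cl <- clades[[i]]
      if (all(cl %in% tipset) && length(cl) < length(tipset) &&
          !any(cl %in% used)) {
        sub_avail <- avail[vapply(avail, function(j) {
          j != i && all(clades[[j]] %in% cl)
        }, logical(1))]
        kids[[length(kids) + 1L]] <- paste0(build(cl, sub_avail), pp[i])
        used <- c(used, cl)
      }
    }
    singles <- setdiff(tipset, used)
    sprintf("(%s)", paste(c(unlist(kids), singles), collapse = ","))
  }
  ref <- taxa[1]
  rest <- setdiff(taxa, ref)
  txt <- sprintf("(%s,%s);", ref, build(rest, seq_along(clades)))
  tree <- ape::read.tree(text = txt)
  ape::unroot(tree)
}

#' Collapse identical alignment rows before inference
#'
#' Only one representative of each set of identical rows is retained for
#' tree inference; [reinsert_taxa()] restores the redundant taxa
#' afterwards.
#'
#' @param aln a `structural_alignment`.
#' @return list with `aln` (reduced) and `map`: named list, one entry
#'   per representative with duplicates, giving all original row names
#'   (representative first).
#' @export
dedup_rows <- function(aln) {
  m <- unclass(aln)
  key <- apply(m, 1, paste, collapse = "")
  first <- !duplicated(key)
  map <- lapply(split(rownames(m), key), identity)
  map <- map[vapply(map, length, integer(1)) > 1]
  # keep original order inside each group, representative first
  map <- lapply(map, function(g) rownames(m)[rownames(m) %in% g])
  names(map) <- vapply(map, `[`, character(1), 1)
  red <- m[first, , drop = FALSE]
  if (nrow(red) < 2) stop("fewer than 2 distinct rows after deduplication")
  list(aln = structural_alignment(red), map = map)
}

#' Reinsert redundant taxa into an inferred tree
#'
#' Each representative tip with duplicates is replaced by a node carrying
#' all original taxa as tips, with posterior probability set to 100 and
#' branch lengths set to 0.001 exactly.
#'
#' @param tree a `phylo` whose tips are the deduplicated representatives.
#' @param map the `map` from [dedup_rows()].
#' @return a `phylo` over the full taxon set.
#' @export
reinsert_taxa <- function(tree, map) {
  txt <- ape::write.tree(tree)
  for (rep_id in names(map)) {
    members <- map[[rep_id]]
    clade <- sprintf("(%s)100",
                     paste(sprintf("%s:0.001", members), collapse = ","))
    # tip labels in newick are delimited by '(' or ',' before and by
    # ':', ',' or ')' after
    txt <- sub(sprintf("(?<=[(,])%s(?=[:,)])", rep_id), clade, txt,
               perl = TRUE)
  }
  ape::read.tree(text = txt)
}
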