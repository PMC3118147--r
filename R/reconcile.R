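# Gene-tree / species-tree LCA reconciliation: duplication and loss
# inference.

#' LCA reconciliation of a rooted gene tree against a rooted species tree
#'
#' Each gene-tree node is mapped to the last common ancestor (in the
#' species tree) of the species of its descendant genes. An internal
#' gene node is a duplication iff it maps to the same species node as at
#' least one of its children (a duplication increases the number of
#' paralogs within one clade); losses are counted along the compressed
#' species-tree paths between a node's mapping and its children's
#' mappings (the absence of an ancestral gene in a descendant clade).
#' For the LCA map these counts are the parsimony minimum.
#'
#' Rooting is the caller's responsibility (e.g. by an outgroup such as
#' the moss clade); no automatic rooting is attempted.
#'
#' @param gene_tree rooted `phylo`.
#' @param species_tree rooted `phylo`.
#' @param tip_map named character vector: gene tip label -> species tip
#'   label.
#' @return list of class `reconciliation`: `mapping` (gene node ->
#'   species node, ape numbering), `duplications` (gene internal node
#'   ids), `n_dup`, `n_loss`, `losses` (data.frame: gene edge and the
#'   species node where each loss is placed).
#' @export
reconcile <- function(gene_tree, species_tree, tip_map) {
  gt <- gene_tree; st <- species_tree
  if (!ape::is.rooted(gt) || !ape::is.rooted(st)) {
    stop("gene and species trees must be rooted")
  }
  unmapped <- setdiff(gt$tip.label, names(tip_map))
  if (length(unmapped)) {
    stop("unmapped gene tip(s): ", paste(unmapped, collapse = ", "))
  }
  if (!all(tip_map[gt$tip.label] %in% st$tip.label)) {
    stop("tip_map points to unknown species tip(s)")
  }
  ng <- length(gt$tip.label)
  Ns <- length(st$tip.label) + st$Nnode
  sanc <- species_ancestry(st)

  # LCA map, computed bottom-up over the gene tree
  desc <- descendant_tips(gt)
  mapping <- integer(ng + gt$Nnode)
  for (v in seq_len(ng + gt$Nnode)) {
    sp <- unique(tip_map[gt$tip.label[desc[[v]]]])
    mapping[v] <- species_mrca(st, sp, sanc)
  }

  children <- split(gt$edge[, 2], gt$edge[, 1])
  dup <- integer(0)
  losses <- list()
  for (v in (ng + 1L):(ng + gt$Nnode)) {
    kids <- children[[as.character(v)]]
    is_dup <- any(mapping[kids] == mapping[v])
    if (is_dup) dup <- c(dup, v)
    for (ch in kids) {
      path <- species_path(mapping[v], mapping[ch], sanc)  # excl. endpoints
      lost_at <- if (is_dup && mapping[ch] != mapping[v]) {
        # the duplicate descends from mapping[v]: one loss in the sister
        # branch(es) at the starting node, then one per intermediate node
        c(mapping[v], path)
      } else {
        path
      }
      if (length(lost_at)) {
        losses[[length(losses) + 1L]] <- data.frame(
          gene_node = v, gene_child = ch, species_node = lost_at)
      }
    }
  }
  loss_tab <- if (length(losses)) do.call(rbind, losses) else
    data.frame(gene_node = integer(0), gene_child = integer(0),
               species_node = integer(0))
  structure(list(mapping = mapping, duplications = dup,
                 n_dup = length(dup), n_loss = nrow(loss_tab),
                 losses = loss_tab),
            class = "reconciliation")
}

# ancestor list (self first, then towards the root) per species node
species_ancestry <- function(st) {
  N <- length(st$tip.label) + st$Nnode
  parent <- rep(NA_integer_, N)
  parent[st$edge[, 2]] <- st$edge[, 1]
  lapply(seq_len(N), function(v) {
    out <- v
    while (!is.na(parent[v])) {
      v <- parent[v]
      out <- c(out, v)
    }
    out
  })
}

# MRCA of a set of species tip labels (1 label -> the tip itself)
species_mrca <- function(st, labels, sanc) {
  ids <- match(labels, st$tip.label)
  common <- Reduce(intersect, sanc[ids])
  common[1]  # ancestor lists are ordered leaf-to-root
}

# species nodes strictly between an ancestor `a` and a descendant `d`
species_path <- function(a, d, sanc) {
  path <- sanc[[d]]
  stopifnot(a %in% path)
  path[seq_len(which(path == a) - 1L)][-1]
}

#' @export
print.reconciliation <- function(x, ...) {
  cat(sprintf("<reconciliation> %d duplication(s), %d loss(es)\n",
              x$n_dup, x$n_loss))
  invisible(x)
}
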