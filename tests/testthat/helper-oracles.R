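# Independent brute-force oracles. Everything here is deliberately
# written from scratch (no calls into the package's computational
# paths) so tests compare two independent routes.

# -- folding ----------------------------------------------------------

# enumerate every non-crossing structure (list of 0-based pair matrices)
oracle_all_structures <- function(n, can_pair, min_loop = 3L) {
  # can_pair: n x n logical
  memo <- new.env()
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(list(matrix(integer(0), ncol = 2)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- rec(i + 1L, j)  # i unpaired
    for (k in (i + min_loop + 1L):j) {
      if (!can_pair[i + 1L, k + 1L]) next
      inner <- rec(i + 1L, k - 1L)
      rest <- if (k + 1L <= j) rec(k + 1L, j) else
        list(matrix(integer(0), ncol = 2))
      for (a in inner) for (b in rest) {
        out[[length(out) + 1L]] <- rbind(c(i, k), a, b)
      }
    }
    memo[[key]] <- out
    out
  }
  rec(0L, n - 1L)
}

# independent scorer: pair scores GC 3, AU 2, GU 1, +1 per stack
oracle_score <- function(chars, pm) {
  if (!nrow(pm)) return(0L)
  sc <- 0L
  for (r in seq_len(nrow(pm))) {
    b <- paste0(chars[pm[r, 1] + 1L], chars[pm[r, 2] + 1L])
    sc <- sc + switch(b, GC = 3L, CG = 3L, AU = 2L, UA = 2L,
                      GU = 1L, UG = 1L, 0L)
  }
  key <- paste(pm[, 1], pm[, 2])
  sc + sum(paste(pm[, 1] + 1L, pm[, 2] - 1L) %in% key)
}

oracle_best_fold_score <- function(seq, min_loop = 3L) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  ok <- c("GC", "CG", "AU", "UA", "GU", "UG")
  can <- outer(chars, chars, function(a, b) paste0(a, b) %in% ok)
  structs <- oracle_all_structures(n, can, min_loop)
  max(vapply(structs, function(pm) oracle_score(chars, pm), integer(1)))
}

# -- window matching --------------------------------------------------

# all qualifying windows by full enumeration with utils::adist
oracle_window_hits <- function(target, query, max_edits) {
  tgt <- chartr("N", "?", target)
  m <- nchar(query); n <- nchar(tgt)
  out <- list()
  for (L in max(1L, m - max_edits):(m + max_edits)) {
    if (L > n) next
    for (s in 0:(n - L)) {
      d <- utils::adist(substr(tgt, s + 1L, s + L), query)[1, 1]
      if (d <= max_edits) out[[length(out) + 1L]] <- c(s, s + L, d)
    }
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0),
                                      edit_distance = integer(0)))
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2], edit_distance = m[, 3])
}

# cluster overlapping windows, pick best (min distance, leftmost start,
# shortest) — same tie rules, independent code
oracle_merge_windows <- function(wins) {
  if (!nrow(wins)) return(wins)
  wins <- wins[order(wins$start, wins$end), , drop = FALSE]
  reps <- list()
  cur <- wins[1, , drop = FALSE]
  hi <- cur$end[1]
  flush <- function(group) {
    group[order(group$edit_distance, group$start,
                group$end - group$start)[1], , drop = FALSE]
  }
  group <- cur
  for (i in seq_len(nrow(wins))[-1]) {
    if (wins$start[i] < hi) {
      group <- rbind(group, wins[i, , drop = FALSE])
    } else {
      reps[[length(reps) + 1L]] <- flush(group)
      group <- wins[i, , drop = FALSE]
    }
    hi <- max(hi, wins$end[i])
  }
  reps[[length(reps) + 1L]] <- flush(group)
  out <- do.call(rbind, reps)
  rownames(out) <- NULL
  out
}

# -- miRcheck ---------------------------------------------------------

# independent rule evaluation from the raw pair table; same rule
# definitions, straight-line code
oracle_mircheck <- function(h, mir, params = list(max_unpaired = 6,
                                                 max_bulges = 3,
                                                 max_len_diff = 3,
                                                 max_asym = 3,
                                                 max_contig = 3,
                                                 min_dist = 5,
                                                 max_dist = 300)) {
  pm <- h$ss$pairs
  partner <- rep(NA_integer_, nchar(h$seq))
  for (r in seq_len(nrow(pm))) {
    partner[pm[r, 1] + 1L] <- pm[r, 2]
    partner[pm[r, 2] + 1L] <- pm[r, 1]
  }
  loop <- h$loop_span
  pos <- mir[1]:(mir[2] - 1L)            # 0-based miR positions
  up <- is.na(partner[pos + 1L])
  res <- list()
  res$rule2 <- sum(up) <= params$max_unpaired
  runs <- integer(0)
  i <- 1L
  while (i <= length(up)) {
    if (up[i]) {
      j <- i
      while (j < length(up) && up[j + 1L]) j <- j + 1L
      runs <- c(runs, j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  res$rule3 <- length(runs) <= params$max_bulges
  res$rule6 <- (if (length(runs)) max(runs) else 0L) <= params$max_contig

  # star location, rederived: partners of paired miR positions except
  # the miR 3'-terminal two, extended 2 nt at the high end
  mir_paired <- pos[!up]
  if (!length(mir_paired)) {
    res$rule1 <- res$rule4 <- res$rule5 <- res$rule7 <- FALSE
    res$star <- NULL
    res$overall <- FALSE
    return(res)
  }
  core_pos <- setdiff(pos[seq_len(max(0L, length(pos) - 2L))], pos[up])
  prt <- partner[core_pos + 1L]
  prt <- prt[!is.na(prt)]
  if (!length(prt)) prt <- partner[mir_paired + 1L]
  star <- c(min(prt), min(max(prt) + 3L, nchar(h$seq)))
  star_core <- c(min(prt), max(prt) + 1L)
  res$star <- star
  side <- function(iv) {
    if (iv[2] <= loop[1]) "5p" else if (iv[1] >= loop[2]) "3p" else "loop"
  }
  mir_in_loop <- side(mir) == "loop"
  res$rule1 <- !mir_in_loop && side(star_core) != "loop" &&
    side(mir) != side(star_core)
  if (mir_in_loop) {
    res$rule1 <- FALSE
    res$rule4 <- res$rule5 <- res$rule7 <- FALSE
    res$overall <- FALSE
    return(res)
  }
  res$rule4 <- abs((mir[2] - mir[1]) - (star[2] - star[1])) <=
    params$max_len_diff
  # asymmetric unpaired: per interior run, surplus over the star-side gap
  asym <- 0L
  i <- 1L
  while (i <= length(up)) {
    if (up[i]) {
      j <- i
      while (j < length(up) && up[j + 1L]) j <- j + 1L
      if (i > 1L && j < length(up)) {
        qL <- partner[pos[i - 1L] + 1L]
        qR <- partner[pos[j + 1L] + 1L]
        gap <- abs(qL - qR) - 1L
        asym <- asym + max(0L, (j - i + 1L) - gap)
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  res$rule5 <- asym <= params$max_asym
  D <- if (mir[1] >= star[2]) mir[1] - star[2] else star[1] - mir[2]
  res$rule7 <- D >= params$min_dist && D <= params$max_dist
  res$overall <- res$rule1 && res$rule2 && res$rule3 && res$rule4 &&
    res$rule5 && res$rule6 && res$rule7
  res
}

# -- likelihood -------------------------------------------------------

# brute-force likelihood: sum over all internal-node state assignments,
# transition probabilities via the R spectral route
oracle_loglik <- function(aln_states, tree, Q, freqs, alpha, ncat,
                          weights = NULL) {
  # aln_states: ntip x nsite integer matrix, 1-based states or NA
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  S <- nrow(Q)
  rates <- phasemir::discrete_gamma(alpha, ncat)
  nnode <- tr$Nnode
  internal <- (ntip + 1L):(ntip + nnode)
  parent_of <- rep(NA_integer_, ntip + nnode)
  parent_of[tr$edge[, 2]] <- tr$edge[, 1]
  elen <- rep(NA_real_, ntip + nnode)
  elen[tr$edge[, 2]] <- tr$edge.length
  root <- internal[is.na(parent_of[internal])]
  nsite <- ncol(aln_states)
  if (is.null(weights)) weights <- rep(1, nsite)
  Pcat <- lapply(seq_len(ncat), function(c) {
    lapply(seq_len(ntip + nnode), function(v) {
      if (is.na(elen[v])) NULL else
        phasemir::transition_prob(Q, freqs, elen[v] * rates[c])
    })
  })
  grid <- as.matrix(do.call(expand.grid, rep(list(seq_len(S)), nnode)))
  ll <- 0
  for (site in seq_len(nsite)) {
    site_lik <- 0
    for (c in seq_len(ncat)) {
      P <- Pcat[[c]]
      state_of <- function(v, grid_col) {
        if (v <= ntip) rep(aln_states[v, site], nrow(grid)) else
          grid[, v - ntip]
      }
      pr <- freqs[grid[, root - ntip]]
      for (e in seq_len(nrow(tr$edge))) {
        a <- tr$edge[e, 1]; b <- tr$edge[e, 2]
        sa <- state_of(a)
        sb <- state_of(b)
        if (b <= ntip && is.na(aln_states[b, site])) next  # missing tip
        pr <- pr * P[[b]][cbind(sa, sb)]
      }
      site_lik <- site_lik + sum(pr) / ncat
    }
    ll <- ll + weights[site] * log(site_lik)
  }
  ll
}

# -- splits / consensus ----------------------------------------------

oracle_split_freqs <- function(trees) {
  taxa <- sort(trees[[1]]$tip.label)
  key_of <- function(tree) {
    unlist(lapply(seq_len(tree$Nnode) + length(tree$tip.label), function(nd) {
      tips <- tree$tip.label[unlist(phangorn_free_desc(tree, nd))]
      side <- if (taxa[1] %in% tips) setdiff(taxa, tips) else tips
      if (length(side) < 2 || length(side) > length(taxa) - 2) return(NULL)
      paste(sort(side), collapse = "|")
    }))
  }
  tab <- table(unlist(lapply(trees, function(t) unique(key_of(t)))))
  tab / length(trees)
}

# descendant tips without using the package helper
phangorn_free_desc <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, phangorn_free_desc, tree = tree))
}

# best non-crossing candidate-pair subset by total score (support +
# covariation + stacking bonus per directly nested pair). Complete
# top-down search with memoization, decomposing on the LAST column (the
# implementation's DP decomposes on the first); cross-checked against
# the bitmask enumeration below on small instances.
oracle_best_pairset <- function(cand, n, stack_bonus = 1) {
  if (!nrow(cand)) return(0)
  sc <- cand$support + cand$covar
  by_j <- split(seq_len(nrow(cand)), factor(cand$j, levels = 0:(n - 1)))
  memoW <- new.env(); memoV <- new.env()
  V <- function(i, j) {  # best of columns i..j given candidate pair (i, j)
    key <- paste(i, j)
    if (!is.null(memoV[[key]])) return(memoV[[key]])
    idx <- which(cand$i == i & cand$j == j)
    inner <- if (i + 1 <= j - 1) {
      best <- W(i + 1, j - 1)
      if (any(cand$i == i + 1 & cand$j == j - 1)) {
        best <- max(best, V(i + 1, j - 1) + stack_bonus)
      }
      best
    } else 0
    memoV[[key]] <- sc[idx] + inner
    memoV[[key]]
  }
  W <- function(i, j) {
    if (i > j) return(0)
    key <- paste(i, j)
    if (!is.null(memoW[[key]])) return(memoW[[key]])
    best <- W(i, j - 1)                    # j unpaired
    for (idx in by_j[[as.character(j)]]) { # or some k pairs j
      k <- cand$i[idx]
      if (k < i) next
      best <- max(best, V(k, j) + W(i, k - 1))
    }
    memoW[[key]] <- best
    best
  }
  W(0, n - 1)
}

# plain bitmask enumeration over every subset (small instances only)
oracle_best_pairset_mask <- function(cand, n, stack_bonus = 1) {
  best <- 0
  m <- nrow(cand)
  if (m == 0) return(0)
  compatible <- function(sel) {
    if (length(sel) < 2) return(TRUE)
    sub <- cand[sel, , drop = FALSE]
    if (anyDuplicated(c(sub$i, sub$j))) return(FALSE)
    for (a in seq_len(nrow(sub) - 1)) for (b in (a + 1):nrow(sub)) {
      i1 <- sub$i[a]; j1 <- sub$j[a]; i2 <- sub$i[b]; j2 <- sub$j[b]
      if (i1 < i2 && i2 < j1 && j1 < j2) return(FALSE)
      if (i2 < i1 && i1 < j2 && j2 < j1) return(FALSE)
    }
    TRUE
  }
  for (mask in 0:(2^m - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    if (!length(sel)) next
    if (!compatible(sel)) next
    key <- paste(cand$i[sel], cand$j[sel])
    stacks <- sum(paste(cand$i[sel] + 1L, cand$j[sel] - 1L) %in% key)
    sc <- sum(cand$support[sel] + cand$covar[sel]) + stack_bonus * stacks
    if (sc > best) best <- sc
  }
  best
}

# -- reconciliation ---------------------------------------------------

# minimal duplication+loss over all ancestrally consistent maps:
# exhaustive search in dynamic-programming form — for every gene node
# and every admissible species placement the cheapest assignment of the
# subtree is found by trying all child placements
oracle_reconcile_min <- function(gene_tree, species_tree, tip_map) {
  gt <- gene_tree; st <- species_tree
  ngt <- length(gt$tip.label)
  nst <- length(st$tip.label)
  Ns <- nst + st$Nnode
  s_parent <- rep(NA_integer_, Ns)
  s_parent[st$edge[, 2]] <- st$edge[, 1]
  anc <- function(v) {
    out <- v
    while (!is.na(s_parent[v])) { v <- s_parent[v]; out <- c(out, v) }
    out
  }
  anc_list <- lapply(seq_len(Ns), anc)
  is_anc <- function(a, d) a %in% anc_list[[d]]
  sdist <- function(a, d) which(anc_list[[d]] == a) - 1L
  s_kids <- split(st$edge[, 2], st$edge[, 1])
  g_kids <- split(gt$edge[, 2], gt$edge[, 1])

  post <- ape::reorder.phylo(gt, "postorder")
  cost <- matrix(Inf, ngt + gt$Nnode, Ns)   # cost[g, s]: subtree minimum
  # charging convention: cost[g, s] excludes losses on the edge into g,
  # so tips only admit their own species
  for (g in seq_len(ngt)) {
    s <- match(tip_map[gt$tip.label[g]], st$tip.label)
    cost[g, s] <- 0
  }
  internal_postorder <- unique(post$edge[, 1])
  for (g in internal_postorder) {
    kids <- g_kids[[as.character(g)]]
    c1 <- kids[1]; c2 <- kids[2]
    for (s in seq_len(Ns)) {
      best <- Inf
      for (s1 in seq_len(Ns)) {
        if (!is.finite(cost[c1, s1]) || !is_anc(s, s1)) next
        for (s2 in seq_len(Ns)) {
          if (!is.finite(cost[c2, s2]) || !is_anc(s, s2)) next
          # event type at g when children sit at s1, s2
          spec <- FALSE
          if (s1 != s && s2 != s && s > nst) {
            kk <- s_kids[[as.character(s)]]
            sub1 <- kk[vapply(kk, function(x) is_anc(x, s1), logical(1))][1]
            sub2 <- kk[vapply(kk, function(x) is_anc(x, s2), logical(1))][1]
            spec <- !is.na(sub1) && !is.na(sub2) && sub1 != sub2
          }
          ev <- if (spec) 0 else 1
          loss <- (sdist(s, s1) - if (spec) 1 else 0) +
                  (sdist(s, s2) - if (spec) 1 else 0)
          tot <- ev + loss + cost[c1, s1] + cost[c2, s2]
          if (tot < best) best <- tot
        }
      }
      cost[g, s] <- best
    }
  }
  root <- internal_postorder[length(internal_postorder)]
  min(cost[root, ])
}

# naive enumeration over full maps (kept for cross-checking the DP on
# the smallest instances)
oracle_reconcile_enum <- function(gene_tree, species_tree, tip_map) {
  gt <- gene_tree; st <- species_tree
  ngt <- length(gt$tip.label)
  nst <- length(st$tip.label)
  s_parent <- rep(NA_integer_, nst + st$Nnode)
  s_parent[st$edge[, 2]] <- st$edge[, 1]
  anc <- function(v) {
    out <- v
    while (!is.na(s_parent[v])) { v <- s_parent[v]; out <- c(out, v) }
    out
  }
  anc_list <- lapply(seq_len(nst + st$Nnode), anc)
  is_anc <- function(a, d) a %in% anc_list[[d]]   # a ancestor-or-equal of d
  sdist <- function(a, d) which(anc_list[[d]] == a) - 1L
  s_kids <- split(st$edge[, 2], st$edge[, 1])

  g_kids <- split(gt$edge[, 2], gt$edge[, 1])
  # fixed tip mappings
  gmap_tip <- function(g) match(tip_map[gt$tip.label[g]], st$tip.label)
  lca_map <- integer(ngt + gt$Nnode)
  order_nodes <- rev(unique(ape::reorder.phylo(gt, "postorder")$edge[, 1]))
  post <- ape::reorder.phylo(gt, "postorder")
  for (g in seq_len(ngt)) lca_map[g] <- gmap_tip(g)
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1]
    kids <- g_kids[[as.character(p)]]
    common <- Reduce(intersect, anc_list[lca_map[kids]])
    lca_map[p] <- common[1]
  }
  internal <- (ngt + 1L):(ngt + gt$Nnode)
  # candidates: ancestors-or-self of the LCA map
  cands <- lapply(internal, function(g) anc_list[[lca_map[g]]])
  best <- Inf
  count_events <- function(map) {
    dup <- 0L; loss <- 0L
    for (g in internal) {
      kids <- g_kids[[as.character(g)]]
      s <- map[g]
      kid_maps <- map[kids]
      # speciation iff the children map into distinct child subtrees
      spec <- FALSE
      if (all(kid_maps != s)) {
        subtree_of <- vapply(kid_maps, function(k) {
          kk <- s_kids[[as.character(s)]]
          kk[vapply(kk, function(x) is_anc(x, k), logical(1))][1]
        }, numeric(1))
        spec <- length(unique(subtree_of)) == length(subtree_of)
      }
      if (!spec) dup <- dup + 1L
      for (ch in kids) {
        k <- sdist(s, map[ch])
        loss <- loss + if (spec) k - 1L else k
      }
    }
    c(dup, loss)
  }
  rec <- function(idx, map) {
    if (idx > length(internal)) {
      ev <- count_events(map)
      tot <- sum(ev)
      if (tot < best) best <<- tot
      return(invisible())
    }
    g <- internal[idx]
    for (s in cands[[idx]]) {
      # ancestral consistency with already-assigned parent
      par <- post$edge[post$edge[, 2] == g, 1]
      if (length(par) && par > ngt && !is.na(map[par])) {
        if (!is_anc(map[par], s)) next
      }
      map[g] <- s
      # children constraints
      kids <- g_kids[[as.character(g)]]
      ok <- all(vapply(kids, function(ch) {
        if (ch <= ngt || !is.na(map[ch])) is_anc(s, map[ch]) else TRUE
      }, logical(1)))
      if (ok) rec(idx + 1L, map)
      map[g] <- NA_integer_
    }
  }
  map0 <- rep(NA_integer_, ngt + gt$Nnode)
  for (g in seq_len(ngt)) map0[g] <- gmap_tip(g)
  # order internal nodes root-first so parent constraints apply
  internal <- internal[order(match(internal, order_nodes))]
  cands <- lapply(internal, function(g) anc_list[[lca_map[g]]])
  rec(1L, map0)
  best
}

# implementation-side total under the same objective
selected_pairset_score <- function(sel, stack_bonus = 1) {
  if (!nrow(sel)) return(0)
  key <- paste(sel$i, sel$j)
  stacks <- sum(paste(sel$i + 1L, sel$j - 1L) %in% key)
  sum(sel$support + sel$covar) + stack_bonus * stacks
}

# encode an alignment's unpaired / doublet columns as 1-based state
# matrices for the brute-force oracle
states_for_oracle <- function(aln, partition, tree) {
  m <- unclass(aln)[tree$tip.label, , drop = FALSE]
  code1 <- matrix(match(m, c("A", "C", "G", "U")), nrow = nrow(m))
  s4 <- code1[, partition$unpaired + 1L, drop = FALSE]
  if (nrow(partition$pairs)) {
    a <- code1[, partition$pairs[, 1] + 1L, drop = FALSE]
    b <- code1[, partition$pairs[, 2] + 1L, drop = FALSE]
    s16 <- 4L * (a - 1L) + b
  } else s16 <- matrix(integer(0), nrow = nrow(m), ncol = 0)
  list(s4 = s4, s16 = s16)
}

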