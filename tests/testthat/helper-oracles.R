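# Shared fixtures and independent oracles.  Oracles are deliberately
# brute-force and never call the code path they check.

nwk <- function(text) ape::read.tree(text = text)

# random rooted tree, optionally with polytomies (collapse random internal
# edges by merging a node into its parent)
random_tree <- function(n, polytomies = FALSE) {
  tr <- ape::rtree(n, rooted = TRUE, br = NULL)
  if (polytomies && n >= 4 && tr$Nnode > 2) {
    k <- sample.int(max(1L, tr$Nnode %/% 3L), 1L)
    for (i in seq_len(k)) {
      ntip <- length(tr$tip.label)
      root <- ntip + 1L
      inner <- setdiff(unique(tr$edge[, 1L]), root)
      cand <- tr$edge[, 2L][tr$edge[, 2L] %in% inner]
      if (!length(cand)) break
      v <- sample(cand, 1L)
      # merge v into its parent
      par <- tr$edge[tr$edge[, 2L] == v, 1L]
      keep <- tr$edge[, 2L] != v
      edges <- tr$edge[keep, , drop = FALSE]
      edges[edges[, 1L] == v, 1L] <- par
      # renumber internal nodes (v vanished)
      shift <- function(x) ifelse(x > v, x - 1L, x)
      edges <- cbind(shift(edges[, 1L]), shift(edges[, 2L]))
      tr <- structure(list(edge = edges, tip.label = tr$tip.label,
                           Nnode = tr$Nnode - 1L), class = "phylo")
    }
  }
  tr
}

clade_sets <- function(tree) {
  n <- length(tree$tip.label)
  sapply((n + 1L):(n + tree$Nnode), function(v) {
    paste(sort(ape::extract.clade(tree, v)$tip.label), collapse = "|")
  })
}

trees_isomorphic <- function(t1, t2) {
  setequal(t1$tip.label, t2$tip.label) &&
    setequal(clade_sets(t1), clade_sets(t2))
}

# MRCA oracle: intersect root-to-leaf paths, take the deepest shared node
oracle_mrca <- function(tree, leaves) {
  n <- length(tree$tip.label)
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  path <- function(lab) {
    v <- match(lab, tree$tip.label)
    out <- v
    while (parent[v] != 0L) { v <- parent[v]; out <- c(out, v) }
    out
  }
  shared <- Reduce(intersect, lapply(leaves, path))
  shared[1L]  # paths are leaf-to-root, first shared entry is deepest
}

# maximal-younger-clade oracle: test every leaf subset for being a clade
# whose members all appear after t, keep the inclusion-maximal ones
oracle_ghost_clades <- function(tree, fad, t) {
  labs <- tree$tip.label
  n <- length(labs)
  young <- labs[fad[labs] > t]
  if (!length(young)) return(list())
  subsets <- list()
  for (mask in seq_len(2^length(young)) - 1L) {
    if (mask == 0L) next
    s <- young[bitwAnd(mask, 2^(seq_along(young) - 1L)) > 0L]
    node <- if (length(s) == 1L) match(s, labs) else ape::getMRCA(tree, s)
    desc <- if (node <= n) labs[node] else ape::extract.clade(tree, node)$tip.label
    if (setequal(desc, s)) subsets[[length(subsets) + 1L]] <- sort(s)
  }
  maximal <- Filter(function(s) !any(vapply(subsets, function(o)
    length(o) > length(s) && all(s %in% o), logical(1))), subsets)
  unique(maximal)
}

# exhaustive parsimony oracle: minimize substitutions over all assignments
# of states to internal nodes and missing-state leaves
oracle_parsimony <- function(tree, mat) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  total <- 0L
  for (j in seq_len(ncol(mat))) {
    col <- mat[tree$tip.label, j]
    free <- c(which(is.na(col)), (n + 1L):nn)   # nodes with free state
    fixed <- integer(nn)
    fixed[seq_len(n)] <- ifelse(is.na(col), NA_integer_, col)
    best <- Inf
    for (mask in seq_len(2^length(free)) - 1L) {
      st <- fixed
      st[free] <- bitwAnd(mask, 2^(seq_along(free) - 1L)) > 0L
      steps <- sum(st[tree$edge[, 1L]] != st[tree$edge[, 2L]])
      if (steps < best) best <- steps
    }
    total <- total + best
  }
  total
}

# dense grid-search oracle for the tilted-split maximum likelihood:
# coarse pass over log10(rho) in [-6, 6], then a fine pass around the best
# point, so the discretization error is far below the 1e-6 check
oracle_tilted_ml <- function(k, m) {
  eval_grid <- function(lr) {
    vapply(lr, function(x) {
      e <- (0:(m - 2)) * x; mx <- max(e)
      (k - 1) * x - (mx + log(sum(exp(e - mx))))
    }, numeric(1))
  }
  coarse <- log(10) * seq(-6, 6, length.out = 24001)
  l1 <- eval_grid(coarse)
  best <- which.max(l1)
  lo <- coarse[max(1, best - 2)]; hi <- coarse[min(length(coarse), best + 2)]
  fine <- seq(lo, hi, length.out = 20001)
  l2 <- eval_grid(fine)
  list(rho_hat = exp(fine[which.max(l2)]), logL1 = max(l2))
}

# uniform random regraft of one leaf (rogue-taxon simulations)
random_regraft <- function(tree, leaf) {
  backbone <- ape::drop.tip(tree, leaf)
  variants <- nestshift:::attach_tip_variants(backbone, leaf)
  variants[[sample.int(length(variants), 1L)]]
}
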