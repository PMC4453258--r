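# Internal helpers shared across modules.  Nothing here is exported.

# Run fn() under a temporary RNG state seeded with `seed`; the caller's RNG
# stream is restored afterwards so library code never perturbs user scripts.
eval_with_seed <- function(seed, fn) {
  if (is.null(seed)) return(fn())
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  fn()
}

# Split one master seed into k reproducible substream seeds (< 2^31).
derive_seeds <- function(seed, k) {
  eval_with_seed(seed, function() sample.int(.Machine$integer.max - 1L, k))
}

# Canonical fingerprint of a clade (order-free), used to compare clades
# across trees and to deduplicate topologies.
clade_signature <- function(labels) paste(sort(labels), collapse = "\r")

# All-node tip-label sets: list of length Ntip + Nnode; entry i = labels of
# the tips descending from node i (a tip's set is itself).
node_tipsets <- function(tree) {
  n <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, seq_len(n + tree$Nnode), type = "tips")
  lapply(desc, function(i) tree$tip.label[i])
}

# children of every node, as a list indexed by node id (tips -> integer(0)).
children_list <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  out <- vector("list", nn)
  for (i in seq_len(nn)) out[[i]] <- integer(0)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]
    out[[p]] <- c(out[[p]], tree$edge[e, 2L])
  }
  out
}

root_node <- function(tree) length(tree$tip.label) + 1L

parent_vector <- function(tree) {
  n <- length(tree$tip.label)
  p <- integer(n + tree$Nnode)
  p[tree$edge[, 2L]] <- tree$edge[, 1L]
  p  # root keeps 0
}

# Build a `phylo` from an arbitrary edge list over character keys.
# Tip keys are those that never occur as a parent; their labels come from
# `tip_labels` (named by key; unnamed keys label themselves).
phylo_from_edges <- function(parents, children, tip_labels = NULL,
                             edge_lengths = NULL) {
  stopifnot(length(parents) == length(children))
  parent_set <- unique(parents)
  is_tip_edge <- !(children %in% parent_set)
  tip_keys <- children[is_tip_edge]
  root_key <- setdiff(parent_set, children)
  if (length(root_key) != 1L)
    stop("edge list does not describe a single rooted tree")
  n <- length(tip_keys)
  if (anyDuplicated(children))
    stop("a node has more than one parent")

  kids_of <- split(seq_along(children), factor(parents, levels = parent_set))

  # preorder traversal assigning ids: tips 1..n in visit order, internals
  # n+1.. in visit order (root first, ape convention)
  num <- integer(0)
  names_num <- character(0)
  tip_counter <- 0L
  int_counter <- n
  order_edges <- integer(0)
  lab <- character(n)

  assign_id <- function(key, tip) {
    if (tip) {
      tip_counter <<- tip_counter + 1L
      id <- tip_counter
      lab[id] <<- if (!is.null(tip_labels) && key %in% names(tip_labels))
        tip_labels[[key]] else key
    } else {
      int_counter <<- int_counter + 1L
      id <- int_counter
    }
    num[key] <<- id
    id
  }

  stack <- list(root_key)
  assign_id(root_key, tip = FALSE)
  # iterative DFS emitting edges in cladewise order
  emit_p <- integer(length(parents))
  emit_c <- integer(length(parents))
  emit_idx <- integer(length(parents))
  ecount <- 0L
  dfs <- function(key) {
    for (ei in kids_of[[key]]) {
      ck <- children[ei]
      is_tip <- !(ck %in% parent_set)
      cid <- assign_id(ck, tip = is_tip)
      ecount <<- ecount + 1L
      emit_p[ecount] <<- num[[key]]
      emit_c[ecount] <<- cid
      emit_idx[ecount] <<- ei
      if (!is_tip) dfs(ck)
    }
  }
  dfs(root_key)

  tr <- list(
    edge = cbind(emit_p, emit_c, deparse.level = 0),
    tip.label = lab,
    Nnode = int_counter - n
  )
  if (!is.null(edge_lengths)) tr$edge.length <- edge_lengths[emit_idx]
  class(tr) <- "phylo"
  attr(tr, "order") <- "cladewise"
  tr
}

# TRUE iff two rooted trees carry the same leaf set and the same set of
# clades (topological isomorphism ignoring child order and branch lengths).
tree_isomorphic <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) return(FALSE)
  sig <- function(tr) {
    n <- length(tr$tip.label)
    sets <- node_tipsets(tr)[(n + 1L):(n + tr$Nnode)]
    sort(vapply(sets, clade_signature, character(1)))
  }
  identical(sig(t1), sig(t2))
}

# Quote tip labels that Newick cannot carry bare (e.g. "GHOST:" prefixes).
quote_labels <- function(tree) {
  bad <- grepl("[^A-Za-z0-9_.-]", tree$tip.label)
  tree$tip.label[bad] <- paste0("'", gsub("'", "''", tree$tip.label[bad]), "'")
  tree
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# every internal node has exactly two children (ape::is.binary treats a
# basal trichotomy as an unrooted binary tree, which is wrong here)
is_bifurcating <- function(tree) {
  n <- length(tree$tip.label)
  kids <- tabulate(tree$edge[, 1L], nbins = n + tree$Nnode)
  all(kids[(n + 1L):(n + tree$Nnode)] == 2L)
}
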