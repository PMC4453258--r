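# Matrix representation with parsimony (MRP) supertree stage: Baum-Ragan
# coding of source trees, heuristic parsimony search (random addition +
# NNI/SPR/TBR swapping), strict consensus, greedy reduced-consensus pruning
# of unstable taxa, and grafting of a resolved crown-group subtree.

#' Encode source trees as an MRP matrix
#'
#' Baum-Ragan coding: one binary character per non-root internal node of
#' each source tree; clade members score 1, other taxa present in that
#' source tree score 0, taxa absent from the tree are missing (`NA`).
#' Repeated source trees yield repeated columns (weighting by repetition).
#' A fully unresolved (star) source tree contributes no columns and raises
#' a warning.
#'
#' @param source_trees List of rooted `phylo` objects (each >= 3 leaves).
#' @param all_taxa Character vector of the full taxon set (default: union
#'   of the source trees' leaves).
#' @param add_allzero_outgroup Add the classic hypothetical all-zero
#'   outgroup taxon `MRP_outgroup` (anchors the rooting of the parsimony
#'   search); off by default, where columns are polarized by each source
#'   tree's own root.
#' @return An `mrp_matrix`: list with `taxa`, `mat` (taxa x characters,
#'   values 0/1/`NA`), and per-column `provenance` (source index, node id).
#' @export
encode_mrp <- function(source_trees, all_taxa = NULL,
                       add_allzero_outgroup = FALSE) {
  if (!length(source_trees)) stop("no source trees")
  source_trees <- lapply(source_trees, validate_tree)
  if (any(vapply(source_trees, function(t) length(t$tip.label), 0L) < 3L))
    stop("each source tree needs at least 3 leaves")
  leaves <- lapply(source_trees, `[[`, "tip.label")
  if (is.null(all_taxa)) all_taxa <- sort(unique(unlist(leaves)))
  extra <- setdiff(unlist(leaves), all_taxa)
  if (length(extra))
    stop("source-tree leaves not in all_taxa: ", paste(extra, collapse = ", "))
  all_taxa <- as.character(all_taxa)

  cols <- list()
  prov_src <- integer(0); prov_node <- integer(0)
  for (s in seq_along(source_trees)) {
    tr <- source_trees[[s]]
    n <- length(tr$tip.label)
    inner <- setdiff((n + 1L):(n + tr$Nnode), root_node(tr))
    if (!length(inner)) {
      warning("source tree ", s, " is a star and contributes no characters")
      next
    }
    sets <- node_tipsets(tr)
    for (v in inner) {
      col <- rep(NA_integer_, length(all_taxa))
      col[match(tr$tip.label, all_taxa)] <- 0L
      col[match(sets[[v]], all_taxa)] <- 1L
      scored <- col[!is.na(col)]
      if (!any(scored == 1L) || !any(scored == 0L)) next  # constant: drop
      cols[[length(cols) + 1L]] <- col
      prov_src <- c(prov_src, s); prov_node <- c(prov_node, v)
    }
  }
  if (!length(cols)) stop("no informative characters could be coded")
  mat <- do.call(cbind, cols)
  rownames(mat) <- all_taxa
  if (add_allzero_outgroup) {
    if ("MRP_outgroup" %in% all_taxa) stop("taxon 'MRP_outgroup' already present")
    mat <- rbind(mat, MRP_outgroup = rep(0L, ncol(mat)))
    all_taxa <- c(all_taxa, "MRP_outgroup")
  }
  if (length(all_taxa) < 3L) stop("an MRP matrix needs at least 3 taxa")
  structure(list(taxa = all_taxa, mat = mat,
                 provenance = data.frame(source = prov_src, node = prov_node)),
            class = "mrp_matrix")
}

#' @export
print.mrp_matrix <- function(x, ...) {
  cat("MRP matrix:", length(x$taxa), "taxa x", ncol(x$mat), "characters;",
      sum(is.na(x$mat)), "missing entries\n")
  invisible(x)
}

#' Serialize an MRP matrix
#'
#' @param x An `mrp_matrix`.
#' @param path Output file.
#' @param format `"nexus"` (DATA block, symbols `01`, missing `?`) or
#'   `"csv"` (taxa in rows).
#' @export
write_mrp <- function(x, path, format = c("nexus", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "mrp_matrix"))
  if (format == "csv") {
    df <- as.data.frame(x$mat)
    names(df) <- paste0("char", seq_len(ncol(df)))
    utils::write.csv(cbind(taxon = x$taxa, df), path, row.names = FALSE,
                     quote = FALSE, na = "?")
    return(invisible(path))
  }
  rows <- apply(x$mat, 1L, function(r) paste(ifelse(is.na(r), "?", r),
                                             collapse = ""))
  lines <- c("#NEXUS", "BEGIN DATA;",
             sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", length(x$taxa),
                     ncol(x$mat)),
             "  FORMAT SYMBOLS=\"01\" MISSING=?;",
             "  MATRIX",
             sprintf("    %s %s", format(x$taxa), rows),
             "  ;", "END;")
  writeLines(lines, path)
  invisible(path)
}

as_phydat <- function(x) {
  chr <- matrix(as.character(x$mat), nrow = nrow(x$mat),
                dimnames = dimnames(x$mat))
  chr[is.na(chr)] <- "?"
  phangorn::phyDat(chr, type = "USER", levels = c("0", "1"), ambiguity = "?")
}

#' Fitch parsimony length of a tree on an MRP matrix
#'
#' Missing states are wildcards (the full state set) and never contribute
#' length.  The tree must be fully bifurcating; resolve polytomies first
#' (see [resolve_polytomies()]).
#'
#' @param tree A bifurcating rooted `phylo` whose leaf set equals the
#'   matrix taxa.
#' @param matrix An `mrp_matrix`.
#' @return Integer parsimony length summed over characters.
#' @export
fitch_score <- function(tree, matrix) {
  stopifnot(inherits(matrix, "mrp_matrix"))
  validate_tree(tree)
  if (!setequal(tree$tip.label, matrix$taxa))
    stop("tree leaf set must equal the matrix taxa")
  if (!is_bifurcating(tree))
    stop("tree must be fully bifurcating; resolve polytomies first")
  as.integer(phangorn::fitch(tree, as_phydat(matrix)))
}

# Internal scorer tolerating trees on a subset of matrix taxa (used during
# stepwise addition).
fitch_partial <- function(tree, pd) as.integer(phangorn::fitch(tree, pd))

#' Parsimony search settings
#'
#' Desk-scale defaults (100 replicates, hold 5, TBR); the full-scale
#' settings (10 000 replicates, hold 20, TBR) are reachable by argument.
#'
#' @param replicates Random-addition replicates (>= 1).
#' @param hold Trees kept per replicate (>= 1).
#' @param swapper `"TBR"`, `"SPR"` or `"NNI"`.
#' @param seed Master seed.
#' @return A `search_settings` list.
#' @export
search_settings <- function(replicates = 100L, hold = 5L,
                            swapper = c("TBR", "SPR", "NNI"), seed = 1L) {
  swapper <- match.arg(swapper)
  stopifnot(replicates >= 1L, hold >= 1L)
  structure(list(replicates = as.integer(replicates), hold = as.integer(hold),
                 swapper = swapper, seed = as.integer(seed)),
            class = "search_settings")
}

## -- edge-key surgery -------------------------------------------------------
# Trees are manipulated as parent/child key lists ("t:<label>" for tips,
# "n<i>" for internal nodes); phylo_from_edges() rebuilds the phylo.

tree_keys <- function(tree) {
  n <- length(tree$tip.label)
  key <- function(id) ifelse(id <= n, paste0("t:", tree$tip.label[id]),
                             paste0("n", id))
  labs <- stats::setNames(tree$tip.label, paste0("t:", tree$tip.label))
  list(p = key(tree$edge[, 1L]), c = key(tree$edge[, 2L]),
       root = paste0("n", n + 1L), labels = labs)
}

keys_to_phylo <- function(p, c, labels) {
  tip_keys <- setdiff(c, p)
  labs <- stats::setNames(sub("^t:", "", tip_keys), tip_keys)
  labs[names(labels)[names(labels) %in% tip_keys]] <-
    labels[names(labels) %in% tip_keys]
  phylo_from_edges(p, c, tip_labels = labs)
}

# splice out internal nodes left with a single child; drop a unary root
suppress_unary_keys <- function(p, c) {
  repeat {
    kid_count <- table(p)
    par_of <- stats::setNames(p, c)
    unary <- names(kid_count)[kid_count == 1L]
    if (!length(unary)) return(list(p = p, c = c))
    v <- unary[[1L]]
    child_edge <- which(p == v)
    w <- c[child_edge]
    if (v %in% c) {          # splice: (u,v),(v,w) -> (u,w)
      up_edge <- which(c == v)
      c[up_edge] <- w
      p <- p[-child_edge]; c <- c[-child_edge]
    } else {                 # unary root: drop it, w becomes root
      p <- p[-child_edge]; c <- c[-child_edge]
    }
  }
}

# descendants (keys) of `node` including itself, from a child map
subtree_keys <- function(p, c, node) {
  out <- node
  frontier <- node
  while (length(frontier)) {
    nxt <- c[p %in% frontier]
    out <- c(out, nxt)
    frontier <- nxt[nxt %in% p]  # recurse only into internals
  }
  unique(out)
}

new_key_counter <- local({
  i <- 0L
  function() { i <<- i + 1L; paste0("x", i) }
})

# All rooted-NNI neighbours: for each internal non-root node v with parent
# u, exchange one child of v with one other child of u.
nni_neighbors <- function(tree) {
  k <- tree_keys(tree)
  p <- k$p; c <- k$c
  out <- list()
  for (v in unique(p)) {
    if (v == k$root) next
    u <- p[match(v, c)]
    v_kids <- c[p == v]
    u_kids <- setdiff(c[p == u], v)
    for (a in v_kids) for (b in u_kids) {
      p2 <- p; c2 <- c
      c2[p == v & c == a] <- b
      c2[p == u & c == b] <- a
      out[[length(out) + 1L]] <- keys_to_phylo(p2, c2, k$labels)
    }
  }
  out
}

# Prune each clade and reattach on every backbone edge (and above the
# backbone root).  With `rerootings = TRUE` (TBR) the pruned clade is also
# reattached in each of its own rerootings.
spr_neighbors <- function(tree, rerootings = FALSE) {
  k <- tree_keys(tree)
  p <- k$p; c <- k$c
  out <- list()
  for (ei in seq_along(p)) {
    v <- c[ei]
    sub <- subtree_keys(p, c, v)
    inside <- (c %in% sub) & (p %in% sub)
    sub_p <- p[inside]; sub_c <- c[inside]
    back <- !(c %in% sub) & seq_along(p) != ei
    bp <- p[back]; bc <- c[back]
    if (length(bc) < 2L) next
    sup <- suppress_unary_keys(bp, bc)
    bp <- sup$p; bc <- sup$c
    back_root <- setdiff(bp, bc)

    variants <- list(list(p = sub_p, c = sub_c, root = v))
    if (rerootings && length(sub_p))
      variants <- c(variants, reroot_variants(sub_p, sub_c, v))

    for (var in variants) {
      for (bi in seq_along(bp)) {
        # split backbone edge bi with a new node nk and hang the clade there:
        # (bp[bi], bc[bi]) becomes (bp[bi], nk), (nk, bc[bi]), (nk, clade root)
        nk <- new_key_counter()
        p3 <- bp; c3 <- bc
        c3[bi] <- nk
        p3 <- c(p3, nk, nk, var$p)
        c3 <- c(c3, bc[bi], var$root, var$c)
        out[[length(out) + 1L]] <- keys_to_phylo(p3, c3, k$labels)
      }
      nk <- new_key_counter()           # attach above the backbone root
      p3 <- c(bp, nk, nk, var$p)
      c3 <- c(bc, back_root, var$root, var$c)
      out[[length(out) + 1L]] <- keys_to_phylo(p3, c3, k$labels)
    }
  }
  out
}

# Rerootings of a pruned clade on each of its internal edges (the TBR
# reconnection-point enumeration).
reroot_variants <- function(sub_p, sub_c, root) {
  out <- list()
  for (ei in seq_along(sub_p)) {
    u <- sub_p[ei]; w <- sub_c[ei]
    if (u == root) next  # rerooting on a root edge reproduces the original
    nk <- new_key_counter()
    # undirected adjacency minus edge (u,w), plus new root nk - u, nk - w
    a <- c(sub_p[-ei], nk, nk)
    b <- c(sub_c[-ei], u, w)
    oriented <- orient_from(a, b, nk)
    sup <- suppress_unary_keys(oriented$p, oriented$c)
    out[[length(out) + 1L]] <- list(p = sup$p, c = sup$c, root = nk)
  }
  out
}

# Orient an undirected edge list away from `root` (BFS).
orient_from <- function(a, b, root) {
  p <- character(0); c <- character(0)
  frontier <- root
  seen <- root
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) {
      hits <- which((a == v & !(b %in% seen)) | (b == v & !(a %in% seen)))
      for (h in hits) {
        w <- if (a[h] == v) b[h] else a[h]
        if (w %in% seen) next
        p <- c(p, v); c <- c(c, w)
        seen <- c(seen, w)
        nxt <- c(nxt, w)
      }
    }
    frontier <- nxt
  }
  list(p = p, c = c)
}

attach_tip_variants <- function(tree, label) {
  k <- tree_keys(tree)
  p <- k$p; c <- k$c
  tk <- paste0("t:", label)
  labs <- c(k$labels, stats::setNames(label, tk))
  out <- list()
  for (ei in seq_along(p)) {
    nk <- new_key_counter()
    p2 <- p; c2 <- c
    c2[ei] <- nk
    p2 <- c(p2, nk, nk)
    c2 <- c(c2, c[ei], tk)
    out[[length(out) + 1L]] <- keys_to_phylo(p2, c2, labs)
  }
  nk <- new_key_counter()
  out[[length(out) + 1L]] <-
    keys_to_phylo(c(p, nk, nk), c(c, k$root, tk), labs)
  out
}

three_taxon_trees <- function(a, b, c3) {
  lab <- c(a, b, c3)
  lapply(1:3, function(i) {
    pair <- lab[-i]
    phylo_from_edges(c("R", "R", "P", "P"),
                     c(lab[i], "P", pair[1L], pair[2L]))
  })
}

#' Heuristic parsimony search
#'
#' Each replicate builds a random-addition starting tree (stepwise
#' insertion at the best-scoring position) and hill-climbs to a local
#' optimum under the chosen branch swapper; up to `hold` equally optimal
#' trees are kept per replicate and the globally best score's trees are
#' returned, deduplicated by topology.  Ties keep earlier-found trees, so
#' the result is deterministic given the seed.
#'
#' @param matrix An `mrp_matrix`.
#' @param settings A [search_settings()] object.
#' @return List of best trees (`phylo`), with the score in attribute
#'   `score`.
#' @export
heuristic_search <- function(matrix, settings = search_settings()) {
  stopifnot(inherits(matrix, "mrp_matrix"))
  pd <- as_phydat(matrix)
  taxa <- matrix$taxa
  if (length(taxa) < 4L) stop("search needs at least 4 taxa")
  neighbors <- switch(settings$swapper,
                      NNI = function(tr) nni_neighbors(tr),
                      SPR = function(tr) spr_neighbors(tr, rerootings = FALSE),
                      TBR = function(tr) spr_neighbors(tr, rerootings = TRUE))
  rep_seeds <- derive_seeds(settings$seed, settings$replicates)
  best_score <- Inf
  best <- list(); best_sig <- character(0)

  add_best <- function(tr, sc) {
    if (sc > best_score) return(invisible())
    if (sc < best_score) { best_score <<- sc; best <<- list(); best_sig <<- character(0) }
    if (length(best) >= settings$hold * settings$replicates) return(invisible())
    sig <- topo_signature(tr)
    if (sig %in% best_sig) return(invisible())
    best[[length(best) + 1L]] <<- tr
    best_sig <<- c(best_sig, sig)
  }

  for (r in seq_len(settings$replicates)) {
    res <- eval_with_seed(rep_seeds[r], function() {
      ord <- sample(taxa)
      cand <- three_taxon_trees(ord[1L], ord[2L], ord[3L])
      sc <- vapply(cand, fitch_partial, 0L, pd = pd)
      cur <- cand[[which.min(sc)]]
      for (x in ord[-(1:3)]) {
        cand <- attach_tip_variants(cur, x)
        sc <- vapply(cand, fitch_partial, 0L, pd = pd)
        cur <- cand[[which.min(sc)]]
      }
      cur_sc <- fitch_partial(cur, pd)
      kept <- list(cur); kept_sc <- cur_sc
      repeat {
        nb <- neighbors(cur)
        if (!length(nb)) break
        sc <- vapply(nb, fitch_partial, 0L, pd = pd)
        if (min(sc) < cur_sc) {
          cur <- nb[[which.min(sc)]]
          cur_sc <- min(sc)
        } else {
          ties <- nb[sc == cur_sc]
          kept <- c(list(cur), ties)
          break
        }
      }
      list(trees = kept[seq_len(min(length(kept), settings$hold))],
           score = cur_sc)
    })
    for (tr in res$trees) add_best(tr, res$score)
  }
  attr(best, "score") <- best_score
  best
}

topo_signature <- function(tree) {
  n <- length(tree$tip.label)
  sets <- node_tipsets(tree)[(n + 1L):(n + tree$Nnode)]
  paste(sort(vapply(sets, clade_signature, character(1))), collapse = "|")
}

#' Strict consensus of rooted trees
#'
#' Keeps exactly the clades present in every input tree; disagreements
#' collapse to polytomies.
#'
#' @param trees Non-empty list of rooted `phylo` objects sharing one leaf
#'   set.
#' @return A rooted `phylo`.
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("empty tree set")
  trees <- lapply(trees, validate_tree)
  base <- trees[[1L]]$tip.label
  ok <- vapply(trees, function(t) setequal(t$tip.label, base), logical(1))
  if (!all(ok)) stop("all trees must share one leaf set")
  if (length(trees) == 1L) return(trees[[1L]])
  cons <- ape::consensus(trees, p = 1, rooted = TRUE)
  cons$node.label <- NULL
  validate_tree(cons)
}

#' Greedy pruning of unstable (rogue) taxa
#'
#' Repeatedly removes the taxon whose deletion most increases the number
#' of resolved nodes in the strict consensus of the leaf-pruned tree set;
#' stops when no removal adds resolution or `max_removals` is reached.
#' For each removed taxon the alternative attachment positions (the
#' sibling clades it floats among across the input trees) are reported.
#'
#' @param trees List of >= 2 rooted trees on one leaf set.
#' @param max_removals Cap on removed taxa (default: leaves minus 4).
#' @return List with `removed` (labels), `positions` (per removed taxon, a
#'   list of distinct sibling clades), and `reduced_consensus`.
#' @export
prune_unstable <- function(trees, max_removals = NULL) {
  if (length(trees) < 2L) stop("need at least 2 trees")
  trees <- lapply(trees, validate_tree)
  taxa <- trees[[1L]]$tip.label
  max_removals <- max_removals %||% max(0L, length(taxa) - 4L)
  removed <- character(0)
  cur <- trees
  resolution <- function(ts) strict_consensus(ts)$Nnode
  cur_res <- resolution(cur)
  while (length(removed) < max_removals) {
    remaining <- setdiff(taxa, removed)
    if (length(remaining) <= 3L) break
    gains <- vapply(remaining, function(x) {
      pruned <- lapply(cur, ape::drop.tip, tip = x)
      resolution(pruned) - cur_res
    }, numeric(1))
    if (max(gains) <= 0) break
    x <- remaining[which.max(gains)]
    cur <- lapply(cur, ape::drop.tip, tip = x)
    cur_res <- resolution(cur)
    removed <- c(removed, x)
  }
  positions <- lapply(removed, function(x) {
    sib <- lapply(trees, function(t) {
      v <- match(x, t$tip.label)
      u <- parent_vector(t)[v]
      kids <- setdiff(children_list(t)[[u]], v)
      labs <- sort(setdiff(unlist(node_tipsets(t)[kids]), removed))
      labs
    })
    unique(sib[lengths(sib) > 0L])
  })
  names(positions) <- removed
  list(removed = removed, positions = positions,
       reduced_consensus = strict_consensus(cur))
}

#' Graft a resolved subtree onto a backbone terminal
#'
#' Replaces the leaf `terminal` of `backbone` by the root of `subtree`
#' (e.g. expanding a crown-group placeholder into its resolved phylogeny).
#' A single label as `subtree` is a relabeling.
#'
#' @param backbone Rooted `phylo`.
#' @param subtree Rooted `phylo`, or a single character label.
#' @param terminal Leaf label of `backbone` to replace.
#' @return The combined tree with `Ntip(backbone) - 1 + Ntip(subtree)`
#'   leaves.
#' @export
graft <- function(backbone, subtree, terminal) {
  validate_tree(backbone)
  ix <- match(terminal, backbone$tip.label)
  if (is.na(ix)) stop("terminal '", terminal, "' not found in backbone")
  if (is.character(subtree) && length(subtree) == 1L) {
    clash <- intersect(subtree, setdiff(backbone$tip.label, terminal))
    if (length(clash)) stop("label collision: ", paste(clash, collapse = ", "))
    backbone$tip.label[ix] <- subtree
    return(backbone)
  }
  validate_tree(subtree)
  clash <- intersect(subtree$tip.label, setdiff(backbone$tip.label, terminal))
  if (length(clash))
    stop("label collision: ", paste(clash, collapse = ", "))
  n_expect <- length(backbone$tip.label) - 1L + length(subtree$tip.label)
  backbone$edge.length <- NULL
  subtree$edge.length <- NULL
  out <- ape::bind.tree(backbone, subtree, where = ix)
  out$node.label <- NULL
  out <- validate_tree(out)
  stopifnot(length(out$tip.label) == n_expect)
  out
}

#' One-call MRP supertree
#'
#' Encodes the source trees, runs the heuristic search and returns the
#' strict consensus of the best trees.  By default the classic all-zero
#' hypothetical outgroup is added to anchor the rooting (parsimony length
#' is unchanged by rerooting, so without an anchor the consensus over
#' rerooted optima collapses); the outgroup is stripped from the result.
#'
#' @inheritParams encode_mrp
#' @param settings A [search_settings()].
#' @return List with `consensus` (`phylo`), `trees` (the optima), `score`,
#'   and `matrix`.
#' @export
mrp_supertree <- function(source_trees, settings = search_settings(),
                          all_taxa = NULL, add_allzero_outgroup = TRUE) {
  mx <- encode_mrp(source_trees, all_taxa,
                   add_allzero_outgroup = add_allzero_outgroup)
  trees <- heuristic_search(mx, settings)
  score <- attr(trees, "score")
  if (add_allzero_outgroup) {
    trees <- lapply(trees, function(t) {
      t <- ape::root(t, outgroup = "MRP_outgroup", resolve.root = TRUE)
      ape::drop.tip(t, "MRP_outgroup")
    })
  }
  cons <- strict_consensus(trees)
  list(consensus = cons, trees = trees, score = score, matrix = mx)
}
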