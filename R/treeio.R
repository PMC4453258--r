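#' Read a rooted tree from Newick or NEXUS
#'
#' Parses a single rooted, possibly polytomous tree.  Polytomies are
#' preserved, never auto-resolved; internal node labels are dropped on input
#' (leaf labels are the taxon identity).  Branch lengths, if present, are
#' retained but ignored by all analysis stages.
#'
#' @param path Path to the tree file.
#' @param format `"auto"` (default, guessed from extension/content),
#'   `"newick"` or `"nexus"`.
#' @return An [ape::read.tree()]-style `phylo` object validated to be a
#'   single rooted tree with unique, non-empty leaf labels.
#' @seealso [write_tree()], [mrca_clade()]
#' @export
read_tree <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(nex|nxs|nexus)$", path, ignore.case = TRUE) ||
                  any(grepl("^#NEXUS", txt, ignore.case = TRUE)))
      "nexus" else "newick"
  }
  if (format == "newick") {
    check_newick_syntax(txt, path)
    body <- paste(txt, collapse = "")
    if (!grepl(";\\s*$", body)) body <- paste0(body, ";")
    tree <- tryCatch(ape::read.tree(text = body),
                     error = function(e) stop("cannot parse Newick in '", path,
                                              "': ", conditionMessage(e)))
  } else {
    tree <- tryCatch(ape::read.nexus(path),
                     error = function(e) stop("cannot parse NEXUS in '", path,
                                              "': ", conditionMessage(e)))
  }
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1L)
      stop("'", path, "' contains ", length(tree),
           " trees; read_tree() expects one (use read_trees())")
    tree <- tree[[1L]]
  }
  if (is.null(tree)) stop("cannot parse tree in '", path, "'")
  tree$node.label <- NULL
  tree$tip.label <- unquote_labels(tree$tip.label)
  validate_tree(tree)
}

# ape keeps the surrounding single quotes of quoted Newick labels; strip
# them and unescape doubled quotes.
unquote_labels <- function(labs) {
  quoted <- grepl("^'.*'$", labs)
  labs[quoted] <- gsub("''", "'", sub("^'(.*)'$", "\\1", labs[quoted]))
  labs
}

#' Read a set of trees (e.g. supertree sources)
#'
#' @inheritParams read_tree
#' @return A list of validated `phylo` objects.
#' @export
read_trees <- function(path, format = c("auto", "newick", "nexus")) {
  format <- match.arg(format)
  txt <- readLines(path, warn = FALSE)
  nexus <- format == "nexus" ||
    (format == "auto" && (grepl("\\.(nex|nxs|nexus)$", path, ignore.case = TRUE) ||
                          any(grepl("^#NEXUS", txt, ignore.case = TRUE))))
  trees <- if (nexus) ape::read.nexus(path) else ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- list(trees)
  lapply(trees, function(tr) {
    tr$node.label <- NULL
    tr$tip.label <- unquote_labels(tr$tip.label)
    validate_tree(tr)
  })
}

# Light syntactic scan so malformed Newick is reported with a position,
# which ape's parser does not do.
check_newick_syntax <- function(lines, path) {
  depth <- 0L
  in_quote <- FALSE
  for (li in seq_along(lines)) {
    chars <- strsplit(lines[li], "", fixed = TRUE)[[1L]]
    for (ci in seq_along(chars)) {
      ch <- chars[ci]
      if (ch == "'") in_quote <- !in_quote
      if (in_quote) next
      if (ch == "(") depth <- depth + 1L
      if (ch == ")") {
        depth <- depth - 1L
        if (depth < 0L)
          stop("malformed Newick in '", path, "': unbalanced ')' at line ",
               li, ", character ", ci)
      }
    }
  }
  if (depth != 0L)
    stop("malformed Newick in '", path, "': ", depth,
         " unclosed '(' at end of file")
  if (in_quote)
    stop("malformed Newick in '", path, "': unterminated quoted label")
  invisible(TRUE)
}

#' Validate the rooted-tree invariants
#'
#' Checks that `tree` is a single rooted tree: exactly one root, every
#' non-root node with exactly one parent, internal nodes with at least two
#' children, and unique non-empty leaf labels.
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly usable in pipelines (returned visibly).
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  n <- length(tree$tip.label)
  if (n < 2L) stop("tree must have at least 2 leaves")
  if (anyNA(tree$tip.label) || any(!nzchar(tree$tip.label)))
    stop("unlabeled leaves are not allowed")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate leaf labels: ", paste(dup, collapse = ", "))
  # rootedness is structural here: exactly one parentless node (checked
  # below); a root polytomy is a valid rooted tree, unlike ape::is.rooted
  nn <- n + tree$Nnode
  kids <- tabulate(tree$edge[, 1L], nbins = nn)
  if (any(kids[(n + 1L):nn] < 2L))
    stop("internal nodes must have at least 2 children")
  pars <- tabulate(tree$edge[, 2L], nbins = nn)
  if (any(pars > 1L)) stop("a node has more than one parent")
  roots <- which(pars[(n + 1L):nn] == 0L)
  if (length(roots) != 1L) stop("tree must have exactly one root")
  if (nrow(tree$edge) != nn - 1L) stop("tree is not connected")
  tree
}

#' Write a tree to Newick or NEXUS
#'
#' Labels containing characters outside `[A-Za-z0-9_.-]` (such as the
#' `GHOST:` prefix of collapsed ghost lineages) are single-quoted so the
#' output round-trips.
#'
#' @param tree A validated `phylo`.
#' @param path Optional output path; when `NULL` the serialized text is
#'   returned instead.
#' @param format `"newick"` (default) or `"nexus"`.
#' @return The serialized text (invisibly when written to `path`).
#' @export
write_tree <- function(tree, path = NULL, format = c("newick", "nexus")) {
  format <- match.arg(format)
  validate_tree(tree)
  nwk <- newick_string(tree)
  txt <- if (format == "newick") nwk else
    paste(c("#NEXUS", "BEGIN TREES;",
            paste0("  TREE tree1 = ", nwk), "END;"), collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# Own Newick emitter: ape's write.tree rewrites characters it dislikes
# inside labels (the GHOST: prefix would not round-trip).
newick_string <- function(tree) {
  n <- length(tree$tip.label)
  ch <- children_list(tree)
  len <- NULL
  if (!is.null(tree$edge.length)) {
    len <- numeric(n + tree$Nnode)
    len[tree$edge[, 2L]] <- tree$edge.length
  }
  q <- function(lab) {
    if (grepl("[^A-Za-z0-9_.-]", lab))
      paste0("'", gsub("'", "''", lab), "'") else lab
  }
  rec <- function(v) {
    s <- if (v <= n) q(tree$tip.label[v]) else
      paste0("(", paste(vapply(ch[[v]], rec, character(1)), collapse = ","), ")")
    if (!is.null(len) && v != n + 1L)
      s <- paste0(s, ":", format(len[v], digits = 15))
    s
  }
  paste0(rec(n + 1L), ";")
}

#' Most recent common ancestor of a clade
#'
#' @param tree A `phylo`.
#' @param leaves Character vector of leaf labels (a clade identifier); a
#'   single leaf returns the leaf node itself.
#' @return The node id of the MRCA.
#' @export
mrca_clade <- function(tree, leaves) {
  leaves <- unique(as.character(leaves))
  if (!length(leaves)) stop("empty leaf set")
  unknown <- setdiff(leaves, tree$tip.label)
  if (length(unknown))
    stop("unknown leaf label(s): ", paste(unknown, collapse = ", "))
  if (length(leaves) == 1L) return(match(leaves, tree$tip.label))
  ape::getMRCA(tree, leaves)
}
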