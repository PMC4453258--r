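test_that("encode_mrp codes clades Baum-Ragan style", {
  t1 <- nwk("((A,B),C);")
  mx <- encode_mrp(list(t1), all_taxa = c("A", "B", "C", "D"))
  expect_equal(ncol(mx$mat), 1L)
  expect_equal(mx$mat[, 1], c(A = 1L, B = 1L, C = 0L, D = NA))

  cat4 <- nwk("(((A,B),C),D);")
  mx2 <- encode_mrp(list(cat4))
  expect_equal(ncol(mx2$mat), 2L)
  sets <- apply(mx2$mat, 2, function(col) paste(sort(names(col)[which(col == 1L)]),
                                                collapse = ""))
  expect_setequal(sets, c("AB", "ABC"))

  # duplicated sources keep duplicated columns (weight by repetition)
  mx3 <- encode_mrp(list(cat4, cat4))
  expect_equal(ncol(mx3$mat), 4L)
  expect_equal(mx3$provenance$source, c(1L, 1L, 2L, 2L))

  expect_warning(encode_mrp(list(nwk("(A,B,C);"), cat4)), "star")
  expect_error(encode_mrp(list(t1), all_taxa = c("A", "B")), "not in all_taxa")

  og <- encode_mrp(list(t1), add_allzero_outgroup = TRUE)
  expect_true("MRP_outgroup" %in% og$taxa)
  expect_true(all(og$mat["MRP_outgroup", ] == 0L))
})

test_that("fitch_score handles binary characters and missing wildcards", {
  mxAB <- encode_mrp(list(nwk("((A,B),C);")))
  expect_equal(fitch_score(nwk("((A,B),C);"), mxAB), 1L)
  expect_equal(fitch_score(nwk("((A,C),B);"), mxAB), 1L)
  expect_error(fitch_score(nwk("(A,B,C);"), mxAB), "bifurcating")
  expect_error(fitch_score(nwk("((A,B),D);"), mxAB), "leaf set")
})

test_that("fitch_score equals the exhaustive assignment oracle", {
  set.seed(13)
  for (rep in 1:10) {
    ntax <- sample(6:8, 1)
    taxa <- LETTERS[seq_len(ntax)]
    ncols <- 12
    mat <- matrix(sample(c(0L, 1L, NA), ntax * ncols, replace = TRUE,
                         prob = c(0.45, 0.4, 0.15)),
                  ntax, ncols, dimnames = list(taxa, NULL))
    keep <- apply(mat, 2, function(col) {
      s <- col[!is.na(col)]; any(s == 0L) && any(s == 1L)
    })
    mat <- mat[, keep, drop = FALSE]
    mx <- structure(list(taxa = taxa, mat = mat,
                         provenance = data.frame(source = integer(0),
                                                 node = integer(0))),
                    class = "mrp_matrix")
    tr <- ape::rtree(ntax, rooted = TRUE, br = NULL)
    tr$tip.label <- sample(taxa)
    expect_identical(fitch_score(tr, mx), oracle_parsimony(tr, mat),
                     info = paste("rep", rep))
  }
})

test_that("heuristic search recovers the generating tree from its own clades", {
  true5 <- nwk("(((A,B),C),(D,E));")
  res <- mrp_supertree(list(true5, true5),
                       search_settings(replicates = 10, hold = 5,
                                       swapper = "SPR", seed = 42))
  expect_true(trees_isomorphic(res$consensus, true5))
  expect_equal(res$score, 6L)  # 3 clades x 2 copies, 1 step each

  # conflict-free 4-taxon matrix: unique most-parsimonious topology
  true4 <- nwk("((A,B),(C,D));")
  res4 <- mrp_supertree(list(true4), search_settings(replicates = 6, seed = 3))
  expect_true(trees_isomorphic(res4$consensus, true4))

  # exhaustive check: no bifurcating tree on the outgroup-rooted matrix
  # scores below the search optimum
  mx <- encode_mrp(list(true5), add_allzero_outgroup = TRUE)
  best <- heuristic_search(mx, search_settings(replicates = 8, seed = 1))
  all6 <- phangorn::allTrees(6, rooted = TRUE, tip.label = mx$taxa)
  scores <- vapply(all6, fitch_score, 0L, matrix = mx)
  expect_equal(attr(best, "score"), min(scores))
})

test_that("heuristic search is deterministic given the seed", {
  true5 <- nwk("(((A,B),C),(D,E));")
  mx <- encode_mrp(list(true5), add_allzero_outgroup = TRUE)
  st <- search_settings(replicates = 5, hold = 3, swapper = "TBR", seed = 11)
  b1 <- heuristic_search(mx, st)
  b2 <- heuristic_search(mx, st)
  expect_equal(length(b1), length(b2))
  expect_identical(lapply(b1, clade_sets), lapply(b2, clade_sets))
})

test_that("strict consensus keeps exactly the shared clades", {
  one <- nwk("((A,B),C);")
  expect_true(trees_isomorphic(strict_consensus(list(one)), one))
  star <- strict_consensus(list(nwk("((A,B),C);"), nwk("((A,C),B);")))
  expect_equal(star$Nnode, 1L)
  c4 <- strict_consensus(list(nwk("(((A,B),C),D);"), nwk("(((B,A),C),D);")))
  expect_true(trees_isomorphic(c4, nwk("(((A,B),C),D);")))
  expect_error(strict_consensus(list(one, nwk("((A,B),D);"))), "leaf set")

  # set-algebra oracle on random trees
  set.seed(23)
  for (rep in 1:10) {
    trees <- lapply(1:3, function(i) {
      tr <- ape::rtree(8, rooted = TRUE, br = NULL)
      tr$tip.label <- LETTERS[1:8]
      tr
    })
    cons <- strict_consensus(trees)
    want <- Reduce(intersect, lapply(trees, clade_sets))
    expect_setequal(clade_sets(cons), want)
  }
})

test_that("unstable-taxon pruning removes rogues and reports their positions", {
  base <- nwk("((((A,B),C),(D,E)),F);")
  moved <- list(base,
                nwk("((((A,F),B),C),(D,E));"),
                nwk("(((A,B),(C,F)),(D,E));"))
  pr <- prune_unstable(moved)
  expect_equal(pr$removed, "F")
  expect_true(trees_isomorphic(pr$reduced_consensus,
                               nwk("(((A,B),C),(D,E));")))
  expect_gte(length(pr$positions$F), 2L)

  same <- list(base, base, base)
  pr0 <- prune_unstable(same)
  expect_length(pr0$removed, 0L)
  expect_true(trees_isomorphic(pr0$reduced_consensus, base))
})

test_that("a randomly regrafted leaf is pruned first in most replicates", {
  set.seed(67)
  reps <- 25
  hit <- 0
  for (i in seq_len(reps)) {
    tr <- ape::rtree(20, rooted = TRUE, br = NULL)
    rogue <- tr$tip.label[1]
    copies <- lapply(1:10, function(j) random_regraft(tr, rogue))
    pr <- prune_unstable(copies, max_removals = 3)
    hit <- hit + (length(pr$removed) >= 1 && pr$removed[1] == rogue)
  }
  expect_gte(hit / reps, 0.95)
})

test_that("graft replaces a terminal by a subtree and is invertible", {
  b <- nwk("((A,Croc),B);")
  s <- nwk("(X,Y);")
  g <- graft(b, s, "Croc")
  expect_true(trees_isomorphic(g, nwk("((A,(X,Y)),B);")))
  # single-leaf subtree is a relabeling
  expect_true(trees_isomorphic(graft(b, "Z", "Croc"), nwk("((A,Z),B);")))
  expect_error(graft(b, s, "Nope"), "not found")
  expect_error(graft(b, nwk("(A,Q);"), "Croc"), "collision")

  set.seed(3)
  for (rep in 1:10) {
    nb <- sample(4:12, 1); ns <- sample(2:8, 1)
    backbone <- ape::rtree(nb, rooted = TRUE, br = NULL)
    backbone$tip.label <- paste0("b", seq_len(nb))
    sub <- ape::rtree(ns, rooted = TRUE, br = NULL)
    sub$tip.label <- paste0("s", seq_len(ns))
    term <- sample(backbone$tip.label, 1)
    g <- graft(backbone, sub, term)
    expect_equal(length(g$tip.label), nb - 1L + ns)
    # pruning the grafted subtree back recovers the backbone minus terminal
    back <- ape::drop.tip(g, sub$tip.label)
    expect_true(trees_isomorphic(back, ape::drop.tip(backbone, term)))
  }
})

test_that("mrp matrices serialize to NEXUS and CSV", {
  mx <- encode_mrp(list(nwk("(((A,B),C),D);")))
  tf <- withr::local_tempfile(fileext = ".nex")
  write_mrp(mx, tf, format = "nexus")
  lines <- readLines(tf)
  expect_equal(lines[1], "#NEXUS")
  expect_true(any(grepl("NTAX=4 NCHAR=2", lines)))
  tfc <- withr::local_tempfile(fileext = ".csv")
  write_mrp(mx, tfc, format = "csv")
  back <- utils::read.csv(tfc, na.strings = "?")
  expect_equal(nrow(back), 4L)
})
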