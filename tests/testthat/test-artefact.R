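# builds a shift_detections object by hand so tracking can be tested
# against chosen per-bin clades
fake_detections <- function(series, picks) {
  rows <- list()
  clades <- list()
  for (p in picks) {
    cid <- paste(sort(p$members), collapse = ",")
    b <- as.character(p$bin)
    if (is.null(clades[[b]])) clades[[b]] <- list()
    clades[[b]][[cid]] <- p$members
    rows[[length(rows) + 1L]] <- data.frame(
      bin = p$bin, clade_id = cid, k = length(p$members),
      delta1 = 1, delta2 = 1, p_local = 0.01, p_tree = 0.01,
      significant = TRUE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "clades") <- clades
  attr(out, "series") <- series
  class(out) <- c("shift_detections", "data.frame")
  out
}

test_that("older_fraction counts sampled members only", {
  ages <- data.frame(taxon = letters[1:20],
                     fad_bin = c(rep(1, 1), rep(2, 19)), lad_bin = NA)
  expect_equal(older_fraction(letters[1:20], ages, 2), 1 / 20)
  expect_equal(older_fraction(letters[2:20], ages, 2), 0)
  ages3 <- data.frame(taxon = letters[1:10],
                      fad_bin = c(rep(1, 3), rep(2, 7)), lad_bin = NA)
  expect_equal(older_fraction(letters[1:10], ages3, 2), 0.3)
  # ghosts are excluded from numerator and denominator
  expect_equal(older_fraction(c(letters[1:10], "GHOST:z"), ages3, 2), 0.3)
  expect_error(older_fraction(letters[1:3], ages3, 0), "no clade member")
})

test_that("classification honours the boundary and is monotone in the threshold", {
  mk <- function(taxa, first_bin) structure(
    list(clade = taxa, stem_node = 0L, first_bin = first_bin,
         bins_detected = first_bin, older_fraction = NA_real_,
         status = NA_character_, threshold_used = NA_real_),
    class = "shift_record")
  ages <- data.frame(taxon = paste0("s", 1:20),
                     fad_bin = c(rep(1, 2), rep(2, 18)), lad_bin = NA)
  # exactly 10% older: genuine ("does not exceed")
  r10 <- classify(list(mk(paste0("s", 1:20), 2)), ages, threshold = 0.10)[[1]]
  expect_equal(r10$older_fraction, 0.10)
  expect_equal(r10$status, "genuine")
  # 30% older: artefact
  ages30 <- data.frame(taxon = paste0("s", 1:10),
                       fad_bin = c(rep(1, 3), rep(2, 7)), lad_bin = NA)
  r30 <- classify(list(mk(paste0("s", 1:10), 2)), ages30, 0.10)[[1]]
  expect_equal(r30$status, "artefact")
  # threshold 1: everything genuine
  expect_equal(classify(list(mk(paste0("s", 1:10), 2)), ages30, 1)[[1]]$status,
               "genuine")
  # monotone: genuine set grows with the threshold
  set.seed(44)
  recs <- lapply(1:12, function(i) mk(sample(paste0("s", 1:10),
                                             sample(3:10, 1)), 2))
  gen_at <- function(th) which(vapply(classify(recs, ages30, th),
                                      `[[`, "", "status") == "genuine")
  thresholds <- c(0, 0.1, 0.25, 0.5, 1)
  gens <- lapply(thresholds, gen_at)
  for (i in seq_along(gens)[-1]) {
    expect_true(all(gens[[i - 1]] %in% gens[[i]]))
  }
  # a clade whose members all first appear at detection is always genuine
  ages0 <- data.frame(taxon = paste0("s", 1:10), fad_bin = 2, lad_bin = NA)
  expect_equal(classify(list(mk(paste0("s", 1:10), 2)), ages0, 0)[[1]]$status,
               "genuine")
})

test_that("shifts are merged across bins by their full-tree stem", {
  tr <- nwk("((((A,B),C),D),(E,F));")
  ages <- data.frame(taxon = c("A", "B", "C", "D", "E", "F"),
                     fad_bin = c(1, 2, 3, 3, 1, 1), lad_bin = NA)
  ser <- nested_series(tr, ages, bins = paste0("b", 1:3))
  det <- fake_detections(ser, list(
    list(bin = 1, members = c("A", "GHOST:B")),
    list(bin = 2, members = c("A", "B")),
    list(bin = 3, members = c("A", "B")),
    list(bin = 2, members = c("E", "F")),
    list(bin = 2, members = c("A", "B", "GHOST:C"))))
  recs <- track_shifts(det, tr)
  expect_length(recs, 3L)
  ab <- Filter(function(r) setequal(r$clade, c("A", "B")), recs)[[1]]
  expect_equal(ab$first_bin, 1L)
  expect_equal(ab$bins_detected, 1:3)
  ef <- Filter(function(r) setequal(r$clade, c("E", "F")), recs)[[1]]
  expect_equal(ef$bins_detected, 2L)
  # punctual record: detected at bin 2 only, not an up-set
  abc <- Filter(function(r) setequal(r$clade, c("A", "B", "C")), recs)[[1]]
  expect_equal(abc$bins_detected, 2L)
  expect_equal(abc$first_bin, 2L)

  recs2 <- classify(recs, ages, 0.10)
  expect_equal(Filter(function(r) setequal(r$clade, c("A", "B", "C")),
                      recs2)[[1]]$status, "artefact")  # 1 of 2 present is older
})

test_that("track_shifts merging is order-independent", {
  tr <- nwk("((((A,B),C),D),(E,F));")
  ages <- data.frame(taxon = c("A", "B", "C", "D", "E", "F"),
                     fad_bin = c(1, 2, 3, 3, 1, 1), lad_bin = NA)
  ser <- nested_series(tr, ages, bins = paste0("b", 1:3))
  picks <- list(list(bin = 1, members = c("A", "GHOST:B")),
                list(bin = 2, members = c("A", "B")),
                list(bin = 3, members = c("A", "B")))
  r1 <- track_shifts(fake_detections(ser, picks), tr)
  r2 <- track_shifts(fake_detections(ser, rev(picks)), tr)
  strip <- function(rs) lapply(rs, function(r) r[c("clade", "first_bin",
                                                   "bins_detected")])
  expect_identical(strip(r1), strip(r2))
})

test_that("an extinction-driven late detection is classified as artefact end to end", {
  # one pendant outgroup against a balanced 64-tip clade whose early fossil
  # record is a single 8-tip subclade: the clade only becomes strongly
  # unbalanced-at-the-stem once the remaining 56 taxa appear in bin 2
  bal <- ape::stree(64, type = "balanced")
  bal$tip.label <- sprintf("c%02d", 1:64)
  full <- graft(nwk("(X,PLACE);"), bal, "PLACE")
  early <- ape::extract.clade(bal, mrca_clade(bal, c("c01", "c08")))$tip.label
  ages <- data.frame(taxon = c("X", bal$tip.label),
                     fad_bin = ifelse(c("X", bal$tip.label) %in% c("X", early),
                                      1L, 2L),
                     lad_bin = NA)
  cfg <- pipeline_config(full, ages, bins = paste0("b", 1:3),
                         settings = null_settings(null_trees = 500, seed = 17),
                         threshold = 0.10)
  out <- run_pipeline(cfg)
  big <- Filter(function(r) length(r$clade) == 64L, out$records)
  expect_length(big, 1L)
  expect_equal(big[[1]]$first_bin, 2L)
  expect_equal(big[[1]]$older_fraction, 8 / 64)
  expect_equal(big[[1]]$status, "artefact")
})

test_that("the pipeline writes idempotent outputs and cleans up on failure", {
  tr <- yule_tree(sim_spec(n_tips = 30, seed = 33))
  ages <- fossilize(tr, psi = 5, n_bins = 4, seed = 12)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- function(dir) pipeline_config(
    tr, ages[, c("taxon", "fad_bin", "lad_bin")], bins = paste0("b", 1:4),
    settings = null_settings(null_trees = 150, seed = 8), out_dir = dir)
  run_pipeline(cfg(d1))
  run_pipeline(cfg(d2))
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_true(all(c("ghosts.tsv", "manifest.json", "shifts.tsv",
                    "summary.tsv") %in% f1))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  # a failing stage aborts with a stage tag and leaves no partial outputs
  d3 <- file.path(withr::local_tempdir(), "out")
  bad <- pipeline_config(tr, data.frame(taxon = "nope", fad_bin = 1,
                                        lad_bin = NA),
                         bins = paste0("b", 1:4), out_dir = d3)
  expect_error(run_pipeline(bad), "\\[slicing\\]")
  expect_false(dir.exists(d3))
})
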