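#' Default stratigraphic time bins
#'
#' The ten ordered intervals spanning the Carnian through the Recent that
#' the crocodyliform analysis slices its phylogeny over, oldest first.
#'
#' @return Character vector of 10 interval names (index 1 = oldest).
#' @export
default_time_bins <- function() {
  c("Carnian-Aalenian",
    "Bajocian-Oxfordian",
    "Kimmeridgean-Barremian",
    "Aptian-Albian",
    "Cenomanian-Santonian",
    "Campanian-Maastrichtian",
    "Palaeocene",
    "Eocene",
    "Oligocene-Miocene",
    "Pliocene-Recent")
}

validate_bins <- function(bins) {
  bins <- as.character(bins)
  if (length(bins) < 2L) stop("need at least 2 time bins")
  if (anyDuplicated(bins)) stop("time-bin names must be unique")
  bins
}

#' Assign taxa to time bins by the oldest-record rule
#'
#' Taxa recorded in several intervals, or with uncertain ages listed as
#' alternative intervals, are scored by their oldest listed interval
#' (smallest bin index); the last-appearance bin is the youngest listed.
#'
#' @param raw_ages A data frame with a `taxon` column and either an
#'   `intervals` column (one or more interval names separated by `;`) or
#'   `first_interval`/`last_interval` columns (`last_interval` optional).
#' @param bins Ordered character vector of interval names, oldest first
#'   (default [default_time_bins()]).
#' @return An age table: data frame with columns `taxon`, `fad_bin`,
#'   `lad_bin` (`NA` when no last appearance was given).
#' @export
assign_bins <- function(raw_ages, bins = default_time_bins()) {
  bins <- validate_bins(bins)
  if (!"taxon" %in% names(raw_ages)) stop("raw_ages must have a 'taxon' column")
  taxa <- as.character(raw_ages$taxon)
  if (anyDuplicated(taxa))
    stop("duplicate taxa in age table: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))

  listed <- if ("intervals" %in% names(raw_ages)) {
    strsplit(as.character(raw_ages$intervals), ";", fixed = TRUE)
  } else if ("first_interval" %in% names(raw_ages)) {
    li <- as.character(raw_ages$first_interval)
    if ("last_interval" %in% names(raw_ages)) {
      la <- as.character(raw_ages$last_interval)
      Map(function(a, b) c(a, if (!is.na(b) && nzchar(b)) b), li, la)
    } else as.list(li)
  } else stop("raw_ages needs an 'intervals' or 'first_interval' column")

  has_lad <- "last_interval" %in% names(raw_ages) &&
    any(!is.na(raw_ages$last_interval) & nzchar(as.character(raw_ages$last_interval)))

  fad <- integer(length(taxa))
  lad <- rep(NA_integer_, length(taxa))
  for (i in seq_along(taxa)) {
    names_i <- trimws(listed[[i]])
    names_i <- names_i[nzchar(names_i)]
    idx <- match(names_i, bins)
    if (anyNA(idx))
      stop("unknown interval name(s) for taxon '", taxa[i], "': ",
           paste(names_i[is.na(idx)], collapse = ", "))
    fad[i] <- min(idx)
    if (has_lad || length(idx) > 1L) lad[i] <- max(idx)
  }
  data.frame(taxon = taxa, fad_bin = fad, lad_bin = lad,
             stringsAsFactors = FALSE)
}

#' Read an age table from CSV
#'
#' Expects columns `taxon,first_interval[,last_interval]` or
#' `taxon,intervals` (UTF-8, header row).
#'
#' @inheritParams assign_bins
#' @param path CSV path.
#' @return Age table as from [assign_bins()].
#' @export
read_ages <- function(path, bins = default_time_bins()) {
  assign_bins(utils::read.csv(path, stringsAsFactors = FALSE), bins)
}

fad_vector <- function(tree, ages) {
  m <- match(tree$tip.label, ages$taxon)
  if (anyNA(m))
    stop("taxa missing from age table: ",
         paste(tree$tip.label[is.na(m)], collapse = ", "))
  stats::setNames(ages$fad_bin[m], tree$tip.label)
}

#' Collapse ghost lineages for one time slice
#'
#' Every maximal clade of the full tree whose members all first appear
#' after bin `t` is replaced by a single ghost leaf labelled
#' `GHOST:<lexicographically smallest member>`: the clade is inferred to be
#' represented by one unsampled lineage in bin `t`.  All taxa with
#' `fad_bin <= t` are retained as ordinary leaves and degree-2 chains are
#' suppressed.
#'
#' @param full_tree The full (final) tree.
#' @param ages Age table from [assign_bins()].
#' @param t Bin index (1-based, oldest = 1).
#' @return A `slice` list: `bin`, `tree` (`NULL` when degenerate),
#'   `ghost_leaves` (the `GHOST:` labels), `ghost_map` (named list mapping
#'   each ghost representative to the collapsed clade's members),
#'   `non_ghost` (taxa present by bin `t`), `degenerate` (fewer than two
#'   leaves remain).
#' @export
ghost_collapse <- function(full_tree, ages, t) {
  validate_tree(full_tree)
  fad <- fad_vector(full_tree, ages)
  n <- length(full_tree$tip.label)
  nn <- n + full_tree$Nnode
  present <- fad <= t
  if (!any(present)) stop("empty slice: no taxon has first appearance <= bin ", t)

  sets <- node_tipsets(full_tree)
  all_younger <- vapply(sets, function(labs) all(fad[labs] > t), logical(1))
  par <- parent_vector(full_tree)
  maximal <- which(all_younger &
                     (par == 0L | !all_younger[pmax(par, 1L)]))

  ghost_map <- list()
  keep <- full_tree$tip.label[present]
  reps <- character(0)
  for (v in maximal) {
    members <- sort(sets[[v]])
    rep <- members[1L]
    ghost_map[[rep]] <- members
    reps <- c(reps, rep)
  }
  kept <- c(keep, reps)
  # paste0 drops zero-length arguments instead of recycling to zero
  ghost_labels <- if (length(reps)) paste0("GHOST:", reps) else character(0)

  degenerate <- length(kept) < 2L
  tree <- NULL
  if (!degenerate) {
    tree <- ape::keep.tip(full_tree, kept)
    ix <- match(reps, tree$tip.label)
    tree$tip.label[ix] <- ghost_labels
  }
  structure(list(bin = t, tree = tree,
                 ghost_leaves = ghost_labels,
                 ghost_map = ghost_map,
                 non_ghost = keep,
                 degenerate = degenerate),
            class = "slice")
}

#' Nested-growth series of time-slice trees
#'
#' Builds one tree per time bin, oldest to youngest, in which taxa enter at
#' their first-appearance bin and are never removed; clades made entirely
#' of later arrivals are collapsed to single ghost leaves.  The series
#' therefore simulates the effect of speciation but not extinction: the
#' final slice is the full tree with no ghosts.
#'
#' @inheritParams ghost_collapse
#' @param bins Ordered interval names (default [default_time_bins()]).
#' @return A `sliced_series`: list of `slice` objects, one per bin from the
#'   first bin holding at least two non-ghost taxa through the last bin,
#'   with attributes `mode = "nested"` and `bins`.
#' @export
nested_series <- function(full_tree, ages, bins = default_time_bins()) {
  bins <- validate_bins(bins)
  validate_tree(full_tree)
  fad <- fad_vector(full_tree, ages)
  if (any(fad < 1L | fad > length(bins)))
    stop("fad_bin outside the bin range")
  slices <- list()
  started <- FALSE
  for (t in seq_along(bins)) {
    n_present <- sum(fad <= t)
    if (!started && n_present < 2L) {
      if (n_present > 0L)
        warning("bin ", t, " ('", bins[t],
                "') holds fewer than 2 sampled taxa; skipped")
      next
    }
    started <- TRUE
    slices[[length(slices) + 1L]] <- ghost_collapse(full_tree, ages, t)
  }
  if (!length(slices)) stop("no bin holds 2 or more sampled taxa")
  structure(slices, class = "sliced_series", mode = "nested", bins = bins)
}

#' Non-nested time-slice series
#'
#' The classic slicing variant for comparison: bin `t` retains taxa whose
#' stratigraphic range `[fad_bin, lad_bin]` overlaps `t` (taxa may drop
#' out), plus ghost leaves for clades of later arrivals.  Requires
#' `lad_bin` for every taxon.
#'
#' @inheritParams nested_series
#' @return A `sliced_series` with attribute `mode = "sliced"`.
#' @export
timeslice_series <- function(full_tree, ages, bins = default_time_bins()) {
  bins <- validate_bins(bins)
  validate_tree(full_tree)
  m <- match(full_tree$tip.label, ages$taxon)
  if (anyNA(m))
    stop("taxa missing from age table: ",
         paste(full_tree$tip.label[is.na(m)], collapse = ", "))
  lad <- ages$lad_bin[m]
  if (anyNA(lad))
    stop("sliced mode requires lad_bin for every taxon; missing for: ",
         paste(full_tree$tip.label[is.na(lad)], collapse = ", "))
  fad <- ages$fad_bin[m]
  slices <- list()
  started <- FALSE
  for (t in seq_along(bins)) {
    surviving <- full_tree$tip.label[lad >= t]
    n_alive <- sum(fad <= t & lad >= t)
    if (!started && n_alive < 2L) next
    started <- TRUE
    if (length(surviving) < 2L) {
      slices[[length(slices) + 1L]] <-
        structure(list(bin = t, tree = NULL, ghost_leaves = character(0),
                       ghost_map = list(), non_ghost = surviving[fad[match(surviving, full_tree$tip.label)] <= t],
                       degenerate = TRUE), class = "slice")
      next
    }
    pruned <- ape::keep.tip(full_tree, surviving)
    slices[[length(slices) + 1L]] <- ghost_collapse(pruned, ages, t)
  }
  if (!length(slices)) stop("no bin holds 2 or more coexisting taxa")
  structure(slices, class = "sliced_series", mode = "sliced", bins = bins)
}

#' @export
print.sliced_series <- function(x, ...) {
  bins <- attr(x, "bins")
  cat("Time-slice series (", attr(x, "mode"), " mode), ",
      length(x), " slices over ", length(bins), " bins\n", sep = "")
  for (s in x) {
    cat(sprintf("  bin %2d (%s): %d taxa + %d ghost lineage(s)%s\n",
                s$bin, bins[s$bin], length(s$non_ghost),
                length(s$ghost_leaves),
                if (s$degenerate) " [degenerate]" else ""))
  }
  invisible(x)
}
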