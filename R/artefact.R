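# Shift tracking across the nested series and the genuine-vs-artefact
# classification: a detected shift is a genuine radiation only when older
# taxa make up no more than a threshold fraction (default 10%) of the
# clade's species richness in the bin where the shift is first detected;
# otherwise it is read as an artefact of the extinction of older lineages.

#' Track detected shifts across time bins
#'
#' Detections at different bins are merged into one record when they denote
#' the same lineage: every slice clade, with ghost representatives expanded
#' to the full-tree clades they collapse, is a clade of the full tree, so
#' its stem node there identifies it across bins.  Punctual shifts
#' (detected then lost) yield records whose `bins_detected` is not an
#' up-set.
#'
#' @param detections A `shift_detections` data frame from
#'   [detect_shifts()].
#' @param full_tree The full tree the series was sliced from.
#' @return List of `shift_record` objects: `clade` (full-tree members),
#'   `stem_node`, `first_bin`, `bins_detected`, `older_fraction`/`status`
#'   unset until [classify()].
#' @export
track_shifts <- function(detections, full_tree) {
  stopifnot(inherits(detections, "shift_detections"))
  validate_tree(full_tree)
  clades <- attr(detections, "clades")
  series <- attr(detections, "series")
  ghost_maps <- list()
  for (s in series) ghost_maps[[as.character(s$bin)]] <- s$ghost_map

  sig <- detections[detections$significant, , drop = FALSE]
  records <- list()
  index <- character(0)  # stem-node keys, insertion-ordered
  for (i in seq_len(nrow(sig))) {
    bin <- as.integer(sig$bin[i])
    members <- clades[[as.character(bin)]][[sig$clade_id[i]]]
    expanded <- expand_ghosts(members, ghost_maps[[as.character(bin)]])
    stem <- mrca_clade(full_tree, expanded)
    key <- as.character(stem)
    if (key %in% index) {
      r <- records[[match(key, index)]]
      r$bins_detected <- sort(unique(c(r$bins_detected, bin)))
      r$first_bin <- min(r$bins_detected)
      records[[match(key, index)]] <- r
    } else {
      full_members <- node_tipsets(full_tree)[[stem]]
      records[[length(records) + 1L]] <- structure(
        list(clade = sort(full_members), stem_node = stem,
             first_bin = bin, bins_detected = bin,
             older_fraction = NA_real_, status = NA_character_,
             threshold_used = NA_real_),
        class = "shift_record")
      index <- c(index, key)
    }
  }
  records[order(vapply(records, `[[`, 0L, "first_bin"))]
}

expand_ghosts <- function(members, ghost_map) {
  out <- lapply(members, function(lab) {
    if (startsWith(lab, "GHOST:")) ghost_map[[sub("^GHOST:", "", lab)]] else lab
  })
  unique(unlist(out))
}

#' Fraction of older taxa in a clade at a bin
#'
#' The share of the clade's species richness in bin `t` made up of taxa
#' that first appeared before `t`:
#' `|members with fad_bin < t| / |members with fad_bin <= t|`.  Ghost
#' leaves are unsampled lineages, not species records, and are excluded
#' from both counts.
#'
#' @param clade Character vector of member labels (full-tree taxa; any
#'   `GHOST:` labels are dropped).
#' @param ages Age table from [assign_bins()].
#' @param t Bin index.
#' @return A fraction in `[0, 1]`.
#' @export
older_fraction <- function(clade, ages, t) {
  clade <- clade[!startsWith(clade, "GHOST:")]
  m <- match(clade, ages$taxon)
  if (anyNA(m))
    stop("clade members missing from age table: ",
         paste(clade[is.na(m)], collapse = ", "))
  fad <- ages$fad_bin[m]
  den <- sum(fad <= t)
  if (den == 0L) stop("no clade member has appeared by bin ", t)
  sum(fad < t) / den
}

#' Classify shift records as genuine or artefact
#'
#' A record is genuine when the fraction of older taxa at its
#' first-detection bin does not exceed `threshold` (boundary equality
#' counts as genuine); otherwise the shift is attributed to the extinction
#' of older lineages and marked an artefact.
#'
#' @param records List of `shift_record`s from [track_shifts()].
#' @param ages Age table.
#' @param threshold Older-taxa fraction above which a shift is an artefact
#'   (default 0.10).
#' @return The records with `older_fraction`, `status` and
#'   `threshold_used` filled.
#' @export
classify <- function(records, ages, threshold = 0.10) {
  stopifnot(threshold >= 0, threshold <= 1)
  lapply(records, function(r) {
    r$older_fraction <- older_fraction(r$clade, ages, r$first_bin)
    r$status <- if (r$older_fraction <= threshold) "genuine" else "artefact"
    r$threshold_used <- threshold
    r
  })
}

#' @export
print.shift_record <- function(x, ...) {
  cat(sprintf("Shift record: %d taxa, first bin %d (detected in %s): %s\n",
              length(x$clade), x$first_bin,
              paste(x$bins_detected, collapse = ","),
              if (is.na(x$status)) "unclassified"
              else sprintf("%s (older fraction %.3f, threshold %.2f)",
                           x$status, x$older_fraction, x$threshold_used)))
  invisible(x)
}

records_table <- function(records) {
  if (!length(records))
    return(data.frame(clade_id = character(0), members = character(0),
                      n_members = integer(0), first_bin = integer(0),
                      bins_detected = character(0), older_fraction = numeric(0),
                      status = character(0), stringsAsFactors = FALSE))
  data.frame(
    clade_id = vapply(records, function(r) r$clade[1L], character(1)),
    members = vapply(records, function(r) paste(r$clade, collapse = ";"),
                     character(1)),
    n_members = vapply(records, function(r) length(r$clade), integer(1)),
    first_bin = vapply(records, `[[`, 0L, "first_bin"),
    bins_detected = vapply(records, function(r)
      paste(r$bins_detected, collapse = ","), character(1)),
    older_fraction = vapply(records, `[[`, 0, "older_fraction"),
    status = vapply(records, `[[`, "", "status"),
    stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' @param tree Path to the full tree, or a `phylo`.
#' @param ages Path to the age CSV, or a raw-age data frame.
#' @param bins Ordered interval names (default [default_time_bins()]).
#' @param mode `"nested"` (default) or `"sliced"`.
#' @param settings A [null_settings()].
#' @param threshold Artefact threshold (default 0.10).
#' @param out_dir Output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(tree, ages, bins = default_time_bins(),
                            mode = c("nested", "sliced"),
                            settings = null_settings(), threshold = 0.10,
                            out_dir = NULL) {
  mode <- match.arg(mode)
  stopifnot(threshold >= 0, threshold <= 1)
  structure(list(tree = tree, ages = ages, bins = validate_bins(bins),
                 mode = mode, settings = settings, threshold = threshold,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Mirrors [pipeline_config()]: top-level keys `tree`, `ages`, `bins`,
#' `mode`, `threshold`, `out_dir` and a `settings` block with
#' `resolutions`, `null_trees`, `alpha`, `seed`.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  st <- y$settings %||% list()
  pipeline_config(
    tree = y$tree, ages = y$ages,
    bins = y$bins %||% default_time_bins(),
    mode = y$mode %||% "nested",
    settings = null_settings(resolutions = st$resolutions %||% 100L,
                             null_trees = st$null_trees %||% 1000L,
                             alpha = st$alpha %||% 0.05,
                             seed = st$seed %||% 1L),
    threshold = y$threshold %||% 0.10,
    out_dir = y$out_dir)
}

#' Run the full slice-scan-track-classify pipeline
#'
#' Executes slicing, per-bin shift scans, cross-bin tracking and the
#' artefact classification; when `config$out_dir` is set it writes one
#' Newick per bin, a `ghosts.tsv`, the per-branch `shifts.tsv`, a
#' `summary.tsv` (one row per shift record) and a machine-readable
#' `manifest.json`.  Outputs are idempotent given the seed; on error all
#' partial outputs are removed.
#'
#' @param config A [pipeline_config()] or the path to a YAML config.
#' @return (Invisibly) list with `series`, `detections`, `records`,
#'   `summary` and `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  tree <- if (inherits(config$tree, "phylo")) config$tree else
    tryCatch(read_tree(config$tree),
             error = function(e) stop("[treeio] ", conditionMessage(e)))
  ages <- if (is.data.frame(config$ages)) {
    if (all(c("taxon", "fad_bin") %in% names(config$ages))) config$ages
    else assign_bins(config$ages, config$bins)
  } else {
    tryCatch(read_ages(config$ages, config$bins),
             error = function(e) stop("[ages] ", conditionMessage(e)))
  }

  series <- tryCatch(
    if (config$mode == "nested") nested_series(tree, ages, config$bins)
    else timeslice_series(tree, ages, config$bins),
    error = function(e) stop("[slicing] ", conditionMessage(e)))
  detections <- tryCatch(detect_shifts(series, config$settings),
                         error = function(e) stop("[shiftstats] ",
                                                  conditionMessage(e)))
  records <- tryCatch(
    classify(track_shifts(detections, tree), ages, config$threshold),
    error = function(e) stop("[artefact] ", conditionMessage(e)))
  summary <- records_table(records)

  if (!is.null(config$out_dir)) {
    ok <- FALSE
    created <- !dir.exists(config$out_dir)
    on.exit(if (!ok) unlink(config$out_dir, recursive = TRUE), add = TRUE)
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    slice_dir <- file.path(config$out_dir, "slices")
    dir.create(slice_dir, showWarnings = FALSE)
    ghost_rows <- list()
    for (s in series) {
      if (!is.null(s$tree))
        write_tree(s$tree, file.path(slice_dir, sprintf("bin_%02d.nwk", s$bin)))
      for (rep in names(s$ghost_map))
        ghost_rows[[length(ghost_rows) + 1L]] <- data.frame(
          bin = s$bin, ghost = paste0("GHOST:", rep),
          members = paste(s$ghost_map[[rep]], collapse = ";"))
    }
    ghosts <- if (length(ghost_rows)) do.call(rbind, ghost_rows) else
      data.frame(bin = integer(0), ghost = character(0), members = character(0))
    utils::write.table(ghosts, file.path(config$out_dir, "ghosts.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(as.data.frame(detections),
                       file.path(config$out_dir, "shifts.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(summary, file.path(config$out_dir, "summary.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    manifest <- list(
      mode = config$mode,
      bins = as.list(config$bins),
      threshold = config$threshold,
      settings = unclass(config$settings),
      n_taxa = length(tree$tip.label),
      package = as.character(utils::packageVersion("nestshift")))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    ok <- TRUE
  }
  invisible(list(series = series, detections = detections, records = records,
                 summary = summary, out_dir = config$out_dir))
}
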