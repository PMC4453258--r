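# Synthetic-data generator: pure-birth(-death) chronograms with optional
# planted rate shifts, Poisson fossil sampling into stratigraphic bins,
# and noisy overlapping source trees for supertree tests.  Every stage of
# the analysis is testable against these generators without external data.

#' Simulation specification
#'
#' @param n_tips Total tips at which the simulation stops (extant plus
#'   extinct), >= 4.
#' @param lambda Base per-lineage speciation rate (1/time).
#' @param shifts List of planted shifts, each a list with `at_ntip` (the
#'   standing tip count at which the shift clade is selected), `frac` (the
#'   clade whose standing tip share is closest to this fraction is chosen),
#'   `mult` (speciation-rate multiplier > 0) and optionally `mu` (extinction
#'   rate inside the clade, for artefact scenarios).
#' @param mu Background extinction rate (default 0 = pure birth).
#' @param psi Per-lineage-time fossil recovery rate for [fossilize()].
#' @param bin_boundaries Optional increasing vector of absolute times
#'   (length = bins + 1) mapping the tree's time span onto time bins.
#' @param seed Master seed.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_tips, lambda = 1, shifts = list(), mu = 0, psi = 1,
                     bin_boundaries = NULL, seed = 1L) {
  stopifnot(n_tips >= 4L, lambda > 0, mu >= 0, psi >= 0)
  for (s in shifts) {
    stopifnot(!is.null(s[["at_ntip"]]), !is.null(s[["frac"]]),
              !is.null(s[["mult"]]), s[["mult"]] > 0,
              s[["frac"]] > 0, s[["frac"]] < 1, s[["at_ntip"]] >= 2L)
  }
  structure(list(n_tips = as.integer(n_tips), lambda = lambda,
                 shifts = shifts, mu = mu, psi = psi,
                 bin_boundaries = bin_boundaries, seed = as.integer(seed)),
            class = "sim_spec")
}

# Event-driven birth-death simulation.  Each lineage is one future edge:
# born at `btime`, it either splits (two daughters inherit its rates),
# dies, or survives to the present.  Shifts are applied when the standing
# lineage count first reaches `at_ntip`: the current clade whose standing
# tip share is closest to `frac` gets its rates multiplied thereafter.
simulate_bd <- function(spec, max_retries = 100L) {
  eval_with_seed(spec$seed, function() {
    for (try in seq_len(max_retries)) {
      res <- simulate_bd_once(spec)
      if (!is.null(res)) return(res)
    }
    stop("simulation failed ", max_retries,
         " times (clade extinct before reaching n_tips); ",
         "lower mu or n_tips")
  })
}

simulate_bd_once <- function(spec) {
  n_target <- spec$n_tips
  cap <- 4L * n_target + 8L
  parent <- integer(cap); btime <- numeric(cap); etime <- rep(NA_real_, cap)
  lam <- numeric(cap); mu <- numeric(cap)
  is_split <- logical(cap); shift_member <- integer(cap)

  parent[1:2] <- 0L; btime[1:2] <- 0
  lam[1:2] <- spec$lambda; mu[1:2] <- spec$mu
  n_nodes <- 2L
  alive <- c(1L, 2L)
  t_now <- 0
  n_tips_done <- 0L
  pending <- spec$shifts
  shift_stems <- integer(0)

  while (n_tips_done + length(alive) < n_target || length(alive) == 0L) {
    if (!length(alive)) return(NULL)  # everything died
    # planted shifts trigger on the standing lineage count
    while (length(pending) && length(alive) >= pending[[1L]]$at_ntip) {
      sh <- pending[[1L]]; pending <- pending[-1L]
      stem <- pick_shift_clade(parent, n_nodes, alive, sh$frac)
      if (is.na(stem)) next
      shift_stems <- c(shift_stems, stem)
      in_clade <- clade_members(parent, n_nodes, stem)
      live_in <- intersect(alive, in_clade)
      lam[live_in] <- lam[live_in] * sh[["mult"]]
      # exact indexing: $mu would partial-match $mult
      if (!is.null(sh[["mu"]])) mu[live_in] <- sh[["mu"]]
    }
    rates <- lam[alive] + mu[alive]
    total <- sum(rates)
    t_now <- t_now + stats::rexp(1L, total)
    v <- alive[sample.int(length(alive), 1L, prob = rates)]
    if (stats::runif(1L) < lam[v] / (lam[v] + mu[v])) {  # speciation
      etime[v] <- t_now; is_split[v] <- TRUE
      kids <- n_nodes + 1:2
      parent[kids] <- v; btime[kids] <- t_now
      lam[kids] <- lam[v]; mu[kids] <- mu[v]
      n_nodes <- n_nodes + 2L
      alive <- c(setdiff(alive, v), kids)
    } else {                                             # extinction
      etime[v] <- t_now
      alive <- setdiff(alive, v)
      n_tips_done <- n_tips_done + 1L
    }
  }
  # freeze survivors at the present
  etime[alive] <- t_now
  list(parent = parent[seq_len(n_nodes)], btime = btime[seq_len(n_nodes)],
       etime = etime[seq_len(n_nodes)], is_split = is_split[seq_len(n_nodes)],
       present = t_now, shift_stems = shift_stems)
}

clade_members <- function(parent, n_nodes, stem) {
  out <- stem
  frontier <- stem
  ids <- seq_len(n_nodes)
  while (length(frontier)) {
    nxt <- ids[parent[ids] %in% frontier]
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

# Standing clade (lineage of the current genealogy) whose share of the
# alive lineages is closest to `frac`; proper clades only.
pick_shift_clade <- function(parent, n_nodes, alive, frac) {
  counts <- integer(n_nodes)
  counts[alive] <- 1L
  for (i in rev(seq_len(n_nodes))) {
    p <- parent[i]
    if (p > 0L) counts[p] <- counts[p] + counts[i]
  }
  tot <- length(alive)
  cand <- which(counts >= 1L & counts < tot)
  if (!length(cand)) return(NA_integer_)
  share <- counts[cand] / tot
  cand[which.min(abs(share - frac))]
}

sim_to_phylo <- function(sim) {
  n <- length(sim$parent)
  is_tip <- !sim$is_split
  key <- function(i) ifelse(is_tip[i], paste0("t", i), paste0("i", i))
  tip_ids <- which(is_tip)
  labels <- stats::setNames(paste0("t", tip_ids), paste0("t", tip_ids))
  has_par <- sim$parent > 0L
  parents <- key(sim$parent[has_par])
  children <- key(which(has_par))
  # the two root lineages hang from a common root node
  root_kids <- which(!has_par)
  parents <- c(parents, rep("root", length(root_kids)))
  children <- c(children, key(root_kids))
  len <- c(sim$etime[has_par] - sim$btime[has_par],
           sim$etime[root_kids] - sim$btime[root_kids])
  tr <- phylo_from_edges(parents, children, tip_labels = labels,
                         edge_lengths = len)
  attr(tr, "present") <- sim$present
  tr
}

#' Constant-rate pure-birth (Yule) chronogram
#'
#' Simulates an equal-rates Markov tree stopped at `n_tips`, with branch
#' lengths in time units and the `present` attribute holding the stopping
#' time.  Deterministic per `spec$seed`.
#'
#' @param spec A [sim_spec()] with no shifts and `mu = 0`.
#' @return A bifurcating `phylo` with branch lengths.
#' @export
yule_tree <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (length(spec$shifts) || spec$mu > 0)
    stop("yule_tree() is the no-shift, no-extinction case; use shifted_tree()")
  sim_to_phylo(simulate_bd(spec))
}

#' Birth(-death) tree with planted rate shifts
#'
#' Lineages descending from each selected stem speciate at
#' `lambda * mult` (and die at the shift's `mu`, if set).  The true shift
#' clades are returned for recovery scoring.  If a shift clade goes
#' extinct before the present the simulation is resampled up to a retry
#' cap.
#'
#' @param spec A [sim_spec()] with at least one shift.
#' @return List with `tree` (a `phylo`) and `true_shifts` (list of tip
#'   label sets, one per planted shift).
#' @export
shifted_tree <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (!length(spec$shifts)) stop("spec has no shifts; use yule_tree()")
  sim <- simulate_bd(spec)
  tree <- sim_to_phylo(sim)
  true_shifts <- lapply(sim$shift_stems, function(stem) {
    ids <- clade_members(sim$parent, length(sim$parent), stem)
    tips <- ids[!sim$is_split[ids]]
    paste0("t", tips)
  })
  list(tree = tree, true_shifts = true_shifts)
}

#' Poisson fossil sampling into stratigraphic bins
#'
#' Fossil finds occur as a Poisson process with rate `psi` along each
#' taxon's terminal branch (or its whole root-to-tip lineage path with
#' `lineage_path = TRUE`).  The first-appearance bin is the bin holding the
#' oldest find and the last-appearance bin that of the youngest.  Taxa
#' with no finds get both set from the branch's end time and are flagged
#' `sampled = FALSE` (drop them with `drop_unsampled = TRUE`).
#'
#' @param tree A chronogram from [yule_tree()]/[shifted_tree()].
#' @param psi Fossil recovery rate (> 0).
#' @param bin_boundaries Increasing vector of absolute times, length
#'   bins + 1, covering the tree's time span (default: the span divided
#'   into `n_bins` equal bins).
#' @param n_bins Number of bins when `bin_boundaries` is `NULL`.
#' @param lineage_path Sample along the whole root-to-tip path instead of
#'   the terminal branch only.
#' @param drop_unsampled Drop taxa with no finds instead of flagging them.
#' @param seed Optional seed.
#' @return Age table: data frame with `taxon`, `fad_bin`, `lad_bin`,
#'   `sampled`.
#' @export
fossilize <- function(tree, psi, bin_boundaries = NULL, n_bins = 10L,
                      lineage_path = FALSE, drop_unsampled = FALSE,
                      seed = NULL) {
  validate_tree(tree)
  if (is.null(tree$edge.length)) stop("fossilize() needs branch lengths")
  if (psi <= 0) stop("psi must be > 0")
  depth <- ape::node.depth.edgelength(tree)
  span <- max(depth)
  if (is.null(bin_boundaries)) {
    bin_boundaries <- seq(0, span, length.out = n_bins + 1L)
  }
  if (length(bin_boundaries) < 3L || is.unsorted(bin_boundaries, strictly = TRUE))
    stop("bin_boundaries must be an increasing vector of length bins + 1")
  if (bin_boundaries[1L] > 0 || bin_boundaries[length(bin_boundaries)] < span - 1e-9)
    stop("bin cover does not span the tree's time range")
  B <- length(bin_boundaries) - 1L
  bin_of <- function(t) pmin(pmax(findInterval(t, bin_boundaries,
                                               rightmost.closed = TRUE), 1L), B)
  n <- length(tree$tip.label)
  par <- parent_vector(tree)
  eval_with_seed(seed, function() {
    fad <- integer(n); lad <- integer(n); sampled <- logical(n)
    for (i in seq_len(n)) {
      if (lineage_path) {
        lo <- 0; hi <- depth[i]
      } else {
        lo <- depth[par[i]]; hi <- depth[i]
      }
      k <- stats::rpois(1L, psi * (hi - lo))
      if (k > 0L) {
        finds <- stats::runif(k, lo, hi)
        fad[i] <- bin_of(min(finds)); lad[i] <- bin_of(max(finds))
        sampled[i] <- TRUE
      } else {
        fad[i] <- lad[i] <- bin_of(hi)
        sampled[i] <- FALSE
      }
    }
    out <- data.frame(taxon = tree$tip.label, fad_bin = fad, lad_bin = lad,
                      sampled = sampled, stringsAsFactors = FALSE)
    if (drop_unsampled) out <- out[out$sampled, , drop = FALSE]
    out
  })
}

#' Noisy overlapping source trees for supertree tests
#'
#' Each source tree is the induced subtree of `true_tree` on a random
#' `coverage` fraction of its leaves (resampled until it has >= 3),
#' perturbed by `error_moves` random rooted-NNI moves.
#'
#' @param true_tree The generating tree.
#' @param k Number of source trees.
#' @param coverage Leaf-sampling fraction in (0, 1].
#' @param error_moves Random NNI perturbations per source tree.
#' @param seed Optional seed.
#' @return List of `k` rooted trees.
#' @export
make_source_trees <- function(true_tree, k, coverage = 0.5, error_moves = 0L,
                              seed = NULL) {
  validate_tree(true_tree)
  stopifnot(k >= 1L, coverage > 0, coverage <= 1)
  n <- length(true_tree$tip.label)
  eval_with_seed(seed, function() {
    lapply(seq_len(k), function(i) {
      repeat {
        m <- max(3L, round(coverage * n))
        keep <- sample(true_tree$tip.label, min(m, n))
        if (length(keep) >= 3L) break
      }
      tr <- ape::keep.tip(true_tree, keep)
      tr$edge.length <- NULL
      for (j in seq_len(error_moves)) {
        nb <- nni_neighbors(tr)
        if (!length(nb)) break
        tr <- nb[[sample.int(length(nb), 1L)]]
      }
      tr
    })
  })
}
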