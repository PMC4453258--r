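# Shift-detection statistics.
#
# Null model: equal-rates Markov (ERM / Yule) tree shape, under which a
# designated daughter of an n-tip clade holds i tips with probability
# 1/(n-1).  The two-rate alternative uses the tilted-geometric partition
# law P(k | m, rho) = rho^(k-1) / sum_{j=1..m-1} rho^(j-1), the conditional
# law of two independent pure-birth sister clades with rate ratio rho given
# their combined tip count; rho = 1 recovers the ERM value.

.nestshift_cache <- new.env(parent = emptyenv())

#' ERM split probability
#'
#' Probability, under the equal-rates Markov (Yule) null, that a designated
#' daughter of an `n`-tip clade subtends `i` tips: uniform, `1/(n-1)`.
#'
#' @param i Daughter tip count(s), `1 <= i <= n-1` (vectorized).
#' @param n Clade tip count, `n >= 2`.
#' @return Probability (vector).
#' @export
erm_split_prob <- function(i, n) {
  if (length(n) != 1L || n < 2L) stop("n must be a single integer >= 2")
  if (any(i < 1L | i > n - 1L)) stop("i must lie in 1..n-1")
  rep(1 / (n - 1), length(i))
}

#' Maximum-likelihood tilted split
#'
#' Maximizes over `rho > 0` the tilted-geometric partition likelihood
#' `P(k | m, rho) = rho^(k-1) / sum_{j=1..m-1} rho^(j-1)`.  At the boundary
#' partitions `k = 1` or `k = m-1` the likelihood tends to 1 as `rho`
#' tends to 0 or infinity, so the supremum of the log-likelihood is exactly
#' 0 and a boundary flag is returned.
#'
#' @param k Focal daughter tip count (`1 <= k <= m-1`).
#' @param m Parent clade tip count (`m >= 2`).
#' @return List with `rho_hat` (`0`/`Inf` at the boundary), `logL1` (the
#'   maximized log-likelihood), `boundary` (logical).
#' @export
tilted_split_ml <- function(k, m) {
  if (m < 2L) stop("m must be >= 2")
  if (k < 1L || k > m - 1L) stop("k must lie in 1..m-1")
  key <- paste0("L1:", k, ":", m)
  hit <- .nestshift_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- if (k == 1L || k == m - 1L) {
    list(rho_hat = if (k == 1L) 0 else Inf, logL1 = 0, boundary = TRUE)
  } else {
    j <- 0:(m - 2L)  # exponents of rho in the normalizer
    negll <- function(x) {
      e <- j * x
      mx <- max(e)
      -((k - 1) * x - (mx + log(sum(exp(e - mx)))))
    }
    opt <- stats::optimize(negll, interval = c(-40, 40), tol = 1e-10)
    list(rho_hat = exp(opt$minimum), logL1 = -opt$objective, boundary = FALSE)
  }
  assign(key, out, envir = .nestshift_cache)
  out
}

# Table of maximized log-likelihoods L1[m, k] for all 2 <= m <= max_m,
# 1 <= k <= m-1 (0 elsewhere).  Cached; the branch scan reads it hot.
logL1_table <- function(max_m) {
  key <- "L1tab"
  tab <- .nestshift_cache[[key]]
  if (is.null(tab) || nrow(tab) < max_m) {
    old <- if (is.null(tab)) 1L else nrow(tab)
    new <- matrix(0, max_m, max_m)
    if (!is.null(tab)) new[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
    for (m in seq(max(2L, old + 1L), max_m)) {
      for (k in seq_len(m - 1L)) new[m, k] <- tilted_split_ml(k, m)$logL1
    }
    assign(key, new, envir = .nestshift_cache)
    tab <- new
  }
  tab
}

#' Branch shift statistics from diversity partitions
#'
#' `delta1` is the support for a rate shift along the focal branch from the
#' partition at its parent node alone: `logL1(k|m) - log erm(k, m)`.
#' `delta2` discounts support better explained by a shift nested inside the
#' focal clade:
#' `[logL1(k|m) + log erm(max(l,r), k)] - [log erm(k, m) + logL1(max(l,r)|k)]`.
#' A pendant focal clade (`k = 1`) takes `delta2 = 0` by convention.
#'
#' @param counts List (or data frame row) with `m` (tips under the parent
#'   node), `k` (tips in the focal clade), and, when the focal clade is
#'   internal, its daughters' tip counts `l` and `r` (`l + r = k`).
#' @return List with `delta1` and `delta2` (finite reals; `delta1 >= 0`).
#' @export
delta_stats <- function(counts) {
  m <- counts$m; k <- counts$k
  if (is.null(m) || is.null(k) || m < 2L || k < 1L || k > m - 1L)
    stop("invalid split counts: need 1 <= k <= m-1")
  d1 <- tilted_split_ml(k, m)$logL1 + log(m - 1)
  if (k == 1L) return(list(delta1 = d1, delta2 = 0))
  l <- counts$l; r <- counts$r
  if (is.null(l) || is.null(r))
    stop("internal focal clade needs daughter counts l and r")
  if (l < 1L || r < 1L || l + r != k) stop("daughter counts must satisfy l + r = k")
  lm <- max(l, r)
  d2 <- (tilted_split_ml(k, m)$logL1 - log(k - 1)) -
    (-log(m - 1) + tilted_split_ml(lm, k)$logL1)
  list(delta1 = d1, delta2 = d2)
}

#' Monte-Carlo resolution of soft polytomies
#'
#' Each polytomy is independently resolved into a bifurcating subtree under
#' the ERM process restricted to its children: children are joined pairwise,
#' uniformly at random, until two remain.  Bifurcating input is returned
#' unchanged.
#'
#' @param tree A `phylo`.
#' @param seed Optional integer; resolution is deterministic per seed and
#'   the caller's RNG stream is left untouched when a seed is given.
#' @return A fully bifurcating `phylo` with the same leaf set.
#' @export
resolve_polytomies <- function(tree, seed = NULL) {
  validate_tree(tree)
  if (is_bifurcating(tree)) return(tree)
  eval_with_seed(seed, function() {
    n <- length(tree$tip.label)
    ch <- children_list(tree)
    ep <- character(0); ec <- character(0)
    counter <- 0L
    key_of <- function(id) if (id <= n) tree$tip.label[id] else paste0("#", id)
    build <- function(node) {
      kids <- vapply(ch[[node]], function(cid) {
        if (cid <= n) key_of(cid) else build(cid)
      }, character(1))
      while (length(kids) > 2L) {
        pick <- sample.int(length(kids), 2L)
        counter <<- counter + 1L
        nk <- paste0("@", counter)
        ep <<- c(ep, nk, nk); ec <<- c(ec, kids[pick])
        kids <- c(kids[-pick], nk)
      }
      me <- key_of(node)
      ep <<- c(ep, me, me); ec <<- c(ec, kids)
      me
    }
    build(n + 1L)
    phylo_from_edges(ep, ec)
  })
}

#' Monte-Carlo settings for the shift scan
#'
#' @param resolutions Whole-tree random polytomy resolutions averaged over
#'   (desk default 100; the full-scale analysis used 10 000 per node and
#'   1 000 000 whole-tree).
#' @param null_trees ERM null trees per scan (desk default 1000).
#' @param alpha Significance level for the tree-wide test.
#' @param seed Master seed; every random draw in a scan descends from it.
#' @return A `null_settings` list.
#' @export
null_settings <- function(resolutions = 100L, null_trees = 1000L,
                          alpha = 0.05, seed = 1L) {
  stopifnot(resolutions >= 1L, null_trees >= 1L, alpha > 0, alpha < 1)
  structure(list(resolutions = as.integer(resolutions),
                 null_trees = as.integer(null_trees),
                 alpha = alpha, seed = as.integer(seed)),
            class = "null_settings")
}

size_class <- function(k) as.integer(floor(log2(pmax(k, 2L))))

# Vectorized delta2 from per-branch (m, k, lmax) arrays via the cached
# L1 table; pendant branches (k = 1) are 0 by convention.
delta2_vec <- function(m, k, lmax, L1) {
  out <- numeric(length(k))
  int <- k >= 2L
  out[int] <- L1[cbind(m[int], k[int])] - log(k[int] - 1) +
    log(m[int] - 1) - L1[cbind(k[int], lmax[int])]
  out
}

# Sample G ERM trees of n tips and return, per tree, the maximum delta2
# over internal branches overall and within each dyadic size class.
erm_null_stats <- function(n, G, L1) {
  nclass <- size_class(n)
  overall <- numeric(G)
  bycls <- matrix(-Inf, G, nclass)
  u <- stats::runif(G * (n - 1L))
  up <- 0L
  ms <- integer(n); ks <- integer(n); ls <- integer(n)
  stack_s <- integer(2L * n); stack_p <- integer(2L * n)
  for (g in seq_len(G)) {
    cnt <- 0L
    top <- 1L
    stack_s[1L] <- n; stack_p[1L] <- 0L
    while (top > 0L) {
      s <- stack_s[top]; p <- stack_p[top]; top <- top - 1L
      up <- up + 1L
      a <- 1L + as.integer(u[up] * (s - 1L))
      if (a >= s) a <- s - 1L
      b <- s - a
      if (p > 0L) {
        cnt <- cnt + 1L
        ms[cnt] <- p; ks[cnt] <- s; ls[cnt] <- max(a, b)
      }
      if (a >= 2L) { top <- top + 1L; stack_s[top] <- a; stack_p[top] <- s }
      if (b >= 2L) { top <- top + 1L; stack_s[top] <- b; stack_p[top] <- s }
    }
    if (cnt == 0L) { overall[g] <- -Inf; next }
    d2 <- delta2_vec(ms[seq_len(cnt)], ks[seq_len(cnt)], ls[seq_len(cnt)], L1)
    overall[g] <- max(d2)
    cls <- size_class(ks[seq_len(cnt)])
    for (cl in unique(cls)) bycls[g, cl] <- max(d2[cls == cl])
  }
  list(overall = overall, by_class = bycls)
}

#' Scan every internal branch of a tree for diversification shifts
#'
#' For each internal branch of the (possibly polytomous) input tree the
#' `delta1`/`delta2` statistics are averaged over random ERM resolutions of
#' the polytomies, and compared against ERM null trees of the same tip
#' count (ghost leaves count as ordinary tips).  `p_tree` is the fraction
#' of null trees whose maximum `delta2` anywhere reaches the branch's value
#' (familywise control over the whole-tree survey); `p_local` compares
#' against the null maximum among clades of the same dyadic size class.
#' Both use the add-one Monte-Carlo estimator, so they are never exactly 0.
#'
#' @param tree A rooted `phylo` with at least 4 leaves.
#' @param settings A [null_settings()] object.
#' @return A `branch_shift_scores` data frame with one row per internal
#'   branch: `clade_id`, `k`, `delta1`, `delta2`, `p_local`, `p_tree`,
#'   `n_resolutions`; the focal clades' member labels are kept in the
#'   `clades` attribute (a named list).
#' @export
branch_shift_scan <- function(tree, settings = null_settings()) {
  validate_tree(tree)
  n <- length(tree$tip.label)
  if (n < 4L) stop("tree too small to scan (need >= 4 leaves)")
  seeds <- derive_seeds(settings$seed, 2L)
  L1 <- logL1_table(n)

  sets <- node_tipsets(tree)
  rt <- root_node(tree)
  internal <- setdiff((n + 1L):(n + tree$Nnode), rt)
  if (!length(internal)) stop("tree has no internal branch to scan")
  sig <- vapply(internal, function(v) clade_signature(sets[[v]]), character(1))

  is_bin <- is_bifurcating(tree)
  n_res <- if (is_bin) 1L else settings$resolutions
  d1 <- matrix(0, length(internal), n_res)
  d2 <- matrix(0, length(internal), n_res)
  res_seeds <- derive_seeds(seeds[1L], n_res)
  for (r in seq_len(n_res)) {
    rtree <- if (is_bin) tree else resolve_polytomies(tree, seed = res_seeds[r])
    stats_r <- branch_partition_counts(rtree, sig)
    dd <- delta2_vec(stats_r$m, stats_r$k, stats_r$lmax, L1)
    d2[, r] <- dd
    d1[, r] <- L1[cbind(stats_r$m, stats_r$k)] + log(stats_r$m - 1)
  }
  delta1 <- rowMeans(d1)
  delta2 <- rowMeans(d2)
  k_obs <- lengths(sets[internal])

  null <- eval_with_seed(seeds[2L], function()
    erm_null_stats(n, settings$null_trees, L1))
  G <- settings$null_trees
  p_tree <- vapply(delta2, function(d) (1 + sum(null$overall >= d)) / (G + 1),
                   numeric(1))
  cls <- size_class(k_obs)
  p_local <- vapply(seq_along(internal), function(i)
    (1 + sum(null$by_class[, cls[i]] >= delta2[i])) / (G + 1), numeric(1))

  out <- data.frame(clade_id = vapply(internal, function(v)
    paste(sort(sets[[v]]), collapse = ","), character(1)),
    node = internal, k = as.integer(k_obs),
    delta1 = delta1, delta2 = delta2,
    p_local = p_local, p_tree = p_tree,
    n_resolutions = n_res, stringsAsFactors = FALSE)
  attr(out, "clades") <- stats::setNames(lapply(internal, function(v) sets[[v]]),
                                         out$clade_id)
  attr(out, "n_tips") <- n
  class(out) <- c("branch_shift_scores", "data.frame")
  out
}

# Per-branch (m, k, lmax) of a *bifurcating* tree, aligned to the clade
# signatures `sig` of the branches being tracked (clades of the unresolved
# input tree persist through any resolution).
branch_partition_counts <- function(rtree, sig) {
  n <- length(rtree$tip.label)
  sets <- node_tipsets(rtree)
  counts <- lengths(sets)
  par <- parent_vector(rtree)
  ch <- children_list(rtree)
  rsig <- vapply((n + 1L):(n + rtree$Nnode),
                 function(v) clade_signature(sets[[v]]), character(1))
  idx <- match(sig, rsig) + n
  if (anyNA(idx)) stop("internal error: input clade lost during resolution")
  m <- counts[par[idx]]
  k <- counts[idx]
  lmax <- vapply(idx, function(v) max(counts[ch[[v]]]), numeric(1))
  list(m = as.integer(m), k = as.integer(k), lmax = as.integer(lmax))
}

#' Best-supported branch of a scan
#'
#' Returns the row with the smallest tree-wide p-value; ties are broken
#' toward the larger Delta2, then the larger focal clade, then
#' lexicographic clade id (stable reporting).
#'
#' @param scores A `branch_shift_scores` data frame.
#' @return One-row data frame.
#' @export
top_shift_branch <- function(scores) {
  stopifnot(inherits(scores, "branch_shift_scores"))
  ord <- order(scores$p_tree, -scores$delta2, -scores$k, scores$clade_id)
  scores[ord[1L], , drop = FALSE]
}

#' Detect shifts across a time-slice series
#'
#' Runs [branch_shift_scan()] on every non-degenerate slice tree with at
#' least 4 leaves and reports branches whose tree-wide Monte-Carlo p-value
#' is at or below `settings$alpha`.  Each bin's scan uses a substream seed
#' derived from the master seed, so the whole series is reproducible.
#'
#' @param series A `sliced_series` from [nested_series()] or
#'   [timeslice_series()].
#' @param settings A [null_settings()] object.
#' @return A `shift_detections` data frame (bin, clade_id, k, delta1,
#'   delta2, p_local, p_tree, significant), ordered old to young, with the
#'   per-bin clade membership lists in the `clades` attribute and the
#'   series in `series`.
#' @export
detect_shifts <- function(series, settings = null_settings()) {
  stopifnot(inherits(series, "sliced_series"))
  bin_seeds <- derive_seeds(settings$seed, length(series))
  rows <- list()
  clades <- list()
  for (i in seq_along(series)) {
    s <- series[[i]]
    if (s$degenerate || is.null(s$tree) || length(s$tree$tip.label) < 4L) next
    st <- settings; st$seed <- bin_seeds[i]
    sc <- branch_shift_scan(s$tree, st)
    sc$bin <- s$bin
    sc$significant <- sc$p_tree <= settings$alpha
    rows[[length(rows) + 1L]] <- as.data.frame(sc)[, c(
      "bin", "clade_id", "k", "delta1", "delta2",
      "p_local", "p_tree", "significant")]
    clades[[as.character(s$bin)]] <- attr(sc, "clades")
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(bin = integer(0), clade_id = character(0), k = integer(0),
               delta1 = numeric(0), delta2 = numeric(0),
               p_local = numeric(0), p_tree = numeric(0),
               significant = logical(0))
  rownames(out) <- NULL
  attr(out, "clades") <- clades
  attr(out, "series") <- series
  attr(out, "alpha") <- settings$alpha
  class(out) <- c("shift_detections", "data.frame")
  out
}
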