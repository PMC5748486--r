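# Presence patterns as tip bitmasks in the order of `labels`.
# Returns list(ids, car, non) dropping carrier-free mutations (with warning).
.presence_patterns <- function(presence, labels) {
  state <- presence$state[, labels, drop = FALSE]
  bits <- bitwShiftL(1L, seq_along(labels) - 1L)
  car <- as.integer((state == "present") %*% bits)
  non <- as.integer((state == "absent") %*% bits)
  keep <- car > 0L
  if (any(!keep))
    warning(sum(!keep), " mutation(s) with no carrier skipped",
            call. = FALSE)
  list(ids = rownames(state)[keep], car = car[keep], non = non[keep])
}

#' Score a rooted sample tree by mutation compatibility
#'
#' A mutation is compatible with the tree if some clade (any node's leaf
#' set, the root clade being the trunk) contains all samples in which it is
#' present and excludes all samples in which it is explicitly absent;
#' missing cells constrain nothing.  The tree score is the number of
#' compatible mutations.  Each compatible mutation is assigned to the
#' smallest such clade's incoming edge, and the per-edge counts are the
#' branch lengths ("mutations supporting this separation"); incompatible
#' (homoplastic) mutations support no branch and are listed separately.
#'
#' @param tree A [sample_tree()] whose tips are the presence-matrix samples.
#' @param presence A [call_presence()] matrix with >= 2 samples.
#' @return The tree with `score`, `support`, `assignment` (named node
#'   index per compatible mutation) and `homoplasy` filled in.
#' @export
score_tree <- function(tree, presence) {
  stopifnot(inherits(tree, "sample_tree"),
            inherits(presence, "presence_matrix"))
  if (!setequal(tree$labels, colnames(presence$state)))
    .stop_invalid("tree tips must match presence-matrix samples")
  pat <- .presence_patterns(presence, tree$labels)
  masks <- .clade_masks(tree$parent, tree$n_tip)
  sizes <- .popcount(masks)
  node <- integer(length(pat$ids))
  for (j in seq_along(pat$ids)) {
    ok <- bitwAnd(masks, pat$car[j]) == pat$car[j] &
      bitwAnd(masks, pat$non[j]) == 0L
    node[j] <- if (any(ok)) which(ok)[which.min(sizes[ok])] else 0L
  }
  compat <- node > 0L
  tree$score <- sum(compat)
  tree$support <- tabulate(node[compat], nbins = length(tree$parent))
  tree$assignment <- setNames(node[compat], pat$ids[compat])
  tree$homoplasy <- pat$ids[!compat]
  tree
}

# Aggregate identical (car, non) patterns with multiplicities.
.aggregate_patterns <- function(pat) {
  key <- paste(pat$car, pat$non)
  first <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[first])))
  list(car = pat$car[first], non = pat$non[first], w = as.numeric(w))
}

.score_parent <- function(parent, n_tip, agg) {
  score_patterns_cpp(.clade_masks(parent, n_tip), agg$car, agg$non, agg$w)
}

#' Find the highest-scoring rooted sample tree
#'
#' Exhaustive mode scores every rooted binary topology (feasible up to
#' `exhaustive_limit` tips) and returns a global maximum-compatibility
#' tree.  Hill-climbing mode runs steepest-ascent over
#' nearest-neighbor-interchange and root-relocation moves, starting from
#' the binary-distance average-linkage join tree plus random restarts.
#' Score ties are broken by the lexicographically smallest canonical
#' newick, so results are deterministic given the seed.
#'
#' @param presence A [call_presence()] matrix with >= 2 samples.
#' @param method `"auto"` (exhaustive when the sample count allows, else
#'   hill-climbing), `"exhaustive"`, or `"hill_climb"`.
#' @param exhaustive_limit Largest sample count for exhaustive search
#'   (default 9; `(2n-3)!!` topologies are visited).
#' @param restarts Number of hill-climbing starts (default 10).
#' @param seed Optional integer seed for the random restarts.
#' @return A scored [sample_tree()] (see [score_tree()]).
#' @export
best_tree <- function(presence, method = c("auto", "exhaustive", "hill_climb"),
                      exhaustive_limit = 9, restarts = 10, seed = NULL) {
  stopifnot(inherits(presence, "presence_matrix"))
  method <- match.arg(method)
  labels <- colnames(presence$state)
  n <- length(labels)
  if (n < 2) .stop_invalid("need at least 2 samples")
  all_missing <- colSums(presence$state != "missing") == 0L
  if (any(all_missing))
    .stop_invalid("sample(s) with only missing calls: ",
                  paste(labels[all_missing], collapse = ", "))
  if (method == "auto")
    method <- if (n <= exhaustive_limit) "exhaustive" else "hill_climb"
  if (method == "exhaustive" && n > exhaustive_limit)
    .stop_invalid(n, " samples exceed the exhaustive limit (",
                  exhaustive_limit, "); use method = \"hill_climb\"")

  pat <- suppressWarnings(.presence_patterns(presence, labels))
  agg <- .aggregate_patterns(pat)

  if (method == "exhaustive") {
    res <- exhaustive_search_cpp(n, agg$car, agg$non, agg$w, labels)
    tree <- as_sample_tree(res$newick)
    # restore tip index order to match `labels`
    tree <- .relabel_tips(tree, labels)
  } else {
    tree <- .hill_climb(presence, labels, agg, restarts = restarts,
                        seed = seed)
  }
  score_tree(tree, presence)
}

# Reorder tip indices of `tree` so tip i carries labels[i].
.relabel_tips <- function(tree, labels) {
  perm <- match(tree$labels, labels)  # tip j in tree -> index perm[j]
  n <- tree$n_tip
  map <- c(perm, (n + 1L):(2L * n - 1L))
  parent <- integer(length(tree$parent))
  for (v in seq_along(tree$parent)) {
    p <- tree$parent[v]
    parent[map[v]] <- if (p == 0L) 0L else map[p]
  }
  sample_tree(parent, labels)
}

.hill_climb <- function(presence, labels, agg, restarts = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(labels)

  starts <- list()
  d <- try(binary_distance_matrix(presence), silent = TRUE)
  if (!inherits(d, "try-error") && !anyNA(d)) {
    hc <- average_linkage(d)
    starts[[1L]] <- as_sample_tree(hc)$parent
  }
  while (length(starts) < max(1L, restarts))
    starts[[length(starts) + 1L]] <- random_topology(labels)$parent

  best_score <- -Inf
  best_parent <- NULL
  best_nwk <- NULL
  for (parent in starts) {
    cur <- parent
    cur_score <- .score_parent(cur, n, agg)
    repeat {
      neigh <- c(.nni_neighbors(cur, n), .leaf_spr_neighbors(cur, n))
      for (x in seq_len(2L * n - 1L)) {
        r <- .reroot(cur, n, x)
        if (!is.null(r)) neigh[[length(neigh) + 1L]] <- r
      }
      if (!length(neigh)) break
      sc <- vapply(neigh, .score_parent, 0, n_tip = n, agg = agg)
      if (max(sc) > cur_score) {
        cur <- neigh[[which.max(sc)]]
        cur_score <- max(sc)
      } else break
    }
    nwk <- .canonical_newick(cur, labels)
    if (cur_score > best_score ||
        (cur_score == best_score && nwk < best_nwk)) {
      best_score <- cur_score
      best_parent <- cur
      best_nwk <- nwk
    }
  }
  sample_tree(best_parent, labels)
}
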